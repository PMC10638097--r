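#' Discrete 3D Laplacian
#'
#' 6-neighbour second central difference summed over the three axes, with
#' replicate-edge padding. By default the stencil uses unit voxel spacing on
#' every axis: the downstream statistic is a rank correlation that compares
#' the two channels voxel-wise with identical stencils, so a per-axis scale
#' is immaterial; set `spacing` to compute in physical units instead.
#'
#' @param channel 3D intensity array (at least 8 voxels per axis).
#' @param spacing Per-axis spacing for physical-unit derivatives, or `NULL`
#'   (default) for voxel units.
#' @return 3D array of the same shape (the Laplacian field).
#' @examples
#' v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 1
#' l <- laplacian_3d(v)
#' l[5, 5, 5] # -6
#' @export
laplacian_3d <- function(channel, spacing = NULL) {
  assert_volume(channel, "channel")
  if (any(dim(channel) < 8L)) {
    stop("field must be at least 8 voxels along every axis", call. = FALSE)
  }
  h2 <- if (is.null(spacing)) c(1, 1, 1) else as.numeric(spacing)^2
  out <- array(0, dim(channel))
  for (a in 1:3) {
    out <- out +
      (shift_array(channel, a, 1L) + shift_array(channel, a, -1L) -
         2 * channel) / h2[a]
  }
  out
}

#' Negative part of a Laplacian field
#'
#' Maps each value v to `max(-v, 0)`. The negative Laplacian is positive
#' inside bright objects near their cores and edges, which is the signal the
#' windowed rank correlation acts on.
#'
#' @param lap 3D array (a Laplacian field).
#' @return Non-negative 3D array, zero wherever `lap >= 0`.
#' @export
negative_part <- function(lap) {
  out <- -lap
  out[out < 0] <- 0
  out
}

#' Third-derivative (gradient-of-Laplacian) magnitude
#'
#' Per-voxel Euclidean norm of the central-difference gradient of the
#' Laplacian field, with replicate-edge padding. Used by the shadow filter:
#' a voxel where the Laplacian changes in one channel but not the other
#' cannot belong to a contact.
#'
#' @inheritParams laplacian_3d
#' @return 3D array of the same shape (non-negative magnitude).
#' @export
third_derivative <- function(channel, spacing = NULL) {
  lap <- laplacian_3d(channel, spacing = spacing)
  h <- if (is.null(spacing)) c(1, 1, 1) else as.numeric(spacing)
  acc <- array(0, dim(lap))
  for (a in 1:3) {
    g <- (shift_array(lap, a, 1L) - shift_array(lap, a, -1L)) / (2 * h[a])
    acc <- acc + g^2
  }
  sqrt(acc)
}

# Tolerance below which a third-derivative magnitude counts as zero:
# 1e-8 times the field's 99th percentile (exact zeros are fragile in floating
# point).
third_derivative_tol <- function(d3) {
  1e-8 * as.numeric(stats::quantile(d3, 0.99, names = FALSE))
}
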