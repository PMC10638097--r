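#' Windowed Spearman correlation of two volumes
#'
#' At every voxel whose centered `(2w+1)^3` cube fits inside the volume,
#' computes the Spearman rank correlation (average ranks for ties) of the two
#' fields over that cube. Windows in which either field is constant have no
#' defined correlation and return 0, so empty background never responds.
#' Voxels whose window does not fit return 0.
#'
#' @param field_a,field_b 3D arrays of identical shape.
#' @param w Window half-width in voxels; `2w+1` must not exceed the smallest
#'   axis.
#' @param mask Optional logical array: evaluate only where `TRUE` (other
#'   voxels return 0). Used internally to avoid computing the intensity
#'   correlation outside candidate contact voxels.
#' @return 3D array of correlations in `[-1, 1]`.
#' @export
windowed_spearman <- function(field_a, field_b, w = 2L, mask = NULL) {
  assert_volume(field_a, "field_a")
  assert_volume(field_b, "field_b")
  if (!identical(dim(field_a), dim(field_b))) {
    stop(sprintf("shape mismatch: (%s) vs (%s)",
                 paste(dim(field_a), collapse = ","),
                 paste(dim(field_b), collapse = ",")), call. = FALSE)
  }
  w <- as.integer(w)
  d <- dim(field_a)
  if (2L * w + 1L > min(d)) {
    stop(sprintf("window of %d voxels exceeds the smallest axis (%d)",
                 2L * w + 1L, min(d)), call. = FALSE)
  }
  msk <- if (is.null(mask)) NULL else as.logical(mask)
  out <- cpp_windowed_spearman(as.numeric(field_a), as.numeric(field_b),
                               as.integer(d), w, msk)
  array(out, d)
}

#' Raw contact response of a channel pair
#'
#' Computes the per-voxel windowed Spearman correlation of the two channels'
#' negative Laplacians (`rho_lap`) and of their raw intensities (`rho_int`),
#' and retains the Laplacian correlation magnitude only where both are
#' negative:
#' `magnitude = -rho_lap` where `rho_lap < 0` and `rho_int < 0`, else 0.
#' The intensity gate prevents low-intensity signal colocalizing with
#' high-intensity signal from being scored as contact. The outer `w`-voxel
#' shell is zeroed (incomplete windows).
#'
#' @param pair A [volume_pair()].
#' @param params A [detect_params()].
#' @return Object of class `response_map`: list with `rho_lap`, `rho_int`,
#'   `magnitude`, `n_window`, `params`.
#' @export
contact_response <- function(pair, params = detect_params()) {
  stopifnot(inherits(pair, "volume_pair"), inherits(params, "detect_params"))
  a <- pair$channel_a
  b <- pair$channel_b
  if (params$presmooth_sigma > 0) {
    sg <- rep(params$presmooth_sigma, 3) * pair$spacing # sigma in voxels
    a <- gaussian_blur(a, sg, pair$spacing)
    b <- gaussian_blur(b, sg, pair$spacing)
  }
  sp <- if (params$physical_units) pair$spacing else NULL
  nl_a <- negative_part(laplacian_3d(a, spacing = sp))
  nl_b <- negative_part(laplacian_3d(b, spacing = sp))
  rho_lap <- windowed_spearman(nl_a, nl_b, params$w)
  cand <- rho_lap < 0
  rho_int <- windowed_spearman(a, b, params$w, mask = cand)
  magnitude <- array(0, dim(a))
  keep <- cand & rho_int < 0
  magnitude[keep] <- -rho_lap[keep]
  magnitude <- zero_shell(magnitude, params$w)
  structure(
    list(rho_lap = rho_lap, rho_int = rho_int, magnitude = magnitude,
         n_window = as.integer((2L * params$w + 1L)^3), params = params),
    class = "response_map"
  )
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf(
    "response_map: %s voxels, window %d, %d voxels with positive response\n",
    paste(dim(x$magnitude), collapse = " x "), x$n_window,
    sum(x$magnitude > 0)
  ))
  invisible(x)
}

# Zero the outer `w`-voxel shell of a volume (padding artifacts).
zero_shell <- function(v, w) {
  d <- dim(v)
  if (w < 1L) return(v)
  v[c(seq_len(w), d[1] - seq_len(w) + 1L), , ] <- 0
  v[, c(seq_len(w), d[2] - seq_len(w) + 1L), ] <- 0
  v[, , c(seq_len(w), d[3] - seq_len(w) + 1L)] <- 0
  v
}
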