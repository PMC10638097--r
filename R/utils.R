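# Internal array helpers shared across modules.

# Shift a 3D array by `by` voxels along `axis` with replicate-edge padding.
shift_array <- function(v, axis, by) {
  d <- dim(v)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] - by
  i[i < 1L] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  v[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
}

# Min-max rescale to [0, 1]; constant arrays map to 0.
rescale01 <- function(v) {
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) {
    return(array(0, dim(v)))
  }
  (v - lo) / (hi - lo)
}

# Global Otsu threshold of a [0,1]-valued volume. EBImage's otsu() works on the
# intensity histogram only, so the volume is passed flattened as a single
# grayscale frame.
otsu_threshold <- function(v01) {
  img <- EBImage::Image(as.numeric(v01), dim = c(length(v01), 1L))
  as.numeric(EBImage::otsu(img, range = c(0, 1)))
}

# 26-neighbourhood binary dilation of a logical 3D array.
dilate26 <- function(mask, iter = 1L) {
  d <- dim(mask)
  out <- cpp_dilate26(as.logical(mask), as.integer(d), as.integer(iter))
  array(out, d)
}

#' Dilate a binary 3D mask
#'
#' 26-neighbourhood (1-voxel cube) binary dilation, repeated `voxels` times.
#' This is the adjacency operation used throughout: contact-mitochondrion
#' association, surface coverage, and ground-truth matching tolerances.
#'
#' @param mask Logical 3D array.
#' @param voxels Number of dilation passes (>= 0; 0 returns the mask).
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, voxels = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  voxels <- as.integer(voxels)
  if (voxels <= 0L) return(mask | mask)
  dilate26(mask, voxels)
}

# Connected-component labelling (26- or 6-connectivity) of a logical 3D array.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  array(lab, d)
}

assert_volume <- function(v, name = "volume") {
  if (!is.array(v) || length(dim(v)) != 3L) {
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  }
  if (!all(is.finite(v))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(v)
}
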