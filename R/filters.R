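#' Bleed-through mask of a channel
#'
#' Standard-score mask: `TRUE` where `(intensity - mean) / sd >= z_filter`,
#' with mean and sd computed over the channel's nonzero voxels (keeping the
#' statistic meaningful in mostly-empty volumes). Because the z-score is a
#' pivotal quantity the filter adapts to each channel's intensity
#' distribution; bleed-through ghosts across z-planes score markedly lower
#' than genuine structures. Response voxels must lie inside the mask of both
#' channels.
#'
#' @param channel 3D intensity array.
#' @param z_filter z-score threshold (default 3).
#' @return Logical 3D array. A degenerate channel (sd = 0 over nonzero
#'   voxels) yields an all-`FALSE` mask with a warning.
#' @export
bleedthrough_mask <- function(channel, z_filter = 3) {
  assert_volume(channel, "channel")
  nz <- channel[channel != 0]
  if (length(nz) < 2L || stats::sd(nz) == 0) {
    warning("degenerate channel (zero variance over nonzero voxels); ",
            "bleed-through mask is empty")
    return(array(FALSE, dim(channel)))
  }
  mu <- mean(nz)
  sdv <- stats::sd(nz)
  (channel - mu) / sdv >= z_filter
}

#' Shadow (third-derivative consistency) filter
#'
#' Removes "shadow" responses: bands parallel to a true interface where the
#' intensity of only one channel is changing. A voxel is zeroed when exactly
#' one of the two third-derivative magnitudes is (numerically) zero; voxels
#' where both are zero, or both nonzero, pass -- a third derivative can be
#' zero for a valid contact, but only in both channels at once.
#'
#' @param resp A `response_map`.
#' @param d3_a,d3_b Third-derivative magnitude fields of the two channels
#'   (from [third_derivative()]).
#' @return The `response_map` with shadow voxels zeroed.
#' @export
shadow_filter <- function(resp, d3_a, d3_b) {
  stopifnot(inherits(resp, "response_map"))
  tol_a <- third_derivative_tol(d3_a)
  tol_b <- third_derivative_tol(d3_b)
  zero_a <- d3_a <= tol_a
  zero_b <- d3_b <= tol_b
  out <- resp
  out$magnitude[xor(zero_a, zero_b)] <- 0
  out
}

#' Segment mitochondria-channel components
#'
#' Foreground by a global Otsu threshold on the min-max `[0,1]`-rescaled
#' channel, labelled with 26-connectivity. Per component: voxel size,
#' `ln(size)` and mean rescaled intensity, plus the keep flag
#' `ln_size >= mito_ln_size & mean_intensity >= mito_min_intensity` that
#' separates genuine mitochondria from small dim vesicle-like objects.
#'
#' @param channel Mitochondria-channel 3D intensity array.
#' @param mito_ln_size,mito_min_intensity Keep thresholds (defaults 9 and
#'   0.2).
#' @return Object of class `mito_components`: list with `labels` (integer 3D
#'   array) and `components` (tibble: label, size, ln_size, mean_intensity,
#'   keep).
#' @export
segment_mito_components <- function(channel, mito_ln_size = 9,
                                    mito_min_intensity = 0.2) {
  assert_volume(channel, "channel")
  v01 <- rescale01(channel)
  thr <- otsu_threshold(v01)
  fg <- v01 > thr
  if (!any(fg)) {
    warning("empty mitochondria foreground")
    return(structure(
      list(labels = array(0L, dim(channel)),
           components = tibble::tibble(
             label = integer(), size = integer(), ln_size = numeric(),
             mean_intensity = numeric(), keep = logical()
           ),
           threshold = thr),
      class = "mito_components"
    ))
  }
  labels <- label_components(fg, connectivity = 26L)
  lab_vec <- labels[labels > 0L]
  size <- tabulate(lab_vec)
  mean_int <- as.numeric(tapply(v01[labels > 0L], lab_vec, mean))
  comp <- tibble::tibble(
    label = seq_along(size),
    size = as.integer(size),
    ln_size = log(size),
    mean_intensity = mean_int,
    keep = log(size) >= mito_ln_size & mean_int >= mito_min_intensity
  )
  structure(list(labels = labels, components = comp, threshold = thr),
            class = "mito_components")
}

#' @export
print.mito_components <- function(x, ...) {
  cat(sprintf("mito_components: %d components (%d kept), Otsu threshold %.4f\n",
              nrow(x$components), sum(x$components$keep), x$threshold))
  invisible(x)
}

#' Vesicle filter: drop contacts without a genuine mitochondrion partner
#'
#' A contact component survives only if at least one of its voxels lies within
#' `adjacency_voxels` 26-dilation steps of a kept mitochondria component.
#' Contacts adjacent only to below-threshold (vesicle-like) components, or to
#' no mitochondria component at all, are removed.
#'
#' @param contacts A `contact_set` from [label_contacts()].
#' @param mito A `mito_components` from [segment_mito_components()].
#' @param params A [detect_params()] (`adjacency_voxels`).
#' @return The filtered `contact_set` (labels of removed contacts zeroed,
#'   feature rows dropped).
#' @export
vesicle_filter <- function(contacts, mito, params = detect_params()) {
  stopifnot(inherits(contacts, "contact_set"),
            inherits(mito, "mito_components"))
  if (!identical(dim(contacts$labels), dim(mito$labels))) {
    stop("contacts and mitochondria labels must share the grid", call. = FALSE)
  }
  keep_ids <- mito$components$label[mito$components$keep]
  out <- contacts
  if (nrow(contacts$features) == 0L) return(out)
  kept_mask <- array(mito$labels %in% keep_ids, dim(mito$labels))
  reach <- if (params$adjacency_voxels > 0L) {
    dilate26(kept_mask, params$adjacency_voxels)
  } else kept_mask
  surviving <- sort(unique(contacts$labels[contacts$labels > 0L & reach]))
  out$labels[!(out$labels %in% surviving)] <- 0L
  out$features <- out$features[out$features$label %in% surviving, , drop = FALSE]
  out
}
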