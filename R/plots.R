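#' Size-intensity scatter of mitochondria components
#'
#' ln(size) against mean rescaled intensity for every mitochondria-channel
#' component, with the keep thresholds drawn; the classic view separating
#' genuine mitochondria from small dim vesicle-like objects.
#'
#' @param mito A `mito_components`.
#' @param mito_ln_size,mito_min_intensity Thresholds to draw.
#' @return A ggplot object.
#' @importFrom ggplot2 .data
#' @export
plot_mito_components <- function(mito, mito_ln_size = 9,
                                 mito_min_intensity = 0.2) {
  stopifnot(inherits(mito, "mito_components"))
  df <- as.data.frame(mito$components)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ln_size,
                                   y = .data$mean_intensity,
                                   colour = .data$keep)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = mito_ln_size, linetype = 2) +
    ggplot2::geom_hline(yintercept = mito_min_intensity, linetype = 2) +
    ggplot2::labs(x = "ln size (voxels)", y = "mean intensity (rescaled)",
                  colour = "kept") +
    ggplot2::theme_minimal()
}

#' Plot one z-slice of a response or channel
#'
#' @param v 3D array (or `response_map`, whose magnitude is shown).
#' @param z Slice index (default: middle slice).
#' @return A ggplot object (raster heat map).
#' @export
plot_slice <- function(v, z = NULL) {
  if (inherits(v, "response_map")) v <- v$magnitude
  assert_volume(v)
  if (is.null(z)) z <- ceiling(dim(v)[3] / 2)
  sl <- v[, , z]
  df <- expand.grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("z = %d", z), fill = "value") +
    ggplot2::theme_minimal()
}
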