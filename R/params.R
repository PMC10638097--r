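#' Detection parameters
#'
#' Bundles every tunable of the contact-detection pipeline. The defaults are
#' the values used throughout: a window half-width of 2 voxels (so each
#' correlation window holds \eqn{(2w+1)^3 = 125} voxels, spanning roughly
#' 350 nm at 25 x 25 x 100 nm voxels), significance level 0.05 with
#' statistical power 0.95, a bleed-through z-score of 3, a 25 x 25 x 5
#' quantification cube (`quant_k = 5`), removal of contacts of 2 voxels or
#' fewer, and the mitochondria/vesicle filter thresholds of 9 (ln voxels) and
#' 0.2 (mean of the min-max rescaled mitochondria channel).
#'
#' @param w Window half-width in voxels; the correlation window is a
#'   `(2*w+1)^3` cube.
#' @param alpha Two-sided significance level for the per-voxel correlation
#'   test.
#' @param power Statistical power (1 - beta) used for the minimum observable
#'   correlation. The default 0.95 reads the "0.05" power setting as
#'   beta = 0.05; set `power = 0.05` for the literal reading.
#' @param z_filter Bleed-through filter threshold: response voxels must have
#'   intensity z-score >= `z_filter` in both channels.
#' @param quant_k Quantification cube parameter k; sampling cubes are
#'   `5k x 5k x k` voxels (lateral, lateral, axial), a physical cube under the
#'   default 4:1 axial anisotropy.
#' @param min_contact_voxels Minimum surviving contact volume in voxels;
#'   smaller components are below the diffraction limit and removed.
#' @param mito_ln_size Mitochondria filter: minimum ln(component size in
#'   voxels) for a component to count as a genuine mitochondrion.
#' @param mito_min_intensity Mitochondria filter: minimum mean intensity of a
#'   component on the `[0,1]`-rescaled mitochondria channel.
#' @param large_contact_voxels Cutoff (voxels) above which a contact is
#'   counted as "large" in cell summaries.
#' @param adjacency_voxels Radius (in 26-neighbourhood dilation steps) used to
#'   associate contacts with mitochondria components and surface voxels with
#'   contacts.
#' @param variance_correction Use the Spearman-specific standard error
#'   `sqrt(1.06/(n-3))` in the Fisher z test (default); `FALSE` uses the plain
#'   `sqrt(1/(n-3))`.
#' @param physical_units Compute differential operators with per-axis physical
#'   spacing instead of unit voxel spacing (default `FALSE`; rank correlations
#'   compare the two channels with identical stencils either way).
#' @param presmooth_sigma Optional isotropic Gaussian pre-smoothing sigma in
#'   voxels applied to both channels before the differential operators;
#'   0 (default) disables it.
#' @param seed Integer seed for any stochastic step (phantom noise).
#'
#' @return An object of class `detect_params` (a named list).
#' @examples
#' p <- detect_params()
#' (2 * p$w + 1)^3 # 125 voxels per window
#' @export
detect_params <- function(w = 2L,
                          alpha = 0.05,
                          power = 0.95,
                          z_filter = 3,
                          quant_k = 5L,
                          min_contact_voxels = 3L,
                          mito_ln_size = 9,
                          mito_min_intensity = 0.2,
                          large_contact_voxels = 500,
                          adjacency_voxels = 1L,
                          variance_correction = TRUE,
                          physical_units = FALSE,
                          presmooth_sigma = 0,
                          seed = 1L) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("`w` must be an integer >= 1", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (!(power > 0 && power < 1)) stop("`power` must lie in (0, 1)", call. = FALSE)
  if (z_filter < 0) stop("`z_filter` must be >= 0", call. = FALSE)
  quant_k <- as.integer(quant_k)
  if (is.na(quant_k) || quant_k < 1L) stop("`quant_k` must be >= 1", call. = FALSE)
  min_contact_voxels <- as.integer(min_contact_voxels)
  if (is.na(min_contact_voxels) || min_contact_voxels < 1L) {
    stop("`min_contact_voxels` must be >= 1", call. = FALSE)
  }
  adjacency_voxels <- as.integer(adjacency_voxels)
  if (is.na(adjacency_voxels) || adjacency_voxels < 0L) {
    stop("`adjacency_voxels` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      w = w, alpha = alpha, power = power, z_filter = z_filter,
      quant_k = quant_k, min_contact_voxels = min_contact_voxels,
      mito_ln_size = mito_ln_size, mito_min_intensity = mito_min_intensity,
      large_contact_voxels = large_contact_voxels,
      adjacency_voxels = adjacency_voxels,
      variance_correction = isTRUE(variance_correction),
      physical_units = isTRUE(physical_units),
      presmooth_sigma = presmooth_sigma,
      seed = as.integer(seed)
    ),
    class = "detect_params"
  )
}

#' @export
print.detect_params <- function(x, ...) {
  cat("Contact detection parameters\n")
  cat(sprintf("  window half-width w: %d  (%d voxels/window)\n",
              x$w, (2L * x$w + 1L)^3))
  cat(sprintf("  alpha: %g   power: %g\n", x$alpha, x$power))
  cat(sprintf("  bleed-through z: %g\n", x$z_filter))
  cat(sprintf("  quantification k: %d  (cube %d x %d x %d voxels)\n",
              x$quant_k, 5L * x$quant_k, 5L * x$quant_k, x$quant_k))
  cat(sprintf("  min contact voxels: %d   large-contact cutoff: %g\n",
              x$min_contact_voxels, x$large_contact_voxels))
  cat(sprintf("  mito filter: ln-size >= %g, mean intensity >= %g\n",
              x$mito_ln_size, x$mito_min_intensity))
  invisible(x)
}
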