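#' Two-sided significance of a Spearman correlation
#'
#' Fisher z-transform test: `z = atanh(rho) * sqrt((n - 3) / 1.06)`,
#' `p = 2 * (1 - pnorm(|z|))`. The 1.06 factor is the standard variance
#' correction for the Spearman coefficient; `variance_correction = FALSE`
#' uses the plain `sqrt(n - 3)` scaling. `|rho|` is clamped to `1 - 1e-12`
#' before the transform.
#'
#' @param rho Correlation value(s) in `[-1, 1]` (vectorized).
#' @param n Window sample count (>= 4).
#' @param variance_correction Use the 1.06 Spearman variance correction.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
spearman_significance <- function(rho, n, variance_correction = TRUE) {
  if (n < 4) stop("`n` must be >= 4", call. = FALSE)
  if (any(abs(rho) > 1)) stop("`rho` must lie in [-1, 1]", call. = FALSE)
  r <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  denom <- if (variance_correction) 1.06 else 1
  z <- atanh(r) * sqrt((n - 3) / denom)
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Minimum observable correlation for a window size
#'
#' The smallest `|rho|` detectable at two-sided level `alpha` with the stated
#' power under the Fisher-z approximation:
#' `rho_min = tanh((z_{1-alpha/2} + z_power) * sqrt(1.06 / (n - 3)))`.
#' Larger windows can detect fainter responses; as `alpha` tends to 0 the
#' minimum observable correlation tends to 1 and no voxel can be retained.
#'
#' @param n Window sample count (>= 4).
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Statistical power in (0, 1).
#' @param variance_correction Use the 1.06 Spearman variance correction.
#' @return Scalar `rho_min` in `[0, 1)`.
#' @examples
#' min_detectable_rho(125, 0.05, 0.95) # about 0.32
#' @export
min_detectable_rho <- function(n, alpha = 0.05, power = 0.95,
                               variance_correction = TRUE) {
  if (n < 4) stop("`n` must be >= 4", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (!(power > 0 && power < 1)) stop("`power` must lie in (0, 1)", call. = FALSE)
  num <- if (variance_correction) 1.06 else 1
  za <- stats::qnorm(alpha / 2, lower.tail = FALSE)
  zb <- stats::qnorm(1 - power, lower.tail = FALSE)
  tanh((za + zb) * sqrt(num / (n - 3)))
}

#' Apply the confidence map to a response
#'
#' Pure masking stage: zeroes the response magnitude wherever the two-sided
#' p-value of `rho_lap` exceeds `alpha` or `|rho_lap|` falls below the
#' minimum observable correlation for the window size. All other voxels are
#' unchanged.
#'
#' @param resp A `response_map` from [contact_response()].
#' @param params A [detect_params()] (`alpha`, `power`, `variance_correction`).
#' @return The `response_map` with filtered `magnitude`, plus elements
#'   `p_value` (per-voxel, on the previous support) and `rho_min`.
#' @export
apply_confidence <- function(resp, params = resp$params) {
  stopifnot(inherits(resp, "response_map"))
  n <- resp$n_window
  rho_min <- min_detectable_rho(n, params$alpha, params$power,
                                params$variance_correction)
  sup <- resp$magnitude > 0
  p <- array(1, dim(resp$magnitude))
  p[sup] <- spearman_significance(resp$rho_lap[sup], n,
                                  params$variance_correction)
  keep <- sup & p <= params$alpha & abs(resp$rho_lap) >= rho_min
  out <- resp
  out$magnitude[!keep] <- 0
  out$p_value <- p
  out$rho_min <- rho_min
  out
}
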