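#' Phantom specification
#'
#' Describes a synthetic two-channel volume. Two kinds are provided:
#'
#' * `"two_object"`: one sphere per channel, separated edge-to-edge by
#'   `separation_nm` along `axis`, imaged with an anisotropic Gaussian PSF.
#'   This is the in-silico demonstration of the detection principle: the
#'   interface between two sub-resolution objects carries a negative windowed
#'   Spearman correlation of the channels' negative Laplacians across the
#'   whole sub-precision separation range.
#' * `"cell"`: a whole-volume phantom with an ER-like tubular channel and a
#'   mitochondria-like ellipsoid channel, designated sub-resolution contact
#'   interfaces, and optional small dim "vesicle" decoys in the mitochondria
#'   channel that generate false contacts for the vesicle filter to remove.
#'
#' Defaults mirror the acquisition regime the pipeline targets: 25 x 25 x 100
#' nm voxels and a Gaussian PSF with 120 nm lateral / 250 nm axial FWHM.
#' Sphere radius defaults to 400 nm: organelle-scale objects, large relative
#' to both the correlation window and the interface width -- the regime in
#' which the differential correlation principle operates (when object size
#' shrinks toward the window/interface scale, the shared radial structure of
#' the two blobs inside one window dominates the opposed edge profiles and
#' the response degrades, a documented limitation). The cell phantom adds a
#' uniform dim haze floor (`haze = 0.02`) plus a small Gaussian read noise
#' (`0.002`): deconvolved super-resolution stacks are near-noiseless over a
#' dim residual background, and that background is what makes the pivotal
#' z-score of the bleed-through filter meaningful. Mitochondria ellipsoids
#' (semi-axes 300 x 800 x 600 nm, about 9,600 voxels) sit above the
#' ln-size-9 (~8,103 voxels) filter threshold by construction; vesicles
#' (60 nm radius, intensity scale 0.1) sit below both thresholds by
#' construction. Designated contacts use a 20 nm edge-to-edge gap, a typical
#' membrane-contact cleft.
#'
#' @param kind `"two_object"` or `"cell"`.
#' @param shape Grid size in voxels `(y, x, z)`.
#' @param spacing Voxel spacing in nm `(y, x, z)`.
#' @param psf_fwhm Gaussian PSF full width at half maximum in nm `(y, x, z)`;
#'   zeros disable blurring along that axis.
#' @param haze Uniform dim background level added to both channels before
#'   noise (intensity units; default 0.02 for the cell phantom, 0 for the
#'   two-object demonstration).
#' @param noise_gaussian Additive Gaussian noise sigma (intensity units;
#'   default 0.002 for the cell phantom, 0 for the two-object demonstration).
#' @param noise_smooth_fwhm Correlation length (FWHM, nm per axis) of the
#'   Gaussian noise. Deconvolution leaves residual noise that is smooth at
#'   roughly half the system PSF, not white per-voxel noise; default
#'   `psf_fwhm / 2`. Set to `c(0, 0, 0)` for white noise.
#' @param noise_poisson Poisson scaling (expected counts per unit intensity);
#'   0 disables shot noise.
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @param resolution_nm System resolution used by the ground-truth rule: the
#'   two-object contact mask is empty when `separation_nm` exceeds it.
#' @param separation_nm Two-object: edge-to-edge gap between the spheres.
#' @param axis Two-object: separation axis, `"x"`, `"y"` or `"z"`.
#' @param radius_nm Two-object: sphere radius.
#' @param intensity Two-object: per-channel peak intensity `c(a, b)`.
#' @param n_vesicles Cell: number of vesicle decoys (0..5).
#' @param vesicle_radius_nm,vesicle_intensity Cell: vesicle geometry/intensity
#'   (relative to the mitochondria channel maximum).
#' @param contact_gap_nm Cell: edge-to-edge gap at designated contacts.
#' @param tube_radius_nm Cell: ER tubule radius.
#' @param gt_margin_voxels Ground-truth margin: contact-mask voxels lie within
#'   this many 26-dilation steps of both true surfaces (1 voxel, mirroring the
#'   two-object rule "gap voxels within one lateral voxel of both surfaces").
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("two_object", "cell"),
                         shape = if (match.arg(kind) == "cell")
                           c(192L, 192L, 64L) else c(128L, 128L, 64L),
                         spacing = c(25, 25, 100),
                         psf_fwhm = c(120, 120, 250),
                         haze = if (match.arg(kind) == "cell") 0.02 else 0,
                         noise_gaussian = if (match.arg(kind) == "cell")
                           0.002 else 0,
                         noise_smooth_fwhm = psf_fwhm / 2,
                         noise_poisson = 0,
                         seed = 1L,
                         resolution_nm = 120,
                         separation_nm = 0,
                         axis = "x",
                         radius_nm = 400,
                         intensity = c(1, 1),
                         n_vesicles = 5L,
                         vesicle_radius_nm = 60,
                         vesicle_intensity = 0.1,
                         contact_gap_nm = 20,
                         tube_radius_nm = 100,
                         gt_margin_voxels = 1L) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  psf_fwhm <- as.numeric(psf_fwhm)
  stopifnot(length(psf_fwhm) == 3L, all(psf_fwhm >= 0))
  if (noise_gaussian < 0 || noise_poisson < 0 || haze < 0) {
    stop("noise and haze parameters must be >= 0", call. = FALSE)
  }
  if (separation_nm < 0) stop("`separation_nm` must be >= 0", call. = FALSE)
  if (!axis %in% c("y", "x", "z")) stop("`axis` must be y, x or z", call. = FALSE)
  structure(
    list(
      kind = kind, shape = shape, spacing = spacing, psf_fwhm = psf_fwhm,
      haze = haze,
      noise_gaussian = noise_gaussian,
      noise_smooth_fwhm = as.numeric(noise_smooth_fwhm),
      noise_poisson = noise_poisson,
      seed = as.integer(seed), resolution_nm = resolution_nm,
      separation_nm = separation_nm, axis = axis, radius_nm = radius_nm,
      intensity = intensity, n_vesicles = as.integer(n_vesicles),
      vesicle_radius_nm = vesicle_radius_nm,
      vesicle_intensity = vesicle_intensity,
      contact_gap_nm = contact_gap_nm, tube_radius_nm = tube_radius_nm,
      gt_margin_voxels = as.integer(gt_margin_voxels)
    ),
    class = "phantom_spec"
  )
}

# Physical coordinates (nm) of voxel centres along each axis.
axis_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

# Squared scaled distance field ((p-c)/semi)^2 summed over axes, as a 3D array.
scaled_dist2 <- function(coords, center, semi) {
  dy2 <- ((coords[[1]] - center[1]) / semi[1])^2
  dx2 <- ((coords[[2]] - center[2]) / semi[2])^2
  dz2 <- ((coords[[3]] - center[3]) / semi[3])^2
  outer(outer(dy2, dx2, "+"), dz2, "+")
}

ellipsoid_mask <- function(shape, spacing, center, semi) {
  co <- axis_coords(shape, spacing)
  extent <- (shape - 1) * spacing
  if (any(center - semi < 0) || any(center + semi > extent)) {
    stop(sprintf("object at (%s) nm with semi-axes (%s) nm exceeds grid bounds",
                 paste(center, collapse = ","), paste(semi, collapse = ",")),
         call. = FALSE)
  }
  scaled_dist2(co, center, semi) <= 1
}

# Tube of circular cross-section running the full x extent.
tube_mask_x <- function(shape, spacing, cy, cz, radius) {
  co <- axis_coords(shape, spacing)
  dy2 <- ((co[[1]] - cy) / radius)^2
  dz2 <- ((co[[3]] - cz) / radius)^2
  sec <- outer(dy2, rep(0, shape[2]), "+") # (y, x) with x contributing 0
  arr <- outer(sec, dz2, "+")
  arr <- arr + 0 # (y, x, z)
  arr <= 1
}

# Separable anisotropic Gaussian blur; sigma given in nm per axis.
gaussian_blur <- function(v, sigma_nm, spacing) {
  d <- dim(v)
  out <- as.numeric(v)
  for (a in 1:3) {
    sig_vox <- sigma_nm[a] / spacing[a]
    if (sig_vox < 1e-8) next
    r <- max(1L, ceiling(4 * sig_vox))
    kern <- stats::dnorm(seq(-r, r), sd = sig_vox)
    kern <- kern / sum(kern)
    out <- cpp_convolve_axis(out, as.integer(d), kern, a)
  }
  array(out, d)
}

#' Add seeded noise to an intensity volume
#'
#' Applies Poisson shot noise (if `poisson_scale > 0`, the volume is treated
#' as expected counts per `1/poisson_scale` intensity units) followed by
#' additive Gaussian noise, then clips at zero.
#'
#' @param v 3D intensity array.
#' @param gaussian_sigma Gaussian noise standard deviation (>= 0), the
#'   marginal per-voxel sd whether or not the noise is smoothed.
#' @param poisson_scale Poisson scaling (>= 0; 0 disables).
#' @param seed RNG seed.
#' @param smooth_fwhm Per-axis FWHM (nm) of the Gaussian noise correlation;
#'   `c(0, 0, 0)` (default) gives white noise.
#' @param spacing Voxel spacing (nm), used only to convert `smooth_fwhm`.
#' @return Noisy volume, same shape, clipped at 0.
#' @export
add_noise <- function(v, gaussian_sigma = 0, poisson_scale = 0, seed = 1L,
                      smooth_fwhm = c(0, 0, 0), spacing = c(25, 25, 100)) {
  if (gaussian_sigma < 0 || poisson_scale < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (gaussian_sigma == 0 && poisson_scale == 0) return(v)
  d <- dim(v)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- as.numeric(v)
  if (poisson_scale > 0) {
    out <- stats::rpois(length(out), out * poisson_scale) / poisson_scale
  }
  if (gaussian_sigma > 0) {
    g <- array(stats::rnorm(length(out)), d)
    if (any(smooth_fwhm > 0)) {
      g <- gaussian_blur(g, smooth_fwhm / (2 * sqrt(2 * log(2))), spacing)
      g <- g / stats::sd(g)
    }
    out <- out + gaussian_sigma * as.numeric(g)
  }
  out[out < 0] <- 0
  array(out, d)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Two-sphere phantom with ground-truth interface
#'
#' One sphere per channel, separated edge-to-edge by `spec$separation_nm`
#' along `spec$axis`, convolved with the anisotropic Gaussian PSF and
#' optionally degraded by noise. The ground-truth contact mask marks the
#' inter-object gap voxels lying within `separation/2 + one lateral voxel` of
#' both sphere surfaces; it is empty when the separation exceeds
#' `spec$resolution_nm`.
#'
#' @param spec A [phantom_spec()] with `kind = "two_object"`.
#' @return A list with elements `pair` (a [volume_pair()]) and `truth`
#'   (list with `contact_mask`, `labels_a`, `labels_b`, `solid_a`, `solid_b`).
#' @export
two_object_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind == "two_object")
  shape <- spec$shape; spacing <- spec$spacing
  extent <- (shape - 1) * spacing
  ax <- match(spec$axis, c("y", "x", "z"))
  center <- round(extent / 2 / spacing) * spacing # snap to a voxel centre
  off <- spec$separation_nm / 2 + spec$radius_nm
  ca <- center; ca[ax] <- center[ax] - off
  cb <- center; cb[ax] <- center[ax] + off
  semi <- rep(spec$radius_nm, 3)
  solid_a <- ellipsoid_mask(shape, spacing, ca, semi)
  solid_b <- ellipsoid_mask(shape, spacing, cb, semi)
  sigma <- spec$psf_fwhm / (2 * sqrt(2 * log(2)))
  a <- gaussian_blur(array(as.numeric(solid_a) * spec$intensity[1], shape),
                     sigma, spacing) + spec$haze
  b <- gaussian_blur(array(as.numeric(solid_b) * spec$intensity[2], shape),
                     sigma, spacing) + spec$haze
  a <- add_noise(a, spec$noise_gaussian, spec$noise_poisson, spec$seed,
                 smooth_fwhm = spec$noise_smooth_fwhm, spacing = spacing)
  b <- add_noise(b, spec$noise_gaussian, spec$noise_poisson, spec$seed + 1L,
                 smooth_fwhm = spec$noise_smooth_fwhm, spacing = spacing)
  co <- axis_coords(shape, spacing)
  da <- sqrt(scaled_dist2(co, ca, c(1, 1, 1))) - spec$radius_nm
  db <- sqrt(scaled_dist2(co, cb, c(1, 1, 1))) - spec$radius_nm
  margin <- spec$separation_nm / 2 + min(spacing[1:2])
  contact <- da >= 0 & db >= 0 & da <= margin & db <= margin
  if (spec$separation_nm > spec$resolution_nm) {
    contact <- array(FALSE, shape)
  }
  list(
    pair = volume_pair(a, b, spacing),
    truth = list(
      contact_mask = contact,
      labels_a = array(as.integer(solid_a), shape),
      labels_b = array(as.integer(solid_b), shape),
      solid_a = solid_a, solid_b = solid_b
    )
  )
}

# Fixed layout of the cell phantom, in nm, for the default 192 x 192 x 64 grid
# (extent 4775 x 4775 x 6300 nm); positions scale proportionally to other grid
# extents while object sizes and contact gaps stay fixed.
cell_layout <- function(extent, spec) {
  s <- extent / c(4775, 4775, 6300)
  mito_semi <- c(300, 800, 600)
  tube_r <- spec$tube_radius_nm
  gap <- spec$contact_gap_nm
  vr <- spec$vesicle_radius_nm
  y1 <- 1200 * s[1]  # m1 centre (contact with tube1 at its upper y apex)
  y2 <- 2900 * s[1]  # m2 centre (contact with tube2)
  t1 <- y1 + mito_semi[1] + gap + tube_r
  t2 <- y2 + mito_semi[1] + gap + tube_r
  list(
    mito = list(
      m1 = list(center = c(y1, 2400 * s[2], 3200 * s[3]), semi = mito_semi),
      m2 = list(center = c(y2, 2400 * s[2], 3200 * s[3]), semi = mito_semi),
      m3 = list(center = c(2400 * s[1], 2400 * s[2], 1300 * s[3]),
                semi = mito_semi)
    ),
    tubes = list(
      t1 = list(cy = t1, cz = 3200 * s[3]),
      t2 = list(cy = t2, cz = 3200 * s[3])
    ),
    # vesicle decoys graze a tubule (gap `gap`) far from the true contacts
    vesicles = list(
      v1 = c(t1 + tube_r + gap + vr, 500 * s[2], 3200 * s[3]),
      v2 = c(t1 + tube_r + gap + vr, 4200 * s[2], 3200 * s[3]),
      v3 = c(t2 + tube_r + gap + vr, 500 * s[2], 3200 * s[3]),
      v4 = c(t2 + tube_r + gap + vr, 4200 * s[2], 3200 * s[3]),
      v5 = c(t1 - tube_r - gap - vr, 500 * s[2], 3200 * s[3])
    )
  )
}

#' Whole-volume cell phantom with ground truth
#'
#' Builds an ER-like channel (two tubules crossing the volume), a
#' mitochondria-like channel (three large ellipsoids, two of which graze a
#' tubule at a sub-resolution gap, forming the designated contacts) and
#' `n_vesicles` small dim vesicle decoys touching the tubules away from the
#' true contacts. Channels are blurred with the Gaussian PSF and noised.
#'
#' Ground truth: `contact_mask` marks voxels within `gt_margin_voxels`
#' 26-dilation steps of both a tubule surface and a genuine (non-vesicle)
#' mitochondrion surface, outside all solids; with two designated contacts it
#' has exactly two connected components. `mito_table` lists every
#' mitochondria-channel object with its true voxel size and intensity scale.
#'
#' @param spec A [phantom_spec()] with `kind = "cell"`.
#' @return List with `pair` (a [volume_pair()]) and `truth` (list with
#'   `contact_mask`, `mito_labels`, `er_mask`, `mito_table`).
#' @export
cell_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind == "cell")
  shape <- spec$shape; spacing <- spec$spacing
  extent <- (shape - 1) * spacing
  lay <- cell_layout(extent, spec)

  mito_solids <- lapply(lay$mito, function(m)
    ellipsoid_mask(shape, spacing, m$center, m$semi))
  tube_solids <- lapply(lay$tubes, function(t)
    tube_mask_x(shape, spacing, t$cy, t$cz, spec$tube_radius_nm))
  ves_centers <- lay$vesicles[seq_len(min(spec$n_vesicles, 5L))]
  ves_solids <- lapply(ves_centers, function(c0)
    ellipsoid_mask(shape, spacing, c0, rep(spec$vesicle_radius_nm, 3)))

  er_solid <- Reduce(`|`, tube_solids)
  mito_true <- Reduce(`|`, mito_solids)
  ves_solid <- if (length(ves_solids)) Reduce(`|`, ves_solids) else
    array(FALSE, shape)
  if (any(er_solid & (mito_true | ves_solid))) {
    stop("infeasible geometry: ER and mitochondria solids overlap",
         call. = FALSE)
  }

  mito_field <- array(0, shape)
  mito_field[mito_true] <- 1
  mito_field[ves_solid] <- spec$vesicle_intensity
  er_field <- array(0, shape)
  er_field[er_solid] <- 1

  sigma <- spec$psf_fwhm / (2 * sqrt(2 * log(2)))
  a <- gaussian_blur(er_field, sigma, spacing) + spec$haze
  b <- gaussian_blur(mito_field, sigma, spacing) + spec$haze
  a <- add_noise(a, spec$noise_gaussian, spec$noise_poisson, spec$seed,
                 smooth_fwhm = spec$noise_smooth_fwhm, spacing = spacing)
  b <- add_noise(b, spec$noise_gaussian, spec$noise_poisson, spec$seed + 1L,
                 smooth_fwhm = spec$noise_smooth_fwhm, spacing = spacing)

  m <- spec$gt_margin_voxels
  contact <- dilate26(er_solid, m) & dilate26(mito_true, m) &
    !er_solid & !mito_true & !ves_solid

  mito_labels <- array(0L, shape)
  tab <- list()
  lab <- 0L
  for (nm in names(mito_solids)) {
    lab <- lab + 1L
    mito_labels[mito_solids[[nm]]] <- lab
    tab[[length(tab) + 1L]] <- tibble::tibble(
      label = lab, object = nm, size_voxels = sum(mito_solids[[nm]]),
      intensity_scale = 1, is_vesicle = FALSE
    )
  }
  for (nm in names(ves_solids)) {
    lab <- lab + 1L
    mito_labels[ves_solids[[nm]]] <- lab
    tab[[length(tab) + 1L]] <- tibble::tibble(
      label = lab, object = nm, size_voxels = sum(ves_solids[[nm]]),
      intensity_scale = spec$vesicle_intensity, is_vesicle = TRUE
    )
  }

  list(
    pair = volume_pair(a, b, spacing),
    truth = list(
      contact_mask = contact,
      mito_labels = mito_labels,
      er_mask = er_solid,
      mito_table = do.call(rbind, tab)
    )
  )
}
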