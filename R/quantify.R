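#' Label contact components
#'
#' 26-connected components of the positive-magnitude support of a filtered
#' response. Components of fewer than `min_contact_voxels` voxels are below
#' the diffraction limit and removed (default 3, i.e. contacts of 2 voxels or
#' fewer are dropped).
#'
#' @param magnitude 3D response-magnitude array (or a `response_map`).
#' @param min_contact_voxels Minimum surviving component volume.
#' @return Object of class `contact_set`: list with `labels` (integer 3D
#'   array, background 0) and `features` (tibble with `label`, `volume`).
#' @export
label_contacts <- function(magnitude, min_contact_voxels = 3L) {
  if (inherits(magnitude, "response_map")) magnitude <- magnitude$magnitude
  assert_volume(magnitude, "magnitude")
  labels <- label_components(magnitude > 0, connectivity = 26L)
  n <- max(labels)
  if (n > 0L) {
    size <- tabulate(labels[labels > 0L], nbins = n)
    drop <- which(size < min_contact_voxels)
    if (length(drop)) labels[array(labels %in% drop, dim(labels))] <- 0L
    keep <- which(size >= min_contact_voxels)
    # relabel 1..k in original order
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    feats <- tibble::tibble(label = seq_along(keep),
                            volume = as.integer(size[keep]))
  } else {
    feats <- tibble::tibble(label = integer(), volume = integer())
  }
  structure(list(labels = labels, features = feats), class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set: %d contacts, %d voxels total\n",
              nrow(x$features), sum(x$labels > 0L)))
  invisible(x)
}

#' Per-contact morphometric features
#'
#' For each contact: the geometric mean of the per-voxel response magnitude,
#' the centroid, the eigenvalues (in nm^2) of the response-weighted covariance
#' of the voxel physical coordinates, and the eigenvalue shape decomposition
#'
#' * `anisotropy = (l1 - l2) / l1` (linear),
#' * `planarity  = (l2 - l3) / l1` (planar),
#' * `sphericity = l3 / l1` (spherical),
#'
#' which sum to 1 for every contact. `height_nm` is the physical axial extent
#' `(max z - min z + 1 voxel) * spacing_z`; `height_mode = "eigen"` uses
#' `2 * sqrt(l1)` instead.
#'
#' @param contacts A `contact_set`.
#' @param magnitude Response-magnitude array (or `response_map`) supplying the
#'   per-voxel weights.
#' @param spacing Voxel spacing `c(y, x, z)` in nm.
#' @param height_mode `"extent"` (default) or `"eigen"`.
#' @return Tibble with one row per contact: label, volume, gm_spearman,
#'   centroid, lambda1..3, sphericity, planarity, anisotropy, height_nm.
#' @export
contact_features <- function(contacts, magnitude, spacing = c(25, 25, 100),
                             height_mode = c("extent", "eigen")) {
  stopifnot(inherits(contacts, "contact_set"))
  if (inherits(magnitude, "response_map")) magnitude <- magnitude$magnitude
  height_mode <- match.arg(height_mode)
  labs <- contacts$features$label
  n <- length(labs)
  cols <- c("gm_spearman", "centroid_y", "centroid_x", "centroid_z",
            "lambda1", "lambda2", "lambda3",
            "sphericity", "planarity", "anisotropy", "height_nm")
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  if (n > 0L) {
    vox <- which(contacts$labels > 0L, arr.ind = TRUE)
    lab_vec <- contacts$labels[contacts$labels > 0L]
    wts <- magnitude[contacts$labels > 0L]
    for (i in seq_len(n)) {
      sel <- lab_vec == labs[i]
      xyz <- vox[sel, , drop = FALSE]
      coords <- sweep(xyz - 1, 2, spacing, "*") # physical nm
      w <- wts[sel]
      if (all(w <= 0)) w <- rep(1, length(w))
      wn <- w / sum(w)
      mu <- colSums(coords * wn)
      cc <- sweep(coords, 2, mu)
      cov <- t(cc * wn) %*% cc
      ev <- sort(pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, 0),
                 decreasing = TRUE)
      l1 <- ev[1]; l2 <- ev[2]; l3 <- ev[3]
      if (l1 <= 0) { sph <- 0; pla <- 0; ani <- 1 } else {
        sph <- l3 / l1; pla <- (l2 - l3) / l1; ani <- (l1 - l2) / l1
      }
      hz <- if (height_mode == "extent") {
        (diff(range(xyz[, 3])) + 1) * spacing[3]
      } else 2 * sqrt(l1)
      gm <- exp(mean(log(pmax(w, .Machine$double.xmin))))
      out[i, ] <- c(gm, mu[1], mu[2], mu[3], l1, l2, l3, sph, pla, ani, hz)
    }
  }
  cbind(contacts$features, tibble::as_tibble(as.data.frame(out)))
}

#' Sliding-window coverage and contact-count statistics
#'
#' Tiles the volume with non-overlapping `5k x 5k x k` cubes (lateral,
#' lateral, axial voxels -- a physical cube under 4:1 axial anisotropy). The
#' mitochondrial surface is the set of boundary voxels (26-neighbourhood) of
#' kept mitochondria components; a surface voxel is covered when it lies
#' within `adjacency_voxels` dilation steps of a contact voxel. Per cube the
#' coverage ratio and the number of distinct contact labels intersecting the
#' cube's surface shell are recorded; cubes with no surface voxels are
#' excluded from aggregation.
#'
#' @param contacts A `contact_set`.
#' @param mito A `mito_components`.
#' @param quant_k Cube parameter k (axial edge; lateral edge is `5k`).
#' @param adjacency_voxels Contact-to-surface association radius.
#' @return Tibble: cube indices, `mito_surface_voxels`,
#'   `covered_surface_voxels`, `coverage_ratio`, `n_contacts`.
#' @export
sliding_window_stats <- function(contacts, mito, quant_k = 5L,
                                 adjacency_voxels = 1L) {
  stopifnot(inherits(contacts, "contact_set"),
            inherits(mito, "mito_components"))
  d <- dim(mito$labels)
  keep_ids <- mito$components$label[mito$components$keep]
  if (length(keep_ids) == 0L) {
    warning("no kept mitochondria components; window table is empty")
    return(tibble::tibble(
      cube_y = integer(), cube_x = integer(), cube_z = integer(),
      mito_surface_voxels = integer(), covered_surface_voxels = integer(),
      coverage_ratio = numeric(), n_contacts = integer()
    ))
  }
  kept <- array(mito$labels %in% keep_ids, d)
  interior <- kept & !dilate26(!kept, 1L)
  surface <- kept & !interior
  contact_mask <- contacts$labels > 0L
  near_contact <- if (adjacency_voxels > 0L && any(contact_mask)) {
    dilate26(contact_mask, adjacency_voxels)
  } else contact_mask
  covered <- surface & near_contact
  shell <- if (adjacency_voxels > 0L) dilate26(surface, adjacency_voxels) else
    surface

  side <- c(5L, 5L, 1L) * as.integer(quant_k)
  nb <- pmax(1L, ceiling(d / side))
  rows <- list()
  for (kz in seq_len(nb[3])) {
    zr <- (((kz - 1L) * side[3] + 1L):min(kz * side[3], d[3]))
    for (kx in seq_len(nb[2])) {
      xr <- (((kx - 1L) * side[2] + 1L):min(kx * side[2], d[2]))
      for (ky in seq_len(nb[1])) {
        yr <- (((ky - 1L) * side[1] + 1L):min(ky * side[1], d[1]))
        surf <- sum(surface[yr, xr, zr])
        if (surf == 0L) next
        cov <- sum(covered[yr, xr, zr])
        in_shell <- shell[yr, xr, zr] & contacts$labels[yr, xr, zr] > 0L
        nlab <- length(unique(contacts$labels[yr, xr, zr][in_shell]))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cube_y = ky, cube_x = kx, cube_z = kz,
          mito_surface_voxels = surf, covered_surface_voxels = cov,
          coverage_ratio = cov / surf, n_contacts = nlab
        )
      }
    }
  }
  if (length(rows) == 0L) {
    warning("no sampling cube contains mitochondrial surface")
    return(tibble::tibble(
      cube_y = integer(), cube_x = integer(), cube_z = integer(),
      mito_surface_voxels = integer(), covered_surface_voxels = integer(),
      coverage_ratio = numeric(), n_contacts = integer()
    ))
  }
  do.call(rbind, rows)
}

#' Large-contact (Q95) summary of a cell
#'
#' Q95 is the 95th quantile of per-contact volumes (linear interpolation
#' between order statistics, i.e. `stats::quantile` type 7). Contacts above
#' Q95 are the cell's "large contacts"; the count with volume strictly above
#' `large_contact_voxels` is also reported.
#'
#' @param contacts A `contact_set` (with feature table).
#' @param large_contact_voxels Large-contact cutoff in voxels (default 500).
#' @return List: `q95_volume`, `large_labels` (labels with volume > Q95),
#'   `mean_large_volume`, `count_above_cutoff`, `n_contacts`.
#' @export
q95_summary <- function(contacts, large_contact_voxels = 500) {
  stopifnot(inherits(contacts, "contact_set"))
  vols <- contacts$features$volume
  if (length(vols) == 0L) {
    return(list(q95_volume = 0, large_labels = integer(),
                mean_large_volume = 0, count_above_cutoff = 0L,
                n_contacts = 0L))
  }
  q95 <- as.numeric(stats::quantile(vols, 0.95, type = 7, names = FALSE))
  large <- contacts$features$label[vols > q95]
  list(
    q95_volume = q95,
    large_labels = large,
    mean_large_volume = if (length(large)) mean(vols[vols > q95]) else q95,
    count_above_cutoff = sum(vols > large_contact_voxels),
    n_contacts = length(vols)
  )
}

#' Compare two groups of per-cell summaries
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature on per-cell
#' values. Statistics are always computed on per-cell aggregates; no outlier
#' removal and no multiple-testing correction are applied.
#'
#' @param cells_a,cells_b Data frames (one row per cell) with a common set of
#'   numeric feature columns; at least 3 cells per group.
#' @param features Feature columns to compare; default: all shared numeric
#'   columns.
#' @return Tibble: feature, n_a, n_b, median_a, median_b, statistic (U),
#'   p_value.
#' @export
compare_groups <- function(cells_a, cells_b, features = NULL) {
  cells_a <- as.data.frame(cells_a)
  cells_b <- as.data.frame(cells_b)
  if (nrow(cells_a) < 3L || nrow(cells_b) < 3L) {
    stop("need at least 3 cells per group for a meaningful comparison",
         call. = FALSE)
  }
  if (is.null(features)) {
    shared <- intersect(names(cells_a), names(cells_b))
    features <- shared[vapply(shared, function(f)
      is.numeric(cells_a[[f]]) && is.numeric(cells_b[[f]]), logical(1))]
  }
  rows <- lapply(features, function(f) {
    wt <- suppressWarnings(
      stats::wilcox.test(cells_a[[f]], cells_b[[f]],
                         alternative = "two.sided", exact = NULL)
    )
    tibble::tibble(
      feature = f, n_a = nrow(cells_a), n_b = nrow(cells_b),
      median_a = stats::median(cells_a[[f]]),
      median_b = stats::median(cells_b[[f]]),
      statistic = unname(wt$statistic), p_value = wt$p.value
    )
  })
  do.call(rbind, rows)
}
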