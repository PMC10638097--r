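#' Run the full contact-detection pipeline on a volume pair
#'
#' Fixed stage order, each stage a pure mask on the response magnitude:
#'
#' 1. response: windowed Spearman of the negative Laplacians, gated by the
#'    intensity correlation ([contact_response()]);
#' 2. bleed-through: response restricted to voxels passing the z-score mask
#'    in both channels ([bleedthrough_mask()]);
#' 3. confidence: significance and minimum observable correlation
#'    ([apply_confidence()]);
#' 4. shadow: third-derivative consistency ([shadow_filter()]);
#' 5. labelling and minimum-size removal ([label_contacts()]);
#' 6. vesicle filter against mitochondria components ([vesicle_filter()]).
#'
#' Retained voxel counts are recorded after every stage and are monotone
#' non-increasing.
#'
#' @param pair A [volume_pair()].
#' @param params A [detect_params()].
#' @param quantify Compute per-contact features, window statistics and the
#'   cell summary (default `TRUE`).
#' @return Object of class `contact_result`: list with `response`
#'   (`response_map` after all masking), `contacts` (`contact_set` with
#'   feature table), `mito` (`mito_components`), `windows` (tibble),
#'   `cell_summary` (list), `manifest_counts` (named integer vector),
#'   `rho_min`, `params`, `spacing`.
#' @export
detect_contacts <- function(pair, params = detect_params(), quantify = TRUE) {
  stopifnot(inherits(pair, "volume_pair"), inherits(params, "detect_params"))
  counts <- integer()

  resp <- contact_response(pair, params)
  counts["response"] <- sum(resp$magnitude > 0)

  mask_a <- bleedthrough_mask(pair$channel_a, params$z_filter)
  mask_b <- bleedthrough_mask(pair$channel_b, params$z_filter)
  resp$magnitude[!(mask_a & mask_b)] <- 0
  counts["bleedthrough"] <- sum(resp$magnitude > 0)

  resp <- apply_confidence(resp, params)
  counts["confidence"] <- sum(resp$magnitude > 0)

  sp <- if (params$physical_units) pair$spacing else NULL
  d3_a <- third_derivative(pair$channel_a, spacing = sp)
  d3_b <- third_derivative(pair$channel_b, spacing = sp)
  resp <- shadow_filter(resp, d3_a, d3_b)
  counts["shadow"] <- sum(resp$magnitude > 0)

  contacts <- label_contacts(resp$magnitude, params$min_contact_voxels)
  counts["min_size"] <- sum(contacts$labels > 0L)

  mito <- segment_mito_components(pair$channel_b, params$mito_ln_size,
                                  params$mito_min_intensity)
  contacts <- vesicle_filter(contacts, mito, params)
  counts["vesicle"] <- sum(contacts$labels > 0L)

  # keep magnitude consistent with surviving contacts
  resp$magnitude[contacts$labels == 0L] <- 0

  windows <- NULL
  cell_summary <- NULL
  if (quantify) {
    contacts$features <- contact_features(contacts, resp, pair$spacing)
    windows <- sliding_window_stats(contacts, mito, params$quant_k,
                                    params$adjacency_voxels)
    q <- q95_summary(contacts, params$large_contact_voxels)
    cell_summary <- list(
      n_contacts = q$n_contacts,
      mean_volume = if (q$n_contacts) mean(contacts$features$volume) else 0,
      q95_volume = q$q95_volume,
      count_above_cutoff = q$count_above_cutoff,
      mean_gm_spearman = if (q$n_contacts)
        mean(contacts$features$gm_spearman) else 0,
      mean_coverage_ratio = if (nrow(windows)) mean(windows$coverage_ratio)
        else 0,
      mean_n_contacts_per_window = if (nrow(windows)) mean(windows$n_contacts)
        else 0
    )
  }

  structure(
    list(response = resp, contacts = contacts, mito = mito,
         windows = windows, cell_summary = cell_summary,
         manifest_counts = counts, rho_min = resp$rho_min,
         params = params, spacing = pair$spacing),
    class = "contact_result"
  )
}

#' @export
print.contact_result <- function(x, ...) {
  cat("contact_result\n")
  cat("  stage voxel counts:\n")
  for (nm in names(x$manifest_counts)) {
    cat(sprintf("    %-12s %d\n", nm, x$manifest_counts[[nm]]))
  }
  cat(sprintf("  contacts: %d   rho_min: %.4f\n",
              nrow(x$contacts$features), x$rho_min))
  invisible(x)
}

#' Detect contacts from files and write all outputs
#'
#' End-to-end orchestration: read the two channels, run [detect_contacts()],
#' write every output via [write_outputs()] plus a run manifest JSON with the
#' parameters, per-stage retained voxel counts and wall time per stage.
#'
#' @param path_a,path_b Input multi-page TIFF stacks.
#' @param out_dir Output directory.
#' @param params A [detect_params()].
#' @param spacing Voxel spacing `c(y, x, z)` nm.
#' @param timestamp Include wall-clock fields in the manifest.
#' @return The run manifest (list), invisibly; written to
#'   `out_dir/manifest.json`.
#' @export
run_detect <- function(path_a, path_b, out_dir, params = detect_params(),
                       spacing = c(25, 25, 100), timestamp = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  pair <- read_volume_pair(path_a, path_b, spacing = spacing)
  result <- detect_contacts(pair, params)
  t1 <- proc.time()[["elapsed"]]
  files <- write_outputs(result, out_dir, timestamp = timestamp)
  manifest <- list(
    inputs = list(channel_a = path_a, channel_b = path_b),
    params = unclass(params),
    spacing_nm = spacing,
    stage_voxels = as.list(result$manifest_counts),
    rho_min = result$rho_min,
    n_contacts = nrow(result$contacts$features),
    outputs = as.list(stats::setNames(files$path, files$kind)),
    version = as.character(utils::packageVersion("contactr"))
  )
  if (timestamp) {
    manifest$wall_seconds <- list(detect = t1 - t0,
                                  total = proc.time()[["elapsed"]] - t0)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate and write a phantom bundle
#'
#' Thin wrapper over the phantom generators: writes the two channel TIFFs,
#' the ground-truth contact mask and a JSON description of the phantom spec.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
run_phantom <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ph <- if (spec$kind == "two_object") two_object_phantom(spec) else
    cell_phantom(spec)
  paths <- list(
    channel_a = file.path(out_dir, "channel_a.tif"),
    channel_b = file.path(out_dir, "channel_b.tif"),
    truth = file.path(out_dir, "truth_contact_mask.tif"),
    spec = file.path(out_dir, "phantom_spec.json")
  )
  write_volume(float32_array(ph$pair$channel_a), paths$channel_a, bits = 32)
  write_volume(float32_array(ph$pair$channel_b), paths$channel_b, bits = 32)
  write_volume(ph$truth$contact_mask, paths$truth, bits = 8)
  jsonlite::write_json(unclass(spec), paths$spec, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Compare two conditions from per-cell summary tables
#'
#' Wrapper over [compare_groups()] accepting lists of cell summaries (as
#' produced by `detect_contacts()$cell_summary`) or data frames.
#'
#' @param summaries_a,summaries_b Lists of per-cell summary lists, or data
#'   frames with one row per cell.
#' @param features Optional feature subset.
#' @return Tibble as in [compare_groups()].
#' @export
run_compare <- function(summaries_a, summaries_b, features = NULL) {
  to_df <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(s) as.data.frame(s[lengths(s) == 1L])))
  }
  compare_groups(to_df(summaries_a), to_df(summaries_b), features = features)
}

#' Recall and precision of detected contacts against a ground-truth mask
#'
#' Voxel-level agreement with a matching tolerance: a ground-truth voxel
#' counts as recovered if a detected contact voxel lies within
#' `tolerance_voxels` 26-dilation steps, and a detected voxel as correct if a
#' ground-truth voxel does. The tolerance (default 2 voxels, about half the
#' lateral resolution at 25 nm voxels) reflects that the interface is
#' reconstructed from sub-resolution evidence.
#'
#' @param detected Logical array (or `contact_set`) of detected contact
#'   voxels.
#' @param truth_mask Logical ground-truth contact mask.
#' @param tolerance_voxels Matching tolerance (26-dilation steps).
#' @return List with `recall`, `precision`, `n_detected`, `n_truth`.
#' @export
contact_agreement <- function(detected, truth_mask, tolerance_voxels = 2L) {
  if (inherits(detected, "contact_set")) detected <- detected$labels > 0L
  stopifnot(identical(dim(detected), dim(truth_mask)))
  n_det <- sum(detected)
  n_tru <- sum(truth_mask)
  if (n_tru == 0L) {
    return(list(recall = NA_real_, precision = if (n_det) 0 else NA_real_,
                n_detected = n_det, n_truth = n_tru))
  }
  det_halo <- if (n_det && tolerance_voxels > 0L)
    dilate26(detected, tolerance_voxels) else detected
  tru_halo <- if (tolerance_voxels > 0L) dilate26(truth_mask, tolerance_voxels)
    else truth_mask
  list(
    recall = sum(truth_mask & det_halo) / n_tru,
    precision = if (n_det) sum(detected & tru_halo) / n_det else NA_real_,
    n_detected = n_det,
    n_truth = n_tru
  )
}
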