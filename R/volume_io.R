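#' Pair of co-registered image channels
#'
#' Couples the two input channels (by convention: channel A = ER, channel B =
#' mitochondria) with the physical voxel spacing. Both channels must be 3D
#' arrays of identical dimensions `(y, x, z)` with finite, non-negative
#' intensities. Intensities are used raw throughout the pipeline; the only
#' internal normalization is a min-max rescale of the mitochondria channel for
#' the vesicle filter's unit-free mean-intensity threshold.
#'
#' @param channel_a 3D numeric array, first channel (ER-like).
#' @param channel_b 3D numeric array, second channel (mitochondria-like).
#' @param spacing Physical voxel size in nm as `c(y, x, z)`; the axial (z)
#'   axis is the third array dimension. Default `c(25, 25, 100)`.
#' @return An object of class `volume_pair`.
#' @export
volume_pair <- function(channel_a, channel_b, spacing = c(25, 25, 100)) {
  assert_volume(channel_a, "channel_a")
  assert_volume(channel_b, "channel_b")
  if (!identical(dim(channel_a), dim(channel_b))) {
    stop(sprintf(
      "channel dimensions differ: (%s) vs (%s)",
      paste(dim(channel_a), collapse = ","),
      paste(dim(channel_b), collapse = ",")
    ), call. = FALSE)
  }
  if (min(channel_a) < 0 || min(channel_b) < 0) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive values (y, x, z) in nm",
         call. = FALSE)
  }
  storage.mode(channel_a) <- "double"
  storage.mode(channel_b) <- "double"
  structure(
    list(channel_a = channel_a, channel_b = channel_b, spacing = spacing),
    class = "volume_pair"
  )
}

#' @export
print.volume_pair <- function(x, ...) {
  d <- dim(x$channel_a)
  cat(sprintf(
    "volume_pair: %d x %d x %d voxels (y, x, z), spacing %g x %g x %g nm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  invisible(x)
}

#' Read a 3D volume from a multi-page TIFF
#'
#' Pages are stacked along the third (z) dimension, giving an array with
#' dimensions `(y, x, z)`. Intensities are returned as doubles, unchanged in
#' value.
#'
#' @param path Path to a multi-page TIFF stack.
#' @param transpose Swap the two lateral axes on read, for stacks stored with
#'   x as the row dimension.
#' @return 3D numeric array.
#' @export
read_volume <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first sample of multi-sample pages
    if (transpose) p <- t(p)
    p
  })
  d <- dim(pages[[1L]])
  v <- array(0, c(d[1L], d[2L], length(pages)))
  for (k in seq_along(pages)) v[, , k] <- pages[[k]]
  storage.mode(v) <- "double"
  v
}

#' Write a 3D volume as a multi-page TIFF
#'
#' `bits = 32` stores IEEE 32-bit floats (lossless for float32 data, used for
#' response magnitudes and intermediate fields); `bits = 8` stores a `[0,1]`
#' mask/intensity volume as 8-bit integers.
#'
#' @param v 3D numeric (or logical, for masks) array `(y, x, z)`.
#' @param path Output path.
#' @param bits 32 (float) or 8 (integer mask).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, bits = 32) {
  if (is.logical(v)) {
    v <- array(as.numeric(v), dim(v))
  }
  assert_volume(v)
  if (bits == 32) {
    write_tiff_float32(v, path)
  } else if (bits == 8) {
    pages <- lapply(seq_len(dim(v)[3L]), function(k) v[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  } else {
    stop("`bits` must be 8 or 32", call. = FALSE)
  }
  invisible(path)
}

# Minimal uncompressed multi-page float32 TIFF writer (little-endian, one
# strip per page, SampleFormat = IEEE float). tiff::writeTIFF only stores
# integer-quantized samples, which would break the lossless round-trip
# contract for floating-point volumes.
write_tiff_float32 <- function(vol, path) {
  ny <- dim(vol)[1L]; nx <- dim(vol)[2L]; nz <- dim(vol)[3L]
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count); w4(value)
  }
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)
  strip_bytes <- 4L * nx * ny
  ifd_bytes <- 2L + 12L * 10L + 4L
  pos <- 8L
  for (k in seq_len(nz)) {
    data_off <- pos + ifd_bytes
    next_off <- if (k < nz) data_off + strip_bytes else 0L
    w2(10L)                            # 10 IFD entries, ascending tag order
    entry(256L, 3L, 1L, nx)            # ImageWidth
    entry(257L, 3L, 1L, ny)            # ImageLength
    entry(258L, 3L, 1L, 32L)           # BitsPerSample
    entry(259L, 3L, 1L, 1L)            # Compression: none
    entry(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)      # StripOffsets
    entry(277L, 3L, 1L, 1L)            # SamplesPerPixel
    entry(278L, 3L, 1L, ny)            # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)   # StripByteCounts
    entry(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
    w4(next_off)
    writeBin(as.numeric(t(vol[, , k])), con, size = 4L, endian = "little")
    pos <- data_off + strip_bytes
  }
  invisible(path)
}

#' Read two channels as a volume pair
#'
#' @param path_a,path_b Paths to the two multi-page TIFF stacks (equal shape).
#' @param spacing Voxel spacing `c(y, x, z)` in nm, or `NULL` to fall back to
#'   the default 25 x 25 x 100 nm with a warning.
#' @param transpose Passed to [read_volume()].
#' @return A [volume_pair()].
#' @export
read_volume_pair <- function(path_a, path_b, spacing = c(25, 25, 100),
                             transpose = FALSE) {
  a <- read_volume(path_a, transpose = transpose)
  b <- read_volume(path_b, transpose = transpose)
  if (is.null(spacing)) {
    warning("no voxel spacing given; assuming 25 x 25 x 100 nm (y, x, z)")
    spacing <- c(25, 25, 100)
  }
  volume_pair(a, b, spacing = spacing)
}

#' Write all detection outputs to a directory
#'
#' Writes the response magnitude (32-bit float TIFF), the binary contact mask
#' (8-bit TIFF), the per-contact feature table and per-window statistics
#' (RFC-4180 CSV with header row), the mitochondria component table, and a
#' JSON summary embedding the complete parameter set used (provenance).
#'
#' @param result A `contact_result` from [detect_contacts()].
#' @param out_dir Output directory (created if missing).
#' @param timestamp Include a wall-clock timestamp in the summary JSON
#'   (`TRUE` by default; disable for byte-identical reruns).
#' @return A tibble manifest with one row per written file.
#' @export
write_outputs <- function(result, out_dir, timestamp = TRUE) {
  stopifnot(inherits(result, "contact_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory '%s'", out_dir),
           call. = FALSE)
    }
  }
  paths <- c(
    response = file.path(out_dir, "response.tif"),
    contact_mask = file.path(out_dir, "contact_mask.tif"),
    contacts = file.path(out_dir, "contacts.csv"),
    windows = file.path(out_dir, "windows.csv"),
    mito = file.path(out_dir, "mito_components.csv"),
    summary = file.path(out_dir, "summary.json")
  )
  write_volume(float32_array(result$response$magnitude), paths[["response"]],
               bits = 32)
  write_volume(result$contacts$labels > 0L, paths[["contact_mask"]], bits = 8)
  utils::write.csv(as.data.frame(result$contacts$features),
                   paths[["contacts"]], row.names = FALSE)
  utils::write.csv(as.data.frame(result$windows), paths[["windows"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$mito$components), paths[["mito"]],
                   row.names = FALSE)
  summary <- list(
    params = unclass(result$params),
    spacing_nm = result$spacing,
    rho_min = result$rho_min,
    n_contacts = nrow(result$contacts$features),
    stage_voxels = as.list(result$manifest_counts),
    cell_summary = result$cell_summary
  )
  if (timestamp) summary$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tibble::tibble(kind = names(paths), path = unname(paths))
}

# Round a double array to float32 precision so what is written is exactly what
# will be read back.
float32_array <- function(v) {
  d <- dim(v)
  out <- readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
                 n = length(v), size = 4L)
  array(out, d)
}
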