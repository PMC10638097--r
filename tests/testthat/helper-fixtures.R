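# Shared fixtures, computed lazily and cached for the whole test run.
# The expensive ones (full cell-phantom detection, noisy two-object response)
# are built once and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Small noiseless two-object phantom (fast: background windows are constant).
small_two_object <- function(separation_nm = 25) {
  fixture(paste0("two_object_", separation_nm), function() {
    two_object_phantom(phantom_spec("two_object", shape = c(96L, 96L, 32L),
                                    separation_nm = separation_nm))
  })
}

small_two_object_response <- function(separation_nm = 25) {
  fixture(paste0("two_object_resp_", separation_nm), function() {
    contact_response(small_two_object(separation_nm)$pair)
  })
}

# Noisy two-object phantom response: haze floor + correlated read noise, the
# fixture for confidence-threshold behaviour (many voxels respond, counts
# shrink as alpha tightens).
noisy_two_object_response <- function() {
  fixture("noisy_two_object_resp", function() {
    ph <- two_object_phantom(phantom_spec(
      "two_object", shape = c(96L, 96L, 32L), separation_nm = 25,
      haze = 0.02, noise_gaussian = 0.002
    ))
    contact_response(ph$pair)
  })
}

# Default cell phantom and its full-pipeline result (the expensive fixture).
cell_fixture <- function() {
  fixture("cell", function() {
    ph <- cell_phantom(phantom_spec("cell"))
    res <- detect_contacts(ph$pair)
    list(ph = ph, res = res)
  })
}

# Constructed quantification fixture: one large ellipsoidal mitochondrion
# whose surface carries a fine-grained random coat of contact voxels, so the
# coated fraction is known and spread uniformly over the surface.
coated_mito_fixture <- function() {
  fixture("coated_mito", function() {
    shape <- c(96L, 96L, 32L)
    co <- lapply(shape, seq_len)
    solid <- outer(outer((co[[1]] - 48)^2 / 20^2, (co[[2]] - 48)^2 / 24^2, "+"),
                   (co[[3]] - 16)^2 / 10^2, "+") <= 1
    ch <- array(0, shape)
    ch[solid] <- 1
    mito <- segment_mito_components(ch)
    shell <- dilate_mask(solid, 1L) & !solid
    set.seed(11)
    coat <- shell & array(stats::runif(prod(shape)) < 0.35, shape)
    mag <- array(0, shape)
    mag[coat] <- 0.5
    contacts <- label_contacts(mag, 1L)
    kept <- array(mito$labels > 0L, shape)
    surface <- kept & dilate_mask(!kept, 1L)
    covered <- surface & dilate_mask(coat, 1L)
    list(mito = mito, contacts = contacts, coat = coat,
         f_true = sum(covered) / sum(surface))
  })
}

# Brute-force Spearman of two equal-length vectors: average ranks, then the
# textbook Pearson formula (independent of the package's C++ path).
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(0)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Brute-force 6-neighbour Laplacian with replicate-edge padding.
brute_laplacian <- function(v) {
  d <- dim(v)
  out <- array(0, d)
  cl <- function(i, n) min(max(i, 1L), n)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    out[i, j, k] <-
      v[cl(i - 1, d[1]), j, k] + v[cl(i + 1, d[1]), j, k] +
      v[i, cl(j - 1, d[2]), k] + v[i, cl(j + 1, d[2]), k] +
      v[i, j, cl(k - 1, d[3])] + v[i, j, cl(k + 1, d[3])] - 6 * v[i, j, k]
  }
  out
}

# Brute-force gradient-of-Laplacian magnitude (central differences, replicate
# edges), independent of the package implementation.
brute_third_derivative <- function(v) {
  lap <- brute_laplacian(v)
  d <- dim(v)
  out <- array(0, d)
  cl <- function(i, n) min(max(i, 1L), n)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    gy <- (lap[cl(i + 1, d[1]), j, k] - lap[cl(i - 1, d[1]), j, k]) / 2
    gx <- (lap[i, cl(j + 1, d[2]), k] - lap[i, cl(j - 1, d[2]), k]) / 2
    gz <- (lap[i, j, cl(k + 1, d[3])] - lap[i, j, cl(k - 1, d[3])]) / 2
    out[i, j, k] <- sqrt(gy^2 + gx^2 + gz^2)
  }
  out
}

# Digital ball / plate contact sets for shape-feature tests (unit spacing).
ball_contact <- function(radius = 8L, pad = 4L) {
  n <- 2L * (radius + pad) + 1L
  co <- lapply(rep(n, 3), seq_len)
  c0 <- radius + pad + 1L
  solid <- outer(outer((co[[1]] - c0)^2, (co[[2]] - c0)^2, "+"),
                 (co[[3]] - c0)^2, "+") <= radius^2
  mag <- array(0, rep(n, 3))
  mag[solid] <- 1
  label_contacts(mag, 3L)
}
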