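test_that("a single bright voxel is the only one passing z = 3", {
  set.seed(12)
  ch <- array(runif(100^3) * 1e-3, c(100, 100, 100))
  ch[50, 50, 50] <- 1000
  m <- bleedthrough_mask(ch, 3)
  expect_identical(sum(m), 1L)
  expect_true(m[50, 50, 50])
})

test_that("a uniform channel degenerates to an empty mask with a warning", {
  ch <- array(5, c(10, 10, 10))
  expect_warning(m <- bleedthrough_mask(ch, 3), "degenerate")
  expect_true(all(!m))
})

test_that("z-plane ghost copies are excluded at z = 3 but included at z = 1", {
  # a bright structure plus a 10%-intensity ghost in the adjacent z-plane,
  # over a dim background: the ghost scores a low z because the pivotal
  # statistic adapts to the channel's intensity distribution
  set.seed(13)
  ch <- array(runif(50 * 50 * 50, 0.005, 0.015), c(50, 50, 50))
  true_idx <- cbind(rep(16:30, each = 15), rep(16:30, times = 15), 25)
  ghost_idx <- cbind(true_idx[, 1], true_idx[, 2], 26)
  ch[true_idx] <- 1
  ch[ghost_idx] <- 0.1
  m3 <- bleedthrough_mask(ch, 3)
  m1 <- bleedthrough_mask(ch, 1)
  expect_true(all(m3[true_idx]))
  expect_true(all(!m3[ghost_idx]))
  expect_true(all(m1[true_idx]))
  expect_true(all(m1[ghost_idx]))
})

test_that("shadow filter keeps both-zero and both-nonzero voxels only", {
  mag <- array(0, c(9, 9, 9))
  mag[3, 3, 3] <- 0.5  # both third derivatives zero here -> retained
  mag[5, 5, 5] <- 0.5  # one-sided change -> shadow, removed
  mag[7, 7, 7] <- 0.5  # both nonzero -> retained
  resp <- structure(list(magnitude = mag, rho_lap = -mag, rho_int = -mag,
                         n_window = 125L, params = detect_params()),
                    class = "response_map")
  d3a <- array(0, c(9, 9, 9)); d3b <- array(0, c(9, 9, 9))
  base <- 1e-3  # sets the 99th-percentile tolerance scale (>1% of voxels)
  d3a[, 9, 9] <- base; d3b[, 9, 9] <- base
  eps <- contactr:::third_derivative_tol(d3a)
  d3b[5, 5, 5] <- 5 * eps           # nonzero in b only: shadow
  d3a[7, 7, 7] <- 5 * eps; d3b[7, 7, 7] <- 5 * eps
  out <- shadow_filter(resp, d3a, d3b)
  expect_identical(out$magnitude[3, 3, 3], 0.5)
  expect_identical(out$magnitude[5, 5, 5], 0)
  expect_identical(out$magnitude[7, 7, 7], 0.5)
})

test_that("a parallel one-channel band is removed while the interface survives", {
  # interface: both channels ramp (both third derivatives nonzero);
  # shadow band 3 voxels away: only one channel changes there
  d <- c(16, 24, 9)
  a <- array(0, d); b <- array(0, d)
  # curved (exponential) profiles: their Laplacian varies, so the third
  # derivative is nonzero where the signal changes
  a[, 1:12, ] <- rep(rep(exp(seq(0, -2.3, length.out = 12)), each = d[1]),
                     times = d[3])
  b[, 10:24, ] <- rep(rep(exp(seq(-2.3, 0, length.out = 15)), each = d[1]),
                      times = d[3])
  pair <- volume_pair(a, b, c(25, 25, 100))
  resp <- contact_response(pair, detect_params(w = 2L))
  mag <- resp$magnitude
  mag[, 1:24, ] <- 0
  mag[8, 11, 5] <- 0.6   # stand-in interface voxel (both channels change)
  mag[8, 20, 5] <- 0.6   # shadow voxel: `a` is flat (zero) at x = 20
  resp$magnitude <- mag
  d3a <- third_derivative(a)
  d3b <- third_derivative(b)
  out <- shadow_filter(resp, d3a, d3b)
  expect_identical(out$magnitude[8, 11, 5], 0.6)
  expect_identical(out$magnitude[8, 20, 5], 0)
})

test_that("mitochondria segmentation separates and flags components by size", {
  shape <- c(48L, 48L, 32L)
  co <- lapply(shape, seq_len)
  big <- outer(outer((co[[1]] - 20)^2 / 16^2, (co[[2]] - 24)^2 / 18^2, "+"),
               (co[[3]] - 16)^2 / 8^2, "+") <= 1
  small <- outer(outer((co[[1]] - 42)^2 / 5^2, (co[[2]] - 42)^2 / 5^2, "+"),
                 (co[[3]] - 26)^2 / 4^2, "+") <= 1
  ch <- array(0, shape)
  ch[big] <- 0.8
  ch[small] <- 0.8
  mito <- segment_mito_components(ch)
  comp <- mito$components[order(-mito$components$size), ]
  expect_identical(nrow(comp), 2L)            # two disjoint ellipsoids
  expect_gte(comp$ln_size[1], 9)              # ~10k voxels: ln about 9.2
  expect_true(comp$keep[1])
  expect_lt(comp$ln_size[2], 9)               # a few hundred voxels
  expect_false(comp$keep[2])
})

test_that("empty foreground yields an empty component table with a warning", {
  expect_warning(mito <- segment_mito_components(array(0, c(10, 10, 10))),
                 "empty")
  expect_identical(nrow(mito$components), 0L)
})

test_that("vesicle filter keeps contacts with a genuine partner only", {
  shape <- c(24L, 24L, 12L)
  labels <- array(0L, shape)
  labels[4:6, 4:6, 4:6] <- 1L     # kept mitochondrion stand-in
  labels[16:18, 16:18, 4:6] <- 2L # vesicle-like component
  comp <- tibble::tibble(
    label = 1:2, size = c(27L, 27L), ln_size = log(c(27, 27)),
    mean_intensity = c(0.9, 0.05), keep = c(TRUE, FALSE)
  )
  mito <- structure(list(labels = labels, components = comp, threshold = 0.5),
                    class = "mito_components")
  mag <- array(0, shape)
  mag[7, 4:6, 4:6] <- 0.5     # touches the kept mitochondrion
  mag[15, 16:18, 4:6] <- 0.5  # touches only the vesicle
  mag[12, 12, 9:11] <- 0.5    # touches nothing
  contacts <- label_contacts(mag, 3L)
  expect_identical(nrow(contacts$features), 3L)
  out <- vesicle_filter(contacts, mito, detect_params())
  expect_identical(nrow(out$features), 1L)
  kept_vox <- which(out$labels > 0L, arr.ind = TRUE)
  expect_true(all(kept_vox[, 1] == 7))
  # contact adjacent to both a vesicle and a kept mitochondrion is retained
  mag2 <- array(0, shape)
  mag2[7, 4:6, 4:6] <- 0.5
  labels2 <- labels
  labels2[8:10, 4:6, 4:6] <- 2L  # vesicle hugging the same contact
  mito2 <- structure(list(labels = labels2, components = comp, threshold = 0.5),
                     class = "mito_components")
  out2 <- vesicle_filter(label_contacts(mag2, 3L), mito2, detect_params())
  expect_identical(nrow(out2$features), 1L)
})

test_that("with vacuous thresholds every mito-adjacent contact survives", {
  shape <- c(16L, 16L, 8L)
  ch <- array(0, shape)
  ch[4:8, 4:8, 3:5] <- 1
  mito <- segment_mito_components(ch, mito_ln_size = -Inf,
                                  mito_min_intensity = 0)
  expect_true(all(mito$components$keep))
  mag <- array(0, shape)
  mag[9, 4:8, 3:5] <- 0.5
  contacts <- label_contacts(mag, 3L)
  out <- vesicle_filter(contacts, mito, detect_params())
  expect_identical(out$features, contacts$features)
})

test_that("every filter stage only ever removes response", {
  resp <- noisy_two_object_response()
  conf <- apply_confidence(resp)
  expect_true(all(conf$magnitude <= resp$magnitude))
  ph <- small_two_object()
  d3a <- third_derivative(ph$pair$channel_a)
  d3b <- third_derivative(ph$pair$channel_b)
  sh <- shadow_filter(conf, d3a, d3b)
  expect_true(all(sh$magnitude <= conf$magnitude))
})
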