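test_that("components of 2 voxels or fewer are removed, 3 and up survive", {
  mag <- array(0, c(16, 16, 8))
  mag[2, 2, 2] <- 0.5                      # volume 1
  mag[6, 6:7, 2] <- 0.5                    # volume 2
  mag[10, 10:12, 2] <- 0.5                 # volume 3
  mag[14, 2:5, 5] <- 0.5                   # volume 4
  mag[2, 10:14, 6] <- 0.5                  # volume 5
  contacts <- label_contacts(mag, min_contact_voxels = 3L)
  expect_setequal(contacts$features$volume, c(3L, 4L, 5L))
  surv <- tabulate(contacts$labels[contacts$labels > 0L])
  expect_true(all(surv >= 3L))
  empty <- label_contacts(array(0, c(10, 10, 10)))
  expect_identical(nrow(empty$features), 0L)
})

test_that("corner-touching blobs are one component under 26-connectivity", {
  mag <- array(0, c(12, 12, 12))
  mag[3:4, 3:4, 3:4] <- 0.5        # 8-voxel cube
  mag[5:6, 5:6, 5:6] <- 0.5        # touches the first only at a corner
  contacts <- label_contacts(mag, 3L)
  expect_identical(nrow(contacts$features), 1L)
  lab6 <- contactr:::label_components(mag > 0, connectivity = 6L)
  expect_identical(max(lab6), 2L)
})

test_that("a digital ball is spherical and a one-voxel plate is planar", {
  ball <- ball_contact(radius = 8L)
  fb <- contact_features(ball, ball$labels * 0 + 1, spacing = c(1, 1, 1))
  expect_identical(nrow(fb), 1L)
  expect_gte(fb$sphericity, 0.95)
  expect_lte(fb$planarity, 0.05)
  plate <- array(0, c(26, 26, 7))
  plate[4:23, 4:23, 4] <- 1
  cp <- label_contacts(plate, 3L)
  fp <- contact_features(cp, plate, spacing = c(1, 1, 1))
  expect_gte(fp$planarity, 0.9)
  expect_lte(fp$sphericity, 0.01)
  expect_identical(fp$height_nm, 1)        # one z-plane at unit spacing
})

test_that("shape decomposition sums to one and ignores labels/translation", {
  set.seed(14)
  mag <- array(0, c(24, 24, 12))
  mag[3:7, 3:9, 3:5] <- runif(105, 0.2, 1)
  mag[15:20, 14:20, 7:10] <- runif(168, 0.2, 1)
  contacts <- label_contacts(mag, 3L)
  f <- contact_features(contacts, mag, spacing = c(25, 25, 100))
  expect_identical(nrow(f), 2L)
  expect_equal(f$sphericity + f$planarity + f$anisotropy, rep(1, 2),
               tolerance = 1e-12)
  # translate the whole field: features identical up to the centroid shift
  shift <- array(0, c(24, 24, 12))
  shift[4:8, 4:10, 4:6] <- mag[3:7, 3:9, 3:5]
  shift[16:21, 15:21, 8:11] <- mag[15:20, 14:20, 7:10]
  fs <- contact_features(label_contacts(shift, 3L), shift,
                         spacing = c(25, 25, 100))
  for (col in c("volume", "gm_spearman", "lambda1", "lambda2", "lambda3",
                "sphericity", "planarity", "anisotropy", "height_nm")) {
    expect_equal(fs[[col]], f[[col]], tolerance = 1e-9)
  }
})

test_that("the geometric mean of the response is reported per contact", {
  mag <- array(0, c(12, 12, 8))
  mag[4, 4:5, 4] <- 0.25
  mag[4, 6:7, 4] <- 1
  contacts <- label_contacts(mag, 3L)
  f <- contact_features(contacts, mag)
  expect_equal(f$gm_spearman, 0.5, tolerance = 1e-12)
})

test_that("degenerate collinear contacts decompose as pure line segments", {
  mag <- array(0, c(12, 12, 8))
  mag[3:9, 5, 4] <- 1
  f <- contact_features(label_contacts(mag, 3L), mag, spacing = c(1, 1, 1))
  expect_equal(f$anisotropy, 1, tolerance = 1e-12)
  expect_equal(f$planarity, 0, tolerance = 1e-12)
  expect_equal(f$sphericity, 0, tolerance = 1e-12)
})

test_that("coverage is 0 with no contacts and 1 for a fully sheathed body", {
  shape <- c(48L, 48L, 24L)
  ch <- array(0, shape)
  ch[10:39, 10:39, 7:18] <- 1  # 30 x 30 x 12 box, above the size threshold
  mito <- segment_mito_components(ch)
  expect_true(all(mito$components$keep))
  none <- sliding_window_stats(label_contacts(array(0, shape)), mito,
                               quant_k = 3L)
  expect_true(all(none$coverage_ratio == 0))
  expect_true(all(none$n_contacts == 0L))
  solid <- ch > 0
  sheath <- dilate_mask(solid, 1L) & !solid
  mag <- array(0, shape)
  mag[sheath] <- 0.9
  full <- sliding_window_stats(label_contacts(mag, 3L), mito, quant_k = 3L)
  expect_true(all(full$coverage_ratio == 1))
  expect_gte(max(full$n_contacts), 1L)
})

test_that("coverage and counts never decrease when contact voxels are added", {
  fx <- coated_mito_fixture()
  w1 <- sliding_window_stats(fx$contacts, fx$mito, quant_k = 5L)
  # add more coat: dilate the contact mask by one voxel
  mag2 <- array(0, dim(fx$contacts$labels))
  mag2[dilate_mask(fx$contacts$labels > 0L, 1L)] <- 0.5
  w2 <- sliding_window_stats(label_contacts(mag2, 1L), fx$mito, quant_k = 5L)
  key1 <- paste(w1$cube_y, w1$cube_x, w1$cube_z)
  key2 <- paste(w2$cube_y, w2$cube_x, w2$cube_z)
  shared <- intersect(key1, key2)
  expect_true(all(w2$coverage_ratio[match(shared, key2)] >=
                    w1$coverage_ratio[match(shared, key1)]))
})

test_that("no kept mitochondria yields an empty window table with a warning", {
  labels <- array(0L, c(16, 16, 8))
  comp <- tibble::tibble(label = integer(), size = integer(),
                         ln_size = numeric(), mean_intensity = numeric(),
                         keep = logical())
  mito <- structure(list(labels = labels, components = comp, threshold = 0.5),
                    class = "mito_components")
  expect_warning(
    w <- sliding_window_stats(label_contacts(array(0, c(16, 16, 8))), mito),
    "no kept"
  )
  expect_identical(nrow(w), 0L)
})

test_that("Q95 follows the linear-interpolation order statistics", {
  mk <- function(vols) {
    structure(list(labels = array(0L, c(4, 4, 4)),
                   features = tibble::tibble(label = seq_along(vols),
                                             volume = as.integer(vols))),
              class = "contact_set")
  }
  expect_identical(q95_summary(mk(rep(7, 100)))$q95_volume, 7)
  vols <- 3:100
  # independent order-statistics oracle: h = (n-1) p + 1, linear interpolation
  h <- (length(vols) - 1) * 0.95 + 1
  oracle <- vols[floor(h)] + (h - floor(h)) * (vols[floor(h) + 1] - vols[floor(h)])
  expect_equal(q95_summary(mk(vols))$q95_volume, oracle, tolerance = 1e-12)
  s <- q95_summary(mk(c(10, 600, 700)), large_contact_voxels = 500)
  expect_identical(s$count_above_cutoff, 2L)
  empty <- q95_summary(mk(integer()))
  expect_identical(empty$n_contacts, 0L)
  expect_identical(empty$q95_volume, 0)
})

test_that("group comparison is an exact two-sided Mann-Whitney on cells", {
  a <- data.frame(coverage = c(1, 2, 3))
  b <- data.frame(coverage = c(10, 11, 12))
  out <- compare_groups(a, b)
  expect_equal(out$p_value, 0.1, tolerance = 1e-12)  # exact enumeration, U = 0
  same <- compare_groups(a, a)
  expect_gte(same$p_value, 0.99)
  shifted <- compare_groups(a + 100, b + 100)
  expect_identical(shifted$p_value, out$p_value)     # rank invariance
  expect_error(compare_groups(data.frame(coverage = 1:2), b), "3 cells")
})
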