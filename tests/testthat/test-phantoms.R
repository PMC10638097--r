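test_that("phantom generation is a pure function of spec and seed", {
  spec <- phantom_spec("two_object", shape = c(64L, 64L, 16L),
                       radius_nm = 200, separation_nm = 50,
                       noise_gaussian = 0.01)
  p1 <- two_object_phantom(spec)
  p2 <- two_object_phantom(spec)
  expect_identical(p1$pair$channel_a, p2$pair$channel_a)
  expect_identical(p1$pair$channel_b, p2$pair$channel_b)
  p3 <- two_object_phantom(phantom_spec("two_object", shape = c(64L, 64L, 16L),
                                        radius_nm = 200, separation_nm = 50,
                                        noise_gaussian = 0.01, seed = 2L))
  expect_false(identical(p1$pair$channel_a, p3$pair$channel_a))
})

test_that("touching spheres overlap at the midplane in both channels", {
  ph <- small_two_object(0)
  mid <- dim(ph$pair$channel_a)[2] %/% 2 + 1L
  a_mid <- ph$pair$channel_a[, mid, ]
  b_mid <- ph$pair$channel_b[, mid, ]
  expect_true(any(a_mid > 0.05 & b_mid > 0.05))
})

test_that("ground-truth mask is nonempty iff separation <= system resolution", {
  for (sep in c(0, 60, 120)) {
    ph <- two_object_phantom(phantom_spec("two_object", shape = c(96L, 96L, 32L),
                                          separation_nm = sep))
    expect_gt(sum(ph$truth$contact_mask), 0)
  }
  far <- two_object_phantom(phantom_spec("two_object", shape = c(96L, 96L, 32L),
                                         separation_nm = 150))
  expect_identical(sum(far$truth$contact_mask), 0L)
})

test_that("out-of-bounds and overlapping geometry raise geometry errors", {
  expect_error(
    two_object_phantom(phantom_spec("two_object", shape = c(32L, 32L, 16L),
                                    radius_nm = 600)),
    "bounds"
  )
  # a negative designated gap sinks the tubule into the mitochondrion
  expect_error(
    cell_phantom(phantom_spec("cell", contact_gap_nm = -150)),
    "overlap"
  )
})

test_that("PSF-free, noise-free spheres reproduce the solid indicators", {
  spec <- phantom_spec("two_object", shape = c(64L, 64L, 24L),
                       psf_fwhm = c(0, 0, 0), separation_nm = 100,
                       radius_nm = 300)
  ph <- two_object_phantom(spec)
  expect_identical(ph$pair$channel_a > 0, ph$truth$solid_a)
  expect_identical(ph$pair$channel_b > 0, ph$truth$solid_b)
  expect_setequal(unique(as.numeric(ph$pair$channel_a)), c(0, 1))
})

test_that("convolution conserves total intensity to within boundary loss", {
  spec <- phantom_spec("two_object", shape = c(96L, 96L, 32L),
                       separation_nm = 50)
  ph <- two_object_phantom(spec)
  expect_equal(sum(ph$pair$channel_a), sum(ph$truth$solid_a),
               tolerance = 0.01)
  expect_equal(sum(ph$pair$channel_b), sum(ph$truth$solid_b),
               tolerance = 0.01)
})

test_that("cell phantom ground truth has the designed structure", {
  fx <- cell_fixture()
  truth <- fx$ph$truth
  gt_labels <- contactr:::label_components(truth$contact_mask)
  expect_identical(max(gt_labels), 2L)  # two designated contacts
  tab <- truth$mito_table
  expect_identical(sum(!tab$is_vesicle), 3L)
  expect_identical(sum(tab$is_vesicle), 5L)
  # genuine mitochondria above, vesicles below, both filter thresholds
  expect_true(all(log(tab$size_voxels[!tab$is_vesicle]) >= 9))
  expect_true(all(tab$intensity_scale[!tab$is_vesicle] >= 0.2))
  expect_true(all(log(tab$size_voxels[tab$is_vesicle]) < 9))
  expect_true(all(tab$intensity_scale[tab$is_vesicle] < 0.2))
  # channels do not overlap as solids
  expect_false(any(truth$er_mask & truth$mito_labels > 0L))
})

test_that("add_noise is seeded, unbiased away from the clip, and validated", {
  v <- array(1, c(50, 50, 40))  # level >> sigma so clipping is inactive
  n1 <- add_noise(v, gaussian_sigma = 0.05, seed = 9L)
  n2 <- add_noise(v, gaussian_sigma = 0.05, seed = 9L)
  expect_identical(n1, n2)
  delta <- n1 - v
  se <- 0.05 / sqrt(length(v))
  expect_lt(abs(mean(delta)), 3 * se)
  expect_identical(add_noise(v, 0, 0), v)
  expect_error(add_noise(v, gaussian_sigma = -1), ">= 0")
  expect_error(add_noise(v, poisson_scale = -1), ">= 0")
  # correlated noise keeps the requested marginal sd
  nc <- add_noise(v, gaussian_sigma = 0.05, seed = 9L,
                  smooth_fwhm = c(60, 60, 125))
  expect_equal(stats::sd(nc - v), 0.05, tolerance = 0.05)
})
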