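test_that("hand-traceable shapes give exact area and perimeter", {
  sq <- segFromMask(mkSquare(10L))
  ms <- measureNest(sq, 1L)
  expect_equal(ms$area_px, 100L)
  expect_equal(ms$perimeter_px, 36)      # 4 sides x 9 unit steps
  line <- matrix(FALSE, 5, 9); line[3, 3:7] <- TRUE
  ml <- measureNest(segFromMask(line), 1L)
  expect_equal(ml$area_px, 5L)
  expect_equal(ml$perimeter_px, 8)       # out-and-back Moore trace
  expect_error(measureNest(sq, 2L), "not present")
})

test_that("digitized disks obey the analytic perimeter and circularity bands", {
  for (r in c(20L, 30L, 50L)) {
    m <- measureNest(segFromMask(mkDisk(r)), 1L)
    expect_lt(abs(m$perimeter_px - 2 * pi * r) / (2 * pi * r), 0.05)
    circ <- 4 * pi * m$area_px / m$perimeter_px^2
    expect_gt(circ, 0.9); expect_lt(circ, 1.1)
  }
})

test_that("the eight parameters match direct formula evaluation", {
  shp <- data.frame(area_px = c(100, 100), perimeter_px = c(36, 36))
  f <- computeCoreFeatures(shp, "c1")
  expect_equal(f$number, 2L)
  expect_equal(f$total_area, 200)
  expect_equal(f$average_area, 100)
  expect_equal(f$total_perimeter, 72)
  expect_equal(f$average_perimeter, 36)
  expect_equal(f$ta_over_tp, 200 / 72, tolerance = 1e-12)
  expect_equal(f$avg_a_over_p, 100 / 36, tolerance = 1e-12)
  expect_equal(f$circularity, 4 * pi * 100 / 36^2, tolerance = 1e-12)
  # n = 1 identities: averages equal totals, both area/perimeter ratios agree
  f1 <- computeCoreFeatures(data.frame(area_px = 317, perimeter_px = 65.94), "c2")
  expect_identical(f1$average_area, f1$total_area)
  expect_identical(f1$average_perimeter, f1$total_perimeter)
  expect_identical(f1$ta_over_tp, f1$avg_a_over_p)
  # empty core is degenerate, not an error
  f0 <- computeCoreFeatures(data.frame(area_px = numeric(),
                                       perimeter_px = numeric()), "c0")
  expect_true(f0$degenerate)
  expect_equal(f0$number, 0L)
  expect_true(is.na(f0$circularity))
  expect_error(computeCoreFeatures(data.frame(area_px = 5, perimeter_px = 0)),
               "positive")
})

test_that("area, perimeter and circularity scale as k^2, k and 1", {
  base <- measureNest(segFromMask(mkDisk(12L)), 1L)
  circ0 <- 4 * pi * base$area_px / base$perimeter_px^2
  for (k in 2:4) {
    mk <- measureNest(segFromMask(mkDisk(12L * k)), 1L)
    expect_lt(abs(mk$area_px / base$area_px - k^2) / k^2, 0.05)
    expect_lt(abs(mk$perimeter_px / base$perimeter_px - k) / k, 0.05)
    circ <- 4 * pi * mk$area_px / mk$perimeter_px^2
    expect_lt(abs(circ - circ0) / circ0, 0.03)
  }
})

test_that("circles out-score blobs on circularity", {
  feat <- function(fam, seed) {
    spec <- syntheticImageSpec(n_nests = 6L, shape_family = fam,
                               size_range_px = c(14, 22), noise_sd = 0,
                               n_distractors = 0L, seed = seed)
    lab <- simulateCoreImage(spec)$truth$labelMask
    computeCoreFeatures(nestShapes(segFromMask(lab > 0)))
  }
  for (seed in c(6, 16)) {
    expect_lt(feat("blob", seed)$circularity, feat("circle", seed)$circularity)
  }
})

test_that("total-over-total is a perimeter-weighted mean of per-nest ratios", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    shp <- data.frame(area_px = runif(n, 50, 4000),
                      perimeter_px = runif(n, 20, 400))
    f <- computeCoreFeatures(shp)
    ratios <- shp$area_px / shp$perimeter_px
    expect_gte(f$ta_over_tp, min(ratios))
    expect_lte(f$ta_over_tp, max(ratios))
  }
})
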