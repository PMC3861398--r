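test_that("constant images give a flagged degenerate channel", {
  px <- array(0.8, c(64, 64, 3))
  ch <- preprocessCore(coreImage(px))
  expect_true(isDegenerate(ch))
  expect_error(binarizeOtsu(ch), "degenerate histogram")
})

test_that("pointwise color transform preserves a two-tone image", {
  px <- array(0, c(64, 64, 3))
  fg <- c(118, 74, 48) / 255; bg <- c(228, 222, 236) / 255
  for (ch in 1:3) px[, , ch] <- bg[ch]
  for (ch in 1:3) px[20:40, 20:40, ch] <- fg[ch]
  channel <- preprocessCore(coreImage(px), denoiseRadius = 0L)
  vals <- unique(as.vector(channelValues(channel)))
  expect_length(vals, 2L)
  expect_setequal(round(sort(vals), 10), c(0, 1))
  # DAB-brown foreground must map to the high end of the channel
  expect_equal(channelValues(channel)[30, 30], 1)
})

test_that("radius-1 median filtering removes isolated salt noise", {
  px <- array(0, c(64, 64, 3))
  bg <- c(228, 222, 236) / 255
  for (ch in 1:3) px[, , ch] <- bg[ch]
  pxNoise <- px
  pxNoise[32, 32, ] <- c(118, 74, 48) / 255  # single stained pixel
  chNoise <- preprocessCore(coreImage(pxNoise), denoiseRadius = 1L)
  expect_true(isDegenerate(chNoise))  # noise removed -> constant channel
})

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  set.seed(42)
  for (rep in 1:5) {
    v <- c(rnorm(4000, 0.25, 0.05), rnorm(1000, 0.75, 0.07))
    v <- matrix(pmin(pmax(v, 0), 1), 50, 100)
    mask <- binarizeOtsu(v)
    expect_lt(abs(attr(mask, "threshold") - bruteOtsu(v)), 1e-12)
  }
  # bimodal two-value channel: threshold strictly between the tones
  v2 <- matrix(0.1, 40, 40); v2[1:4, ] <- 0.9
  m2 <- binarizeOtsu(v2)
  th <- attr(m2, "threshold")
  expect_true(th > 0.1 && th < 0.9)
  expect_identical(unname(m2 == TRUE), unname(v2 == 0.9))
  # idempotence on a 0/1 channel: binarization reproduces the mask
  known <- matrix(0, 32, 32); known[10:20, 5:15] <- 1
  bk <- binarizeOtsu(known)
  expect_identical(matrix(as.numeric(bk), 32, 32), known)
})

test_that("opening removes sub-element objects and thin bridges", {
  m <- matrix(FALSE, 20, 20); m[10, 10] <- TRUE
  expect_false(any(morphOpen(m, 1L)))
  disk <- mkDisk(15L)
  opened <- morphOpen(disk, 2L)
  expect_lt(sum(xor(opened, disk)), 40)          # unchanged up to boundary px
  expect_identical(morphOpen(opened, 2L), opened) # idempotent
  # two squares joined by a 1-px bridge separate at radius 2
  b <- matrix(FALSE, 30, 40)
  b[10:20, 5:15] <- TRUE; b[10:20, 25:35] <- TRUE; b[15, 16:24] <- TRUE
  expect_equal(max(nestmorph:::label8(b)), 1L)
  expect_equal(max(nestmorph:::label8(morphOpen(b, 2L))), 2L)
})

test_that("hole filling restores interiors and is idempotent", {
  annulus <- mkDisk(12L) & !mkDisk(6L, pad = 11L)
  filled <- fillHoles(annulus)
  expect_identical(filled, mkDisk(12L))
  expect_identical(fillHoles(filled), filled)
  # nested ring-in-ring collapses to one solid disk
  nested <- mkDisk(14L) & !mkDisk(10L, pad = 9L) |
    (mkDisk(6L, pad = 13L) & !mkDisk(3L, pad = 16L))
  expect_identical(fillHoles(nested), mkDisk(14L))
  # no holes -> unchanged
  sq <- mkSquare(8L)
  expect_identical(fillHoles(sq), sq)
})

test_that("boundary map equals the 4-neighbour scan oracle", {
  sq <- mkSquare(10L)
  bm <- extractBoundaries(sq)$boundaryMap
  expect_equal(sum(bm), 36L)
  expect_identical(bm, loopBoundary4(sq))
  expect_false(any(extractBoundaries(matrix(FALSE, 8, 8))$boundaryMap))
  full <- matrix(TRUE, 9, 11)
  bmFull <- extractBoundaries(full)$boundaryMap
  expect_identical(bmFull, loopBoundary4(full))
  expect_false(bmFull[5, 5])
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(runif(30 * 30) > 0.6, 30, 30)
    m <- fillHoles(morphOpen(m, 1L))
    expect_identical(extractBoundaries(m)$boundaryMap, loopBoundary4(m))
  }
})

test_that("override rasters force and erase regions", {
  m <- mkDisk(8L)
  keep <- matrix(0L, nrow(m), ncol(m))
  expect_identical(applyOverrides(m, keep), m)
  rm <- keep; rm[m] <- 2L
  expect_equal(nNests(labelNests(applyOverrides(m, rm), 1L)), 0L)
  add <- keep; add[2:5, 2:5] <- 1L
  expect_equal(nNests(labelNests(applyOverrides(m, add), 1L)),
               nNests(labelNests(m, 1L)) + 1L)
  expect_error(applyOverrides(m, matrix(0L, 3, 3)), "same shape")
})

test_that("labeling is 8-connected, size-filtered and raster-ordered", {
  m <- matrix(FALSE, 40, 40)
  m[5:10, 5:10] <- TRUE       # 36 px, first in raster order
  m[25:34, 25:34] <- TRUE     # 100 px
  seg <- labelNests(m, minSize = 10L)
  expect_equal(nNests(seg), 2L)
  expect_equal(labelMask(seg)[6, 6], 1L)   # raster-scan numbering
  expect_equal(labelMask(seg)[30, 30], 2L)
  expect_equal(nNests(labelNests(m, minSize = 50L)), 1L)  # 36 px dropped
  # diagonal-touching pixels form one component
  d <- matrix(FALSE, 10, 10); d[3, 3] <- TRUE; d[4, 4] <- TRUE
  expect_equal(nNests(labelNests(d, minSize = 1L)), 1L)
  # contours are closed
  for (ct in contours(seg)) expect_identical(ct[1, ], ct[nrow(ct), ])
})

test_that("full pipeline is deterministic and recovers a noise-free core", {
  spec <- syntheticImageSpec(n_nests = 9L, noise_sd = 0, seed = 200,
                             size_range_px = c(10, 20))
  sim <- simulateCoreImage(spec)
  s1 <- segmentCore(sim$image)
  s2 <- segmentCore(sim$image)
  expect_identical(labelMask(s1), labelMask(s2))
  expect_identical(contours(s1), contours(s2))
  expect_equal(nNests(s1), 9L)
  expect_false(is.null(paramsUsed(s1)$threshold))
})
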