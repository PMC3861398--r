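#' Specification for a synthetic stained-core image
#'
#' Describes a synthetic brightfield core: DAB-brown tumor-nest blobs of
#' controlled count, size and shape on a pale counterstain background, with
#' optional additive Gaussian noise and unstained vessel/nerve-like
#' distractor structures. Rendering is fully determined by the spec (including
#' its seed), so a spec is a reproducible recipe for one core plus its ground
#' truth.
#'
#' @param width_px,height_px raster size in pixels (default 512 x 512, a
#'   desk-scale stand-in for full-resolution core scans).
#' @param n_nests number of tumor nests to place (>= 0).
#' @param shape_family one of \code{"circle"}, \code{"ellipse"},
#'   \code{"blob"}. Blobs are ellipses with a low-order sinusoidal radial
#'   perturbation, so circularity strictly below 1 is generable without
#'   self-intersection.
#' @param size_range_px numeric length-2, (min_radius, max_radius) of the
#'   nests' major semi-axis in pixels; min_radius >= 2.
#' @param stain_fg_rgb,stain_bg_rgb 8-bit RGB triplets for DAB-positive nest
#'   tissue and for the pale counterstained background.
#' @param distractor_rgb 8-bit RGB triplet for unstained distractor
#'   structures; default is an eosinophilic pink with negligible DAB signal.
#' @param noise_sd additive Gaussian noise standard deviation in 8-bit
#'   intensity units (0 disables noise).
#' @param n_distractors number of unstained vessel/nerve-like shapes.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return a validated \code{SyntheticImageSpec} (named list).
#' @seealso [simulateCoreImage()]
#' @export
syntheticImageSpec <- function(width_px = 512L, height_px = 512L,
                               n_nests = 12L, shape_family = "blob",
                               size_range_px = c(10, 24),
                               stain_fg_rgb = c(118L, 74L, 48L),
                               stain_bg_rgb = c(228L, 222L, 236L),
                               distractor_rgb = c(205L, 150L, 160L),
                               noise_sd = 4, n_distractors = 3L,
                               seed = 1L) {
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               n_nests = as.integer(n_nests),
               shape_family = match.arg(shape_family,
                                        c("circle", "ellipse", "blob")),
               size_range_px = as.numeric(size_range_px),
               stain_fg_rgb = as.integer(stain_fg_rgb),
               stain_bg_rgb = as.integer(stain_bg_rgb),
               distractor_rgb = as.integer(distractor_rgb),
               noise_sd = as.numeric(noise_sd),
               n_distractors = as.integer(n_distractors),
               seed = as.integer(seed))
  stopIfNot(spec$width_px >= 32 && spec$height_px >= 32,
            "raster must be at least 32 x 32")
  stopIfNot(spec$n_nests >= 0, "n_nests must be non-negative")
  stopIfNot(length(spec$size_range_px) == 2 &&
            spec$size_range_px[1] >= 2 &&
            spec$size_range_px[2] >= spec$size_range_px[1],
            "size_range_px must be (min_radius, max_radius) with min >= 2")
  for (col in list(spec$stain_fg_rgb, spec$stain_bg_rgb, spec$distractor_rgb))
    stopIfNot(length(col) == 3 && all(col >= 0) && all(col <= 255),
              "colors must be 8-bit RGB triplets")
  stopIfNot(spec$noise_sd >= 0, "noise_sd must be non-negative")
  stopIfNot(spec$n_distractors >= 0, "n_distractors must be non-negative")
  class(spec) <- "SyntheticImageSpec"
  spec
}

#' @export
print.SyntheticImageSpec <- function(x, ...) {
  cat(sprintf(
    "SyntheticImageSpec: %dx%d, %d %s nest(s), radii [%g, %g], noise sd %g, %d distractor(s), seed %d\n",
    x$width_px, x$height_px, x$n_nests, x$shape_family,
    x$size_range_px[1], x$size_range_px[2], x$noise_sd, x$n_distractors,
    x$seed))
  invisible(x)
}

# One placed shape. All geometry in pixel units; angle in radians.
# Family "circle": a == b, amp = 0; "ellipse": amp = 0; "blob": amp > 0 with
# low-order sinusoidal radial modulation rho(theta) = 1 + amp*sin(m*theta+ph)
# in normalized ellipse coordinates. amp < 1 guarantees a simple closed curve.
sampleShape <- function(family, size_range) {
  a <- runif(1, size_range[1], size_range[2])
  sh <- list(family = family, a = a, b = a, angle = 0, amp = 0, m = 0L,
             phase = 0)
  if (family %in% c("ellipse", "blob")) {
    sh$b <- a * runif(1, 0.55, 0.9)
    sh$angle <- runif(1, 0, pi)
  }
  if (family == "blob") {
    sh$amp <- runif(1, 0.12, 0.25)
    sh$m <- sample(3:5, 1)
    sh$phase <- runif(1, 0, 2 * pi)
  }
  sh
}

shapeOuterRadius <- function(sh) sh$a * (1 + sh$amp)

# Logical raster of the shape over the full H x W grid (pixel centers at
# integer (row, col)); restricted to a bounding box for speed.
rasterizeShape <- function(sh, H, W) {
  R <- ceiling(shapeOuterRadius(sh)) + 2L
  rows <- max(1L, floor(sh$cy - R)):min(H, ceiling(sh$cy + R))
  cols <- max(1L, floor(sh$cx - R)):min(W, ceiling(sh$cx + R))
  dy <- outer(rows - sh$cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - sh$cx)
  xr <- dx * cos(sh$angle) + dy * sin(sh$angle)
  yr <- -dx * sin(sh$angle) + dy * cos(sh$angle)
  u <- xr / sh$a
  v <- yr / sh$b
  rho <- sqrt(u^2 + v^2)
  inside <- if (sh$amp > 0) {
    theta <- atan2(v, u)
    rho <= 1 + sh$amp * sin(sh$m * theta + sh$phase)
  } else rho <= 1
  list(rows = rows, cols = cols, inside = inside)
}

# Analytic area/perimeter of the continuous shape. Circles and ellipses use
# closed forms (Ramanujan's approximation for the ellipse perimeter); blobs
# use a dense boundary polygon (shoelace area, polyline length).
shapeAnalytic <- function(sh) {
  if (sh$amp == 0 && sh$a == sh$b) {
    return(list(area = pi * sh$a^2, perimeter = 2 * pi * sh$a))
  }
  if (sh$amp == 0) {
    a <- sh$a; b <- sh$b
    return(list(area = pi * a * b,
                perimeter = pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))))
  }
  theta <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
  g <- 1 + sh$amp * sin(sh$m * theta + sh$phase)
  x <- sh$a * g * cos(theta)
  y <- sh$b * g * sin(theta)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  area <- abs(sum(xs[-1] * ys[-length(ys)] - xs[-length(xs)] * ys[-1])) / 2
  perim <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  list(area = area, perimeter = perim)
}

placeShapes <- function(shapes, H, W, placed = list(), maxAttempts = 10000L) {
  attempts <- 0L
  out <- placed
  for (sh in shapes) {
    R <- shapeOuterRadius(sh)
    repeat {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        dataError(sprintf(
          "shape placement failed after %d rejection attempts: raster too crowded for the requested shapes",
          maxAttempts))
      cx <- runif(1, R + 2, W - R - 1)
      cy <- runif(1, R + 2, H - R - 1)
      ok <- TRUE
      for (p in out) {
        # conservative bounding-circle test with a 2 px guard band keeps
        # shapes disjoint, which the per-nest ground truth requires
        if ((cx - p$cx)^2 + (cy - p$cy)^2 <
            (R + shapeOuterRadius(p) + 2)^2) { ok <- FALSE; break }
      }
      if (ok) { sh$cx <- cx; sh$cy <- cy; out <- c(out, list(sh)); break }
    }
  }
  out[seq(length(placed) + 1L, length.out = length(shapes))]
}

# Unstained structures; sizes scale with the raster so small desk-scale
# images stay placeable.
sampleDistractor <- function(H, W) {
  s <- min(H, W)
  kind <- sample(c("nerve", "vessel"), 1)
  if (kind == "nerve") {
    a <- runif(1, 0.028, 0.06) * s
    sh <- list(family = "ellipse", a = a, b = runif(1, 2, 4),
               angle = runif(1, 0, pi), amp = 0, m = 0L, phase = 0,
               kind = "nerve")
  } else {
    r <- runif(1, 0.012, 0.024) * s
    sh <- list(family = "circle", a = r, b = r, angle = 0, amp = 0, m = 0L,
               phase = 0, kind = "vessel", inner = 0.55 * r)
  }
  sh
}

#' Render a synthetic core image with ground truth
#'
#' Draws \code{n_nests} non-overlapping nest shapes (rejection sampling with a
#' hard attempt cap; a crowded raster raises an error rather than silently
#' dropping nests), renders them in the foreground stain color on the
#' background color, adds unstained distractor structures and optional
#' Gaussian noise, and returns both the image and the exact ground truth.
#'
#' @param spec a [syntheticImageSpec()].
#' @param coreId,patientId identifiers stored in the returned image.
#' @return list with elements \describe{
#'   \item{image}{a [CoreImage-class].}
#'   \item{truth}{list with \code{labelMask} (integer matrix, 0 background,
#'     k = nest k in placement order) and \code{nests}, a data frame with one
#'     row per nest: \code{nest_id}, \code{cx}, \code{cy}, \code{area_analytic},
#'     \code{perimeter_analytic}, \code{area_px} (rendered pixel count).}
#' }
#' @export
simulateCoreImage <- function(spec, coreId = "core1", patientId = "patient1") {
  stopifnot(inherits(spec, "SyntheticImageSpec"))
  H <- spec$height_px; W <- spec$width_px
  withSeed(spec$seed, {
    nests <- lapply(seq_len(spec$n_nests), function(i)
      sampleShape(spec$shape_family, spec$size_range_px))
    nests <- placeShapes(nests, H, W)
    distr <- lapply(seq_len(spec$n_distractors), function(i) sampleDistractor(H, W))
    distr <- placeShapes(distr, H, W, placed = nests)

    labelMask <- matrix(0L, H, W)
    img <- array(0, dim = c(H, W, 3))
    bg <- spec$stain_bg_rgb / 255
    for (ch in 1:3) img[, , ch] <- bg[ch]

    fg <- spec$stain_fg_rgb / 255
    for (k in seq_along(nests)) {
      ras <- rasterizeShape(nests[[k]], H, W)
      sub <- labelMask[ras$rows, ras$cols]
      sub[ras$inside] <- k
      labelMask[ras$rows, ras$cols] <- sub
      for (ch in 1:3) {
        plane <- img[, , ch]
        psub <- plane[ras$rows, ras$cols]
        psub[ras$inside] <- fg[ch]
        plane[ras$rows, ras$cols] <- psub
        img[, , ch] <- plane
      }
    }

    dcol <- spec$distractor_rgb / 255
    for (d in distr) {
      ras <- rasterizeShape(d, H, W)
      inside <- ras$inside
      if (identical(d$kind, "vessel")) {
        # annular lumen: hollow out the center, like a vessel cross-section
        dr <- d; dr$a <- d$inner; dr$b <- d$inner
        rin <- rasterizeShape(dr, H, W)
        hole <- matrix(FALSE, length(ras$rows), length(ras$cols))
        ri <- match(rin$rows, ras$rows); ci <- match(rin$cols, ras$cols)
        hole[ri, ci] <- rin$inside
        inside <- inside & !hole
      }
      for (ch in 1:3) {
        plane <- img[, , ch]
        psub <- plane[ras$rows, ras$cols]
        psub[inside] <- dcol[ch]
        plane[ras$rows, ras$cols] <- psub
        img[, , ch] <- plane
      }
    }

    if (spec$noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, spec$noise_sd / 255), dim(img))
      img[img < 0] <- 0; img[img > 1] <- 1
    }

    nestTab <- if (length(nests)) {
      do.call(rbind, lapply(seq_along(nests), function(k) {
        an <- shapeAnalytic(nests[[k]])
        data.frame(nest_id = k, cx = nests[[k]]$cx, cy = nests[[k]]$cy,
                   area_analytic = an$area, perimeter_analytic = an$perimeter,
                   area_px = sum(labelMask == k))
      }))
    } else {
      data.frame(nest_id = integer(), cx = numeric(), cy = numeric(),
                 area_analytic = numeric(), perimeter_analytic = numeric(),
                 area_px = integer())
    }

    list(image = coreImage(img, coreId, patientId),
         truth = list(labelMask = labelMask, nests = nestTab))
  })
}
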