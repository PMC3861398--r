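# Segmentation of DAB-stained tumor nests: stain separation, adaptive Otsu
# binarization, morphological opening, hole filling, boundary extraction and
# 8-connected labeling with a minimum object size. Connectivity pairing is
# the standard digital-topology choice: 8-connected foreground, 4-connected
# background.

# Ruifrok-Johnston H-DAB stain vectors (optical-density space, rows
# normalized): hematoxylin, DAB, and their residual (cross product).
hdabStainMatrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(h / sqrt(sum(h^2)), d / sqrt(sum(d^2)), r / sqrt(sum(r^2)))
  rownames(m) <- c("hematoxylin", "dab", "residual")
  m
}

#' Extract the DAB stain channel from an RGB core image
#'
#' Converts the image to optical density, unmixes it with the standard
#' published H-DAB stain vectors (robust to the hematoxylin counterstain),
#' median-filters the DAB concentration to suppress speckle noise, and
#' linearly stretches the result to [0, 1]. A constant input image cannot be
#' stretched; the stretch is then skipped and the returned channel is flagged
#' degenerate.
#'
#' @param image a [CoreImage-class].
#' @param denoiseRadius median-filter radius in pixels (0 disables filtering).
#' @return a [StainChannel-class] (provenance \code{"deconvolution"}).
#' @export
preprocessCore <- function(image, denoiseRadius = 1L) {
  stopifnot(is(image, "CoreImage"))
  px <- imagePixels(image)
  H <- dim(px)[1]; W <- dim(px)[2]
  # optical density; +1/256 guards log(0) on saturated black pixels
  od <- -log10((matrix(px, ncol = 3L) * 255 + 1) / 256)
  conc <- od %*% solve(hdabStainMatrix())
  dab <- matrix(conc[, 2L], H, W)
  rng <- range(dab)
  if (rng[2] - rng[1] < 1e-12) {
    return(new("StainChannel", values = dab, provenance = "deconvolution",
               degenerate = TRUE))
  }
  dab <- (dab - rng[1]) / (rng[2] - rng[1])
  if (denoiseRadius > 0) {
    dab <- if (denoiseRadius == 1L) median3x3(dab) else
      matrix(as.numeric(EBImage::medianFilter(dab,
                                              size = as.integer(denoiseRadius))),
             H, W)
    rng <- range(dab)
    if (rng[2] - rng[1] < 1e-12)
      return(new("StainChannel", values = dab, provenance = "deconvolution",
                 degenerate = TRUE))
    dab <- (dab - rng[1]) / (rng[2] - rng[1])
  }
  new("StainChannel", values = dab, provenance = "deconvolution",
      degenerate = FALSE)
}

#' Otsu binarization of a stain channel
#'
#' Thresholds at the maximizer of the between-class variance computed on a
#' 256-bin histogram of [0, 1]; foreground is strictly above the threshold.
#'
#' @param channel a [StainChannel-class] or numeric matrix with values in
#'   [0, 1].
#' @return logical foreground mask with the threshold stored in
#'   \code{attr(, "threshold")}.
#' @export
binarizeOtsu <- function(channel) {
  v <- if (is(channel, "StainChannel")) channelValues(channel) else channel
  stopifnot(is.matrix(v))
  if (length(unique(as.vector(v))) < 2L)
    statError("degenerate histogram: channel has fewer than 2 distinct values")
  th <- otsuThreshold256(v)
  mask <- v > th
  attr(mask, "threshold") <- as.numeric(th)
  mask
}

# Textbook Otsu on a 256-bin histogram of [0, 1]: split after bin k
# partitions the bins into 1..k and (k+1)..256; the threshold is the upper
# edge of bin k maximizing w1 * w2 * (mu1 - mu2)^2 (first maximum on ties),
# so thresholding with a strict > reproduces the optimal class split.
otsuThreshold256 <- function(v) {
  bins <- pmin(pmax(floor(as.vector(v) * 256) + 1L, 1L), 256L)
  counts <- as.numeric(tabulate(bins, nbins = 256L))  # doubles: w1*w2 can exceed 2^31
  mids <- (seq_len(256L) - 0.5) / 256
  w1 <- cumsum(counts)
  m1 <- cumsum(counts * mids)
  tot <- w1[256L]; mtot <- m1[256L]
  k <- 1:255
  w2 <- tot - w1[k]
  bc <- ifelse(w1[k] > 0 & w2 > 0,
               w1[k] * w2 * (m1[k] / w1[k] - (mtot - m1[k]) / w2)^2, -Inf)
  which.max(bc) / 256
}

#' Morphological opening with a disk structuring element
#'
#' Erosion followed by dilation; smooths silhouettes, separates thin bridges
#' between adjacent nests and removes protrusions smaller than the element.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels; 0 returns the mask unchanged.
#' @return logical matrix.
#' @export
morphOpen <- function(mask, radius = 2L) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (radius <= 0) return(mask)
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::opening(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                          kern)
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

#' Fill interior holes of a binary mask
#'
#' Every background component not 4-connected to the raster border becomes
#' foreground, restoring the morphological integrity of nests whose interior
#' stained weakly.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fillHoles <- function(mask) {
  stopifnot(is.matrix(mask))
  out <- EBImage::fillHull(matrix(as.numeric(mask > 0), nrow(mask),
                                  ncol(mask)))
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

# Vectorized 3x3 median filter (edge-replicated borders) via the classic
# 19-comparison median-of-9 sorting network; orders of magnitude faster in R
# than a general-radius median for the common radius-1 case.
median3x3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- rbind(m[1, , drop = FALSE], m, m[H, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, W, drop = FALSE])
  p <- vector("list", 9L)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    p[[k]] <- pad[dr + seq_len(H), dc + seq_len(W)]
  }
  srt <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); p[[j]] <<- pmax(p[[i]], p[[j]]); p[[i]] <<- lo
  }
  srt(2, 3); srt(5, 6); srt(8, 9)
  srt(1, 2); srt(4, 5); srt(7, 8)
  srt(2, 3); srt(5, 6); srt(8, 9)
  srt(1, 4); srt(6, 9); srt(5, 8)
  srt(4, 7); srt(2, 5); srt(3, 6)
  srt(5, 8); srt(5, 3); srt(7, 5)
  srt(5, 3)
  p[[5]]
}

# Foreground pixels with at least one 4-neighbour in the background; pixels
# on the raster rim count the outside as background. On a binary mask this
# is the inner morphological gradient, the pixel set a Sobel edge detector
# lights up on solid regions.
innerBoundary4 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bgUp <- rbind(TRUE, !mask[-H, , drop = FALSE])
  bgDown <- rbind(!mask[-1, , drop = FALSE], TRUE)
  bgLeft <- cbind(TRUE, !mask[, -W, drop = FALSE])
  bgRight <- cbind(!mask[, -1, drop = FALSE], TRUE)
  mask & (bgUp | bgDown | bgLeft | bgRight)
}

#' Extract boundary map and per-nest contours from a binary mask
#'
#' The boundary map marks foreground pixels adjacent (4-neighbourhood) to
#' background — the inner gradient of the mask, i.e. the edge pixels of each
#' nest. Contours are closed 8-connected Moore traces through boundary-pixel
#' centers, one per 8-connected component, in raster-scan order.
#'
#' @param mask logical matrix.
#' @return list with \code{boundaryMap} (logical matrix) and \code{contours}
#'   (list of closed (row, col) matrices).
#' @export
extractBoundaries <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  lab <- relabelRasterOrder(label8(mask))
  list(boundaryMap = innerBoundary4(mask), contours = traceAllComponents(lab))
}

#' Apply a pathologist-style override raster to a mask
#'
#' Non-interactive stand-in for expert correction of the automatic
#' segmentation: an override raster of the same shape forces pixels to
#' foreground (code 1 = add) or background (code 2 = remove) and leaves
#' code-0 pixels untouched.
#'
#' @param mask logical matrix.
#' @param override integer matrix of the same shape with values 0 (keep),
#'   1 (add), 2 (remove).
#' @return logical matrix.
#' @export
applyOverrides <- function(mask, override) {
  stopifnot(is.matrix(mask))
  if (!is.matrix(override) || !all(dim(override) == dim(mask)))
    dataError("override raster must have the same shape as the mask")
  if (!all(override %in% c(0L, 1L, 2L)))
    dataError("override values must be 0 (keep), 1 (add) or 2 (remove)")
  out <- mask > 0
  out[override == 1L] <- TRUE
  out[override == 2L] <- FALSE
  out
}

#' Label tumor nests in a binary mask
#'
#' 8-connected component labeling; components smaller than \code{minSize}
#' pixels are discarded (automated proxy for expert deletion of noise
#' signals) and surviving labels are renumbered 1..n in raster-scan order of
#' each nest's first pixel. Components touching the raster rim are kept —
#' a circular core field gives no natural exclusion rule — but their labels
#' are flagged.
#'
#' @param mask logical matrix.
#' @param minSize minimum object size in pixels.
#' @param extraParams named list merged into the \code{paramsUsed} record.
#' @return a [NestSegmentation-class]; zero nests is a valid result.
#' @export
labelNests <- function(mask, minSize = 50L, extraParams = list()) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  lab <- label8(mask)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < minSize)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabelRasterOrder(lab)
  }
  n <- max(lab)
  cts <- traceAllComponents(lab)
  H <- nrow(lab); W <- ncol(lab)
  touching <- if (n > 0L) {
    rim <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
    sort(as.integer(rim[rim > 0L]))
  } else integer()
  params <- c(list(min_size = as.integer(minSize),
                   connectivity = "8-connected foreground, 4-connected background",
                   perimeter_convention = "Moore contour through boundary-pixel centers, diagonal steps sqrt(2)"),
              extraParams)
  storage.mode(lab) <- "integer"
  new("NestSegmentation", labelMask = lab, contours = cts,
      boundaryMap = innerBoundary4(lab > 0L), borderTouching = touching,
      paramsUsed = params)
}

#' Full nest-segmentation pipeline for one core
#'
#' Runs stain separation, Otsu binarization, morphological opening, hole
#' filling, optional override application and labeling in sequence. A core
#' whose stain channel is degenerate (no contrast at all) yields an empty
#' segmentation flagged in \code{paramsUsed$degenerate} rather than an error,
#' so cohort-scale runs survive blank cores.
#'
#' @param image a [CoreImage-class].
#' @param denoiseRadius median-filter radius passed to [preprocessCore()].
#' @param openingRadius disk radius passed to [morphOpen()].
#' @param minSize minimum nest size in pixels passed to [labelNests()].
#' @param override optional override raster for [applyOverrides()].
#' @return a [NestSegmentation-class] with the threshold and all settings in
#'   \code{paramsUsed}.
#' @export
segmentCore <- function(image, denoiseRadius = 1L, openingRadius = 2L,
                        minSize = 50L, override = NULL) {
  stopifnot(is(image, "CoreImage"))
  channel <- preprocessCore(image, denoiseRadius = denoiseRadius)
  base <- list(denoise_radius = as.integer(denoiseRadius),
               opening_radius = as.integer(openingRadius),
               core_id = coreId(image), patient_id = patientId(image))
  if (isDegenerate(channel)) {
    warning(sprintf("core %s: degenerate stain channel, empty segmentation",
                    coreId(image)))
    empty <- matrix(0L, nrow(channelValues(channel)),
                    ncol(channelValues(channel)))
    return(labelNests(empty > 0L, minSize = minSize,
                      extraParams = c(base, list(threshold = NA_real_,
                                                 degenerate = TRUE))))
  }
  mask <- binarizeOtsu(channel)
  th <- attr(mask, "threshold")
  mask <- morphOpen(mask, radius = openingRadius)
  mask <- fillHoles(mask)
  if (!is.null(override)) mask <- applyOverrides(mask, override)
  labelNests(mask, minSize = minSize,
             extraParams = c(base, list(threshold = th, degenerate = FALSE)))
}
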