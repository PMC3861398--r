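# The eight nest-morphology parameters of one core. Areas are pixel counts;
# perimeters are Moore-contour lengths (axial step 1, diagonal step sqrt(2)).
# All geometric quantities stay in pixel units.

#' Measure one nest
#'
#' @param segmentation a [NestSegmentation-class].
#' @param nestId integer label of the nest.
#' @return data frame row with \code{nest_id}, \code{area_px} (pixel count)
#'   and \code{perimeter_px} (closed Moore-contour length; an isolated single
#'   pixel is assigned perimeter 1 so the value is always positive).
#' @export
measureNest <- function(segmentation, nestId) {
  stopifnot(is(segmentation, "NestSegmentation"))
  n <- nNests(segmentation)
  if (!(nestId %in% seq_len(n)))
    dataError(sprintf("nest id %s not present (segmentation has %d nests)",
                      format(nestId), n))
  area <- sum(labelMask(segmentation) == nestId)
  perim <- contourLength(contours(segmentation)[[nestId]])
  if (perim <= 0) perim <- 1
  data.frame(nest_id = as.integer(nestId), area_px = area,
             perimeter_px = perim)
}

#' Measure all nests of a segmentation
#'
#' @param segmentation a [NestSegmentation-class].
#' @return data frame with one row per nest (\code{nest_id}, \code{area_px},
#'   \code{perimeter_px}); zero rows for an empty segmentation.
#' @export
nestShapes <- function(segmentation) {
  stopifnot(is(segmentation, "NestSegmentation"))
  n <- nNests(segmentation)
  if (n == 0L)
    return(data.frame(nest_id = integer(), area_px = numeric(),
                      perimeter_px = numeric()))
  areas <- tabulate(labelMask(segmentation), nbins = n)
  perims <- vapply(contours(segmentation), contourLength, numeric(1))
  perims[perims <= 0] <- 1
  data.frame(nest_id = seq_len(n), area_px = areas, perimeter_px = perims)
}

#' Compute the eight core-level morphology parameters
#'
#' Given per-nest areas A_i and perimeters P_i, computes: number n;
#' total_perimeter = sum P_i; average_perimeter = sum P_i / n; total_area =
#' sum A_i; average_area = sum A_i / n; ta_over_tp = sum A_i / sum P_i;
#' avg_a_over_p = (1/n) sum (A_i / P_i); circularity = (1/n) sum
#' (4 pi A_i / P_i^2). Circularity is 1 for a perfect disk and smaller for
#' irregular shapes; it is not clamped at 1 because digitization can push
#' small near-circular objects slightly above it.
#'
#' @param shapes data frame with columns \code{area_px} and
#'   \code{perimeter_px}, one row per nest (e.g. from [nestShapes()]); an
#'   empty data frame yields a degenerate record.
#' @param coreId identifier copied into the output.
#' @return one-row data frame with columns \code{core_id}, \code{number},
#'   \code{total_perimeter}, \code{average_perimeter}, \code{total_area},
#'   \code{average_area}, \code{ta_over_tp}, \code{avg_a_over_p},
#'   \code{circularity}, \code{degenerate}. For a core without nests the
#'   counts and totals are 0, the ratio/average fields are \code{NA} and
#'   \code{degenerate} is \code{TRUE}.
#' @export
computeCoreFeatures <- function(shapes, coreId = "core1") {
  stopifnot(is.data.frame(shapes))
  n <- nrow(shapes)
  if (n == 0L)
    return(data.frame(core_id = as.character(coreId), number = 0L,
                      total_perimeter = 0, average_perimeter = NA_real_,
                      total_area = 0, average_area = NA_real_,
                      ta_over_tp = NA_real_, avg_a_over_p = NA_real_,
                      circularity = NA_real_, degenerate = TRUE))
  A <- as.numeric(shapes$area_px)
  P <- as.numeric(shapes$perimeter_px)
  if (any(P <= 0)) dataError("all nest perimeters must be positive")
  data.frame(core_id = as.character(coreId), number = n,
             total_perimeter = sum(P), average_perimeter = sum(P) / n,
             total_area = sum(A), average_area = sum(A) / n,
             ta_over_tp = sum(A) / sum(P),
             avg_a_over_p = mean(A / P),
             circularity = mean(4 * pi * A / P^2),
             degenerate = FALSE)
}

#' Segment a core image and compute its feature row
#'
#' Convenience wrapper: [segmentCore()] then [nestShapes()] and
#' [computeCoreFeatures()].
#'
#' @inheritParams segmentCore
#' @return list with \code{segmentation}, \code{shapes} and \code{features}.
#' @export
coreFeaturePipeline <- function(image, denoiseRadius = 1L, openingRadius = 2L,
                                minSize = 50L, override = NULL) {
  seg <- segmentCore(image, denoiseRadius = denoiseRadius,
                     openingRadius = openingRadius, minSize = minSize,
                     override = override)
  shp <- nestShapes(seg)
  list(segmentation = seg, shapes = shp,
       features = computeCoreFeatures(shp, coreId = coreId(image)))
}
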