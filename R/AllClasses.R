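#' @import methods
#' @importFrom stats rnorm rexp runif median pchisq pnorm qnorm quantile setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' CoreImage: one RGB tissue-core raster
#'
#' Container for a single brightfield core image together with its core and
#' patient identifiers. Pixels are stored as an H x W x 3 numeric array with
#' intensities in [0, 1] (8-bit images are divided by 255 on import).
#'
#' @slot pixels numeric array, H x W x 3, values in [0, 1].
#' @slot coreId character scalar identifying the core.
#' @slot patientId character scalar identifying the patient the core came from.
#'
#' @seealso [coreImage()], [simulateCoreImage()], [segmentCore()]
#' @export
setClass("CoreImage",
  representation(pixels = "array", coreId = "character", patientId = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("'pixels' must be an H x W x 3 array")
    if (d[1] < 32L || d[2] < 32L)
      return("image must be at least 32 x 32 pixels")
    if (anyNA(object@pixels) || min(object@pixels) < 0 || max(object@pixels) > 1)
      return("pixel values must lie in [0, 1]")
    if (length(object@coreId) != 1L || length(object@patientId) != 1L)
      return("'coreId' and 'patientId' must be length-1 character")
    TRUE
  })

#' StainChannel: scalar DAB-positivity raster
#'
#' Single-channel image in which higher values indicate more DAB (brown
#' chromogen) signal, produced by [preprocessCore()]. Carries a provenance tag
#' and a degeneracy flag (set when the source image was constant and the
#' contrast stretch had to be skipped).
#'
#' @slot values numeric matrix, same H x W as the source image, finite values.
#' @slot provenance character, one of \code{"deconvolution"} or
#'   \code{"luminance"}.
#' @slot degenerate logical flag; \code{TRUE} when the input image carried no
#'   contrast and the channel is constant.
#'
#' @export
setClass("StainChannel",
  representation(values = "matrix", provenance = "character",
                 degenerate = "logical"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("channel values must be finite")
    if (!object@provenance %in% c("deconvolution", "luminance"))
      return("provenance must be 'deconvolution' or 'luminance'")
    TRUE
  })

#' NestSegmentation: labeled tumor-nest mask with boundaries
#'
#' Result of the segmentation pipeline for one core: an integer label mask
#' (0 = background, k = nest k, labels consecutive in raster-scan order of
#' each nest's first pixel), per-nest closed boundary contours traced through
#' boundary-pixel centers, a binary boundary map, the labels of nests touching
#' the image rim, and a record of the parameters used.
#'
#' @slot labelMask integer matrix; 0 background, k = nest k.
#' @slot contours list of n two-column (row, col) matrices; each closed
#'   (first vertex equals last vertex), 8-connected.
#' @slot boundaryMap logical matrix marking foreground pixels that have at
#'   least one 4-neighbour in the background.
#' @slot borderTouching integer vector of labels whose nests touch the rim
#'   (kept, but flagged, because a circular core field has no natural
#'   exclusion rule).
#' @slot paramsUsed named list recording threshold, opening radius, minimum
#'   object size and related settings.
#'
#' @seealso [segmentCore()], [labelNests()], [measureNest()]
#' @export
setClass("NestSegmentation",
  representation(labelMask = "matrix", contours = "list",
                 boundaryMap = "matrix", borderTouching = "integer",
                 paramsUsed = "list"),
  validity = function(object) {
    labs <- sort(unique(as.integer(object@labelMask)))
    labs <- labs[labs > 0L]
    n <- length(labs)
    if (n > 0L && !identical(labs, seq_len(n)))
      return("labels must be consecutive 1..n")
    if (length(object@contours) != n)
      return("one contour per labeled nest required")
    for (ct in object@contours) {
      if (!is.matrix(ct) || ncol(ct) != 2L || nrow(ct) < 2L)
        return("contours must be (row, col) matrices with >= 2 vertices")
      if (!all(ct[1L, ] == ct[nrow(ct), ]))
        return("contours must be closed (first vertex == last vertex)")
    }
    TRUE
  })

#' CutpointResult: survival-driven two-cutpoint grading of one parameter
#'
#' Output of the exhaustive best-P two-cutpoint search ([searchCutpoints()]):
#' the optimal pair of cutpoints on the parameter's own scale, the induced
#' three-level grade assignment (I: v <= cut1; II: cut1 < v <= cut2;
#' III: v > cut2), the maximized 2-df log-rank statistic, and both the
#' uncorrected best-P p-value and a multiplicity-corrected p-value.
#'
#' @slot parameterName character; which parameter was graded.
#' @slot cut1,cut2 numeric cutpoints, cut1 < cut2.
#' @slot grades factor with levels I, II, III; one per patient.
#' @slot logrankChisq numeric; maximized 2-df log-rank chi-square.
#' @slot pValue numeric; uncorrected p from the chi-square (2 df). Because the
#'   cutpoints were chosen to maximize this statistic, this p-value is
#'   anti-conservative and is reported as the uncorrected best-P value.
#' @slot pValueCorrected numeric; selection-corrected p-value (see
#'   [searchCutpoints()] for the correction used).
#' @slot groupSizes integer vector (nI, nII, nIII).
#' @slot nCandidates integer; number of feasible cutpoint pairs searched.
#'
#' @export
setClass("CutpointResult",
  representation(parameterName = "character", cut1 = "numeric",
                 cut2 = "numeric", grades = "factor",
                 logrankChisq = "numeric", pValue = "numeric",
                 pValueCorrected = "numeric", groupSizes = "integer",
                 nCandidates = "integer"),
  validity = function(object) {
    if (object@cut1 >= object@cut2) return("cut1 must be < cut2")
    if (!identical(levels(object@grades), c("I", "II", "III")))
      return("grades must be a factor with levels I, II, III")
    if (sum(object@groupSizes) != length(object@grades))
      return("group sizes must partition the cohort")
    TRUE
  })
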