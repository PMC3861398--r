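# Accessor generics for the S4 containers. Slot access from user code should
# go through these, not @.

#' @rdname CoreImage-class
#' @param object a \code{CoreImage}, \code{StainChannel},
#'   \code{NestSegmentation} or \code{CutpointResult}.
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))

#' @rdname CoreImage-class
#' @export
setGeneric("coreId", function(object) standardGeneric("coreId"))

#' @rdname CoreImage-class
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))

#' @rdname StainChannel-class
#' @export
setGeneric("channelValues", function(object) standardGeneric("channelValues"))

#' @rdname StainChannel-class
#' @export
setGeneric("isDegenerate", function(object) standardGeneric("isDegenerate"))

#' @rdname NestSegmentation-class
#' @export
setGeneric("labelMask", function(object) standardGeneric("labelMask"))

#' @rdname NestSegmentation-class
#' @export
setGeneric("contours", function(object) standardGeneric("contours"))

#' @rdname NestSegmentation-class
#' @export
setGeneric("boundaryMap", function(object) standardGeneric("boundaryMap"))

#' @rdname NestSegmentation-class
#' @export
setGeneric("nNests", function(object) standardGeneric("nNests"))

#' @rdname NestSegmentation-class
#' @export
setGeneric("paramsUsed", function(object) standardGeneric("paramsUsed"))

#' @rdname CutpointResult-class
#' @export
setGeneric("cutpoints", function(object) standardGeneric("cutpoints"))

#' @rdname CutpointResult-class
#' @export
setGeneric("grades", function(object) standardGeneric("grades"))

setMethod("imagePixels", "CoreImage", function(object) object@pixels)
setMethod("coreId", "CoreImage", function(object) object@coreId)
setMethod("patientId", "CoreImage", function(object) object@patientId)
setMethod("channelValues", "StainChannel", function(object) object@values)
setMethod("isDegenerate", "StainChannel", function(object) object@degenerate)
setMethod("labelMask", "NestSegmentation", function(object) object@labelMask)
setMethod("contours", "NestSegmentation", function(object) object@contours)
setMethod("boundaryMap", "NestSegmentation", function(object) object@boundaryMap)
setMethod("nNests", "NestSegmentation",
          function(object) length(object@contours))
setMethod("paramsUsed", "NestSegmentation", function(object) object@paramsUsed)
setMethod("cutpoints", "CutpointResult",
          function(object) c(cut1 = object@cut1, cut2 = object@cut2))
setMethod("grades", "CutpointResult", function(object) object@grades)

setMethod("show", "CoreImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CoreImage %s (patient %s): %d x %d RGB\n",
              object@coreId, object@patientId, d[1], d[2]))
})

setMethod("show", "StainChannel", function(object) {
  cat(sprintf("StainChannel (%s): %d x %d, range [%.3f, %.3f]%s\n",
              object@provenance, nrow(object@values), ncol(object@values),
              min(object@values), max(object@values),
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "NestSegmentation", function(object) {
  n <- length(object@contours)
  cat(sprintf("NestSegmentation: %d nest%s on %d x %d raster\n",
              n, if (n == 1L) "" else "s",
              nrow(object@labelMask), ncol(object@labelMask)))
  if (length(object@borderTouching))
    cat("  nests touching image rim (kept, flagged):",
        paste(object@borderTouching, collapse = ", "), "\n")
  pu <- object@paramsUsed
  if (length(pu))
    cat("  params:", paste(names(pu), unlist(lapply(pu, format)),
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CutpointResult", function(object) {
  cat(sprintf("CutpointResult '%s': cut1=%.6g cut2=%.6g\n",
              object@parameterName, object@cut1, object@cut2))
  cat(sprintf("  groups I/II/III: %s; log-rank chi2(2df)=%.4f\n",
              paste(object@groupSizes, collapse = "/"), object@logrankChisq))
  cat(sprintf("  p (uncorrected best-P) = %.4g; p (corrected) = %.4g\n",
              object@pValue, object@pValueCorrected))
})
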