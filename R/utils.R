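# Internal helpers.

# All generator randomness is scoped with withr::with_seed so no call touches
# the global RNG stream.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopIfNot <- function(cond, msg, class = "nestmorph_error") {
  if (!isTRUE(cond))
    stop(errorCondition(msg, class = c(class, "error", "condition")))
  invisible(TRUE)
}

dataError <- function(msg) {
  stop(errorCondition(msg,
       class = c("nestmorph_data_error", "nestmorph_error", "error", "condition")))
}

configError <- function(msg) {
  stop(errorCondition(msg,
       class = c("nestmorph_config_error", "nestmorph_error", "error", "condition")))
}

statError <- function(msg) {
  stop(errorCondition(msg,
       class = c("nestmorph_stat_error", "nestmorph_error", "error", "condition")))
}

#' Construct a CoreImage
#'
#' @param pixels H x W x 3 numeric array in [0, 1], or an integer array in
#'   0..255 (rescaled automatically).
#' @param coreId,patientId identifier strings.
#' @return a [CoreImage-class] object.
#' @export
coreImage <- function(pixels, coreId = "core1", patientId = "patient1") {
  if (max(pixels) > 1) pixels <- pixels / 255
  new("CoreImage", pixels = pixels, coreId = as.character(coreId),
      patientId = as.character(patientId))
}
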