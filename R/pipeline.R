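# Orchestration: configuration, staged execution (simulate -> features ->
# grade -> survival -> report), manifests with checksums and timings. Stage
# outputs are plain CSV/JSON/PNG/TIFF so any stage can be inspected or its
# inputs replaced; a rerun of a stage only needs the files of the stage
# before it.

#' Build a pipeline run configuration
#'
#' Defaults mirror a two-cores-per-patient study of 202 patients (404 cores)
#' followed for five years. The synthetic study wires a per-patient latent
#' aggressiveness level (1..3) into both the images and the hazard: higher
#' levels show more, rounder nests (raising nest number, total perimeter and
#' circularity together, the direction in which those three parameters carry
#' risk) and a proportionally higher recurrence hazard, so a correctly
#' working pipeline recovers the association between integrated score 1 and
#' survival.
#'
#' @param out_dir output directory of the run.
#' @param n_patients,cores_per_patient cohort design (default 202 x 2).
#' @param width_px,height_px,noise_sd,n_distractors passed to the per-core
#'   image specs.
#' @param n_nests_min,n_nests_max integer vectors of length 3: nest-count
#'   range per latent level. More aggressive levels carry more nests.
#' @param size_min,size_max numeric vectors of length 3: nest radius range
#'   per latent level. Aggressive tumors fragment into many small nests, so
#'   the defaults shrink with the level; together with rounder shapes this
#'   drives the per-nest size parameters (average area, average perimeter
#'   and both area-to-perimeter ratios) down as risk rises.
#' @param shape_by_level shape family per latent level.
#' @param baseline_hazard,log_hr_per_level,censoring_rate,followup_horizon
#'   survival generator: hazard = baseline * exp(log_hr_per_level *
#'   (level - 2) + covariate effects), exponential censoring, administrative
#'   censoring at the horizon (months).
#' @param covariate_effects named log-hazard coefficients for the clinical
#'   covariates.
#' @param denoise_radius,opening_radius,min_size segmentation parameters.
#' @param min_frac minimum grading group fraction.
#' @param core_aggregation how to combine the cores of a patient into
#'   patient-level features: \code{"mean"} (default), \code{"max"} or
#'   \code{"first"}, over non-degenerate cores.
#' @param seed master seed; all stage randomness derives from it.
#' @return a validated \code{RunConfig} (named list).
#' @export
runConfig <- function(out_dir = "nestmorph_run",
                      n_patients = 202L, cores_per_patient = 2L,
                      width_px = 512L, height_px = 512L, noise_sd = 4,
                      n_distractors = 3L,
                      n_nests_min = c(6L, 13L, 22L),
                      n_nests_max = c(10L, 18L, 30L),
                      size_min = c(14, 11, 9),
                      size_max = c(26, 20, 16),
                      shape_by_level = c("blob", "ellipse", "circle"),
                      baseline_hazard = 0.009,
                      log_hr_per_level = log(1.8),
                      censoring_rate = 0.004, followup_horizon = 60,
                      covariate_effects = c(t_stage = log(1.3),
                                            n_stage = log(1.3),
                                            hist_grade = log(1.4),
                                            hormone_receptor = log(0.7),
                                            her2 = 0),
                      denoise_radius = 1L, opening_radius = 2L,
                      min_size = 50L, min_frac = 0.10,
                      core_aggregation = "mean", seed = 1L) {
  cfg <- list(out_dir = out_dir,
              n_patients = as.integer(n_patients),
              cores_per_patient = as.integer(cores_per_patient),
              width_px = as.integer(width_px),
              height_px = as.integer(height_px),
              noise_sd = as.numeric(noise_sd),
              n_distractors = as.integer(n_distractors),
              n_nests_min = as.integer(n_nests_min),
              n_nests_max = as.integer(n_nests_max),
              size_min = as.numeric(size_min),
              size_max = as.numeric(size_max),
              shape_by_level = as.character(shape_by_level),
              baseline_hazard = as.numeric(baseline_hazard),
              log_hr_per_level = as.numeric(log_hr_per_level),
              censoring_rate = as.numeric(censoring_rate),
              followup_horizon = as.numeric(followup_horizon),
              covariate_effects = covariate_effects,
              denoise_radius = as.integer(denoise_radius),
              opening_radius = as.integer(opening_radius),
              min_size = as.integer(min_size),
              min_frac = as.numeric(min_frac),
              core_aggregation = match.arg(core_aggregation,
                                           c("mean", "max", "first")),
              seed = as.integer(seed))
  if (cfg$n_patients < 1L) configError("n_patients must be positive")
  if (cfg$cores_per_patient < 1L) configError("cores_per_patient must be positive")
  if (length(cfg$n_nests_min) != 3L || length(cfg$n_nests_max) != 3L ||
      any(cfg$n_nests_max < cfg$n_nests_min) || any(cfg$n_nests_min < 0L))
    configError("n_nests_min/max must be valid length-3 level ranges")
  if (length(cfg$size_min) != 3L || length(cfg$size_max) != 3L ||
      any(cfg$size_max < cfg$size_min) || any(cfg$size_min < 2))
    configError("size_min/max must be valid length-3 radius ranges (>= 2)")
  if (length(cfg$shape_by_level) != 3L ||
      !all(cfg$shape_by_level %in% c("circle", "ellipse", "blob")))
    configError("shape_by_level must name 3 shape families")
  if (cfg$min_frac <= 0 || cfg$min_frac >= 0.5)
    configError("min_frac must be in (0, 0.5)")
  if (cfg$baseline_hazard <= 0 || cfg$censoring_rate <= 0 ||
      cfg$followup_horizon <= 0)
    configError("hazard, censoring rate and horizon must be positive")
  class(cfg) <- "RunConfig"
  cfg
}

#' @export
print.RunConfig <- function(x, ...) {
  cat(sprintf("RunConfig: %d patients x %d cores, %dx%d px, seed %d -> %s\n",
              x$n_patients, x$cores_per_patient, x$width_px, x$height_px,
              x$seed, x$out_dir))
  invisible(x)
}

pipelinePaths <- function(cfg) {
  list(images = file.path(cfg$out_dir, "images"),
       masks = file.path(cfg$out_dir, "truth_masks"),
       clinical = file.path(cfg$out_dir, "clinical.csv"),
       truthNests = file.path(cfg$out_dir, "truth_nests.csv"),
       featuresCores = file.path(cfg$out_dir, "features_cores.csv"),
       nests = file.path(cfg$out_dir, "nests.csv"),
       featuresPatients = file.path(cfg$out_dir, "features_patients.csv"),
       grades = file.path(cfg$out_dir, "grades.csv"),
       cutpoints = file.path(cfg$out_dir, "cutpoints.json"),
       results = file.path(cfg$out_dir, "results.json"),
       report = file.path(cfg$out_dir, "report.md"),
       manifest = file.path(cfg$out_dir, "manifest.json"),
       config = file.path(cfg$out_dir, "config.json"))
}

writeManifest <- function(cfg, stage, files, timings, warnings = character()) {
  paths <- pipelinePaths(cfg)
  manifest <- if (file.exists(paths$manifest))
    jsonlite::read_json(paths$manifest, simplifyVector = TRUE) else
    list(config = unclass(cfg),
         software_version = as.character(packageVersion("nestmorph")),
         stages = list())
  files <- files[file.exists(files)]
  manifest$stages[[stage]] <- list(
    files = as.list(setNames(as.character(tools::md5sum(files)),
                             basename(files))),
    seconds = round(as.numeric(timings), 3),
    warnings = as.list(warnings),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate the full synthetic study bundle
#'
#' Writes, under \code{out_dir}: one PNG image and one 16-bit TIFF
#' ground-truth mask per core, a ground-truth nest table, a clinical CSV
#' (patient id, latent level, covariates, follow-up time, event flag), the
#' config snapshot and a manifest with checksums.
#'
#' @param cfg a [runConfig()].
#' @return invisible list of written paths.
#' @export
runSimulate <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  t0 <- Sys.time()
  paths <- pipelinePaths(cfg)
  dir.create(paths$images, recursive = TRUE, showWarnings = FALSE)
  dir.create(paths$masks, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(paths$images))
    configError(paste("cannot create output directory:", paths$images))
  n <- cfg$n_patients
  withSeed(cfg$seed, {
    level <- sample(1:3, n, replace = TRUE)
    cov <- sampleCovariates(n)
    eff <- rep(0, n)
    for (nm in intersect(names(cfg$covariate_effects), names(cov)))
      eff <- eff + cfg$covariate_effects[[nm]] * cov[[nm]]
    # center the covariate contribution so baseline_hazard is the hazard of
    # an average mid-level patient and the cohort event fraction stays in
    # the realistic range for a five-year disease-free-survival endpoint
    eff <- eff - mean(eff)
    hazard <- cfg$baseline_hazard * exp(cfg$log_hr_per_level * (level - 2) + eff)
    tEvent <- rexp(n, hazard)
    tCens <- rexp(n, cfg$censoring_rate)
    time <- pmin(tEvent, tCens, cfg$followup_horizon)
    event <- as.integer(tEvent <= pmin(tCens, cfg$followup_horizon))
    pid <- sprintf("P%04d", seq_len(n))
    clinical <- data.frame(patient_id = pid, latent_level = level, cov,
                           time = time, event = event)
    nCores <- n * cfg$cores_per_patient
    coreSeeds <- sample.int(2147483646L, nCores)
    nestCounts <- integer(nCores)
    truthAll <- vector("list", nCores)
    ci <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(cfg$cores_per_patient)) {
        ci <- ci + 1L
        lv <- level[i]
        nNest <- sample(cfg$n_nests_min[lv]:cfg$n_nests_max[lv], 1L)
        spec <- syntheticImageSpec(
          width_px = cfg$width_px, height_px = cfg$height_px,
          n_nests = nNest, shape_family = cfg$shape_by_level[lv],
          size_range_px = c(cfg$size_min[lv], cfg$size_max[lv]),
          noise_sd = cfg$noise_sd,
          n_distractors = cfg$n_distractors, seed = coreSeeds[ci])
        cid <- sprintf("%s_c%d", pid[i], j)
        sim <- simulateCoreImage(spec, coreId = cid, patientId = pid[i])
        writeCoreImage(sim$image, file.path(paths$images,
                                            paste0(cid, ".png")))
        writeLabelMask(sim$truth$labelMask,
                       file.path(paths$masks, paste0(cid, ".tif")))
        tr <- sim$truth$nests
        if (nrow(tr)) tr <- cbind(core_id = cid, tr)
        truthAll[[ci]] <- tr
        nestCounts[ci] <- nNest
      }
    }
    write.csv(clinical, paths$clinical, row.names = FALSE)
    truth <- do.call(rbind, truthAll[vapply(truthAll, nrow, 0L) > 0])
    write.csv(truth, paths$truthNests, row.names = FALSE)
  })
  writeSpecJson(cfg, paths$config)
  writeManifest(cfg, "simulate",
                c(paths$clinical, paths$truthNests, paths$config,
                  list.files(paths$images, full.names = TRUE),
                  list.files(paths$masks, full.names = TRUE)),
                difftime(Sys.time(), t0, units = "secs"))
  invisible(paths)
}

aggregateByPatient <- function(featCores, mode) {
  cols <- c("number", "total_perimeter", "average_perimeter", "total_area",
            "average_area", "ta_over_tp", "avg_a_over_p", "circularity")
  ok <- featCores[!featCores$degenerate, , drop = FALSE]
  agg <- function(v) switch(mode, mean = mean(v), max = max(v), first = v[1L])
  out <- do.call(rbind, lapply(split(ok, ok$patient_id), function(d)
    cbind(data.frame(patient_id = d$patient_id[1L], n_cores = nrow(d)),
          as.data.frame(lapply(d[cols], agg)))))
  rownames(out) <- NULL
  out
}

#' Segment all cores and compute the feature tables
#'
#' Reads every \code{*.png} in the image directory, applies per-core
#' overrides when an \code{override_<core_id>.png} file exists, and writes
#' the per-nest table, the per-core eight-parameter table and the
#' patient-level table (aggregation over non-degenerate cores per
#' \code{core_aggregation}).
#'
#' @param cfg a [runConfig()].
#' @return invisible paths list.
#' @export
runFeatures <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  t0 <- Sys.time()
  paths <- pipelinePaths(cfg)
  imgs <- sort(list.files(paths$images, pattern = "\\.png$",
                          full.names = TRUE))
  imgs <- imgs[!grepl("^override_", basename(imgs))]
  if (!length(imgs)) dataError(paste("no images found in", paths$images))
  warningsLog <- character()
  featRows <- vector("list", length(imgs))
  nestRows <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    cid <- tools::file_path_sans_ext(basename(imgs[i]))
    pid <- sub("_c\\d+$", "", cid)
    img <- readCoreImage(imgs[i], coreId = cid, patientId = pid)
    ovPath <- file.path(paths$images, paste0("override_", cid, ".png"))
    override <- if (file.exists(ovPath)) readOverride(ovPath) else NULL
    res <- withCallingHandlers(
      coreFeaturePipeline(img, denoiseRadius = cfg$denoise_radius,
                          openingRadius = cfg$opening_radius,
                          minSize = cfg$min_size, override = override),
      warning = function(w) {
        warningsLog <<- c(warningsLog, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    featRows[[i]] <- cbind(res$features, patient_id = pid)
    if (nrow(res$shapes))
      nestRows[[i]] <- cbind(core_id = cid, res$shapes)
  }
  featCores <- do.call(rbind, featRows)
  nDegen <- sum(featCores$degenerate)
  if (nDegen > 0)
    warningsLog <- c(warningsLog,
                     sprintf("%d degenerate core(s) excluded from patient aggregation", nDegen))
  nests <- do.call(rbind, nestRows[!vapply(nestRows, is.null, TRUE)])
  write.csv(nests, paths$nests, row.names = FALSE)
  write.csv(featCores, paths$featuresCores, row.names = FALSE)
  featPat <- aggregateByPatient(featCores, cfg$core_aggregation)
  write.csv(featPat, paths$featuresPatients, row.names = FALSE)
  writeManifest(cfg, "features",
                c(paths$nests, paths$featuresCores, paths$featuresPatients),
                difftime(Sys.time(), t0, units = "secs"), warningsLog)
  message(sprintf("features: %d cores in, %d patients out, %d degenerate",
                  nrow(featCores), nrow(featPat), nDegen))
  invisible(paths)
}

featureParams <- c("number", "total_perimeter", "average_perimeter",
                   "total_area", "average_area", "ta_over_tp",
                   "avg_a_over_p", "circularity")
set1Params <- c("number", "circularity", "total_perimeter")
set2Params <- c("average_area", "average_perimeter", "ta_over_tp",
                "avg_a_over_p")

#' Grade the parameters and build the integrated scores
#'
#' Joins patient-level features with the clinical table (an error names any
#' patient present in one and missing from the other), runs the best-P
#' two-cutpoint search per parameter, sums grade scores of the negative set
#' (number, circularity, total perimeter) into score1 and of the positive
#' set (average area, average perimeter, total area/total perimeter, average
#' area/perimeter) into score2, and tiles both scores by the same search.
#'
#' @param cfg a [runConfig()].
#' @return invisible paths list.
#' @export
runGrade <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  t0 <- Sys.time()
  paths <- pipelinePaths(cfg)
  feat <- read.csv(paths$featuresPatients, stringsAsFactors = FALSE)
  clin <- read.csv(paths$clinical, stringsAsFactors = FALSE)
  onlyFeat <- setdiff(feat$patient_id, clin$patient_id)
  if (length(onlyFeat))
    dataError(paste("clinical table missing patient(s) present in images:",
                    paste(onlyFeat, collapse = ", ")))
  merged <- merge(feat, clin, by = "patient_id")
  cuts <- list()
  for (pm in featureParams) {
    res <- searchCutpoints(merged[[pm]], merged$time, merged$event,
                           minFrac = cfg$min_frac, parameterName = pm)
    merged[[paste0("grade_", pm)]] <- as.integer(grades(res))
    cuts[[pm]] <- list(cut1 = res@cut1, cut2 = res@cut2,
                       logrank_chisq = res@logrankChisq, p = res@pValue,
                       p_corrected = res@pValueCorrected,
                       group_sizes = res@groupSizes,
                       n_candidates = res@nCandidates)
  }
  merged$score1 <- integrateGrades(
    setNames(merged[paste0("grade_", set1Params)], set1Params), set1Params)
  merged$score2 <- integrateGrades(
    setNames(merged[paste0("grade_", set2Params)], set2Params), set2Params)
  for (sc in c("score1", "score2")) {
    tl <- tileScores(merged[[sc]], merged$time, merged$event,
                     minFrac = cfg$min_frac, parameterName = sc)
    merged[[paste0(sc, "_tile")]] <- as.character(tl$tiles)
    cuts[[sc]] <- list(cut1 = tl$result@cut1, cut2 = tl$result@cut2,
                       logrank_chisq = tl$result@logrankChisq,
                       p = tl$result@pValue,
                       p_corrected = tl$result@pValueCorrected,
                       group_sizes = tl$result@groupSizes,
                       n_candidates = tl$result@nCandidates)
  }
  write.csv(merged, paths$grades, row.names = FALSE)
  jsonlite::write_json(cuts, paths$cutpoints, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeManifest(cfg, "grade", c(paths$grades, paths$cutpoints),
                difftime(Sys.time(), t0, units = "secs"))
  invisible(paths)
}

#' Survival evaluation of grades, scores and tiles
#'
#' Kaplan-Meier/log-rank across score tiles, chi-square association between
#' the two integrated tilings, ROC (five-year horizon) for each parameter
#' and both scores, and a multivariate Cox model of the score tiles
#' (ordinal) plus clinical covariates. Writes \code{results.json}.
#'
#' @param cfg a [runConfig()].
#' @return invisible paths list.
#' @export
runSurvival <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  t0 <- Sys.time()
  paths <- pipelinePaths(cfg)
  d <- read.csv(paths$grades, stringsAsFactors = FALSE)
  d$score1_tile <- factor(d$score1_tile, levels = c("low", "middle", "high"))
  d$score2_tile <- factor(d$score2_tile, levels = c("low", "middle", "high"))
  warningsLog <- character()
  results <- list(n_patients = nrow(d), n_events = sum(d$event))

  results$logrank <- list(
    score1_tiles = kmLogrank(d, d$score1_tile)[c("chisq", "df", "p")],
    score2_tiles = kmLogrank(d, d$score2_tile)[c("chisq", "df", "p")])
  km1 <- kmLogrank(d, d$score1_tile)
  results$km_score1 <- lapply(km1$curves, function(cu)
    list(time = cu$time, surv = cu$surv))

  results$association_tiles <- chisqAssociation(d$score1_tile,
                                                d$score2_tile)[c("chisq", "df", "p")]

  rocs <- list()
  for (pm in c(featureParams, "score1", "score2")) {
    r <- tryCatch(rocForRecurrence(d[[pm]], d$time, d$event,
                                   horizon = cfg$followup_horizon),
                  error = function(e) NULL)
    if (is.null(r)) next
    if (r$n_excluded > 0)
      warningsLog <- c(warningsLog,
                       sprintf("ROC %s: %d patient(s) censored before horizon excluded",
                               pm, r$n_excluded))
    rocs[[pm]] <- r[c("auc", "ci95", "p_value", "n_pos", "n_neg",
                      "n_excluded")]
  }
  results$roc <- rocs

  covs <- intersect(c("t_stage", "n_stage", "hist_grade",
                      "hormone_receptor", "her2"), names(d))
  coxData <- d
  coxData$score1_tile <- as.integer(coxData$score1_tile)
  coxData$score2_tile <- as.integer(coxData$score2_tile)
  cox <- withCallingHandlers(
    coxMultivariate(coxData, c("score1_tile", "score2_tile", covs)),
    warning = function(w) {
      warningsLog <<- c(warningsLog, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  results$cox <- list(table = cox$table, loglik = cox$loglik, n = cox$n,
                      n_events = cox$n_events)
  results$warnings <- warningsLog

  jsonlite::write_json(results, paths$results, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeManifest(cfg, "survival", paths$results,
                difftime(Sys.time(), t0, units = "secs"), warningsLog)
  invisible(paths)
}

#' Render a human-readable report from results.json
#'
#' @param cfg a [runConfig()] whose results file exists.
#' @return invisible report path.
#' @export
runReport <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  t0 <- Sys.time()
  paths <- pipelinePaths(cfg)
  if (!file.exists(paths$results))
    dataError("results.json not found; run the survival stage first")
  res <- jsonlite::read_json(paths$results, simplifyVector = TRUE)
  if (!length(res)) dataError("results.json is empty")
  cuts <- jsonlite::read_json(paths$cutpoints, simplifyVector = TRUE)
  ln <- c("# Tumor-nest morphometrics report", "",
          sprintf("Patients: %d; events: %d", res$n_patients, res$n_events),
          "", "## Cutpoints and grading", "",
          "| parameter | cut1 | cut2 | log-rank chi2 | p | p corrected | groups |",
          "|---|---|---|---|---|---|---|")
  for (pm in names(cuts)) {
    cc <- cuts[[pm]]
    ln <- c(ln, sprintf("| %s | %.6g | %.6g | %.3f | %.3g | %.3g | %s |",
                        pm, cc$cut1, cc$cut2, cc$logrank_chisq, cc$p,
                        cc$p_corrected,
                        paste(cc$group_sizes, collapse = "/")))
  }
  ln <- c(ln, "", "## ROC (five-year recurrence)", "",
          "| marker | AUC | 95% CI | p | pos/neg (excl) |", "|---|---|---|---|---|")
  for (pm in names(res$roc)) {
    r <- res$roc[[pm]]
    ln <- c(ln, sprintf("| %s | %.3f | %.3f-%.3f | %.3g | %d/%d (%d) |",
                        pm, r$auc, r$ci95[1], r$ci95[2], r$p_value,
                        r$n_pos, r$n_neg, r$n_excluded))
  }
  ln <- c(ln, "", "## Log-rank across integrated-score tiles", "",
          sprintf("- score1 tiles: chi2 = %.3f (df %d), p = %.3g",
                  res$logrank$score1_tiles$chisq, res$logrank$score1_tiles$df,
                  res$logrank$score1_tiles$p),
          sprintf("- score2 tiles: chi2 = %.3f (df %d), p = %.3g",
                  res$logrank$score2_tiles$chisq, res$logrank$score2_tiles$df,
                  res$logrank$score2_tiles$p),
          "", "## Multivariate Cox model", "",
          "| covariate | HR | 95% CI | p |", "|---|---|---|---|")
  ct <- res$cox$table
  for (i in seq_len(nrow(ct)))
    ln <- c(ln, sprintf("| %s | %.3f | %.3f-%.3f | %.3g |",
                        ct$covariate[i], ct$hr[i], ct$lo[i], ct$hi[i],
                        ct$p[i]))
  if (length(res$warnings))
    ln <- c(ln, "", "## Warnings", "", paste("-", unlist(res$warnings)))
  writeLines(ln, paths$report)
  writeManifest(cfg, "report", paths$report,
                difftime(Sys.time(), t0, units = "secs"))
  invisible(paths$report)
}

#' Run the whole pipeline end to end
#'
#' \code{simulate -> features -> grade -> survival -> report} under one
#' config and seed; deterministic given both.
#'
#' @param cfg a [runConfig()].
#' @return invisible paths list.
#' @export
runAll <- function(cfg) {
  runSimulate(cfg)
  runFeatures(cfg)
  runGrade(cfg)
  runSurvival(cfg)
  runReport(cfg)
  invisible(pipelinePaths(cfg))
}
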