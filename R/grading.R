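# Survival-driven three-level grading: exhaustive best-P two-cutpoint search
# maximizing the 2-df log-rank statistic over all ordered pairs of observed
# values, followed by grade assignment and score integration. This is the
# X-tile-style "best P value" procedure; its uncorrected p-value is
# anti-conservative by construction and is therefore reported alongside a
# labeled selection-corrected p-value.

# k-group log-rank chi-square ((k-1) df), hypergeometric variance. Used by
# the search via an incremental prefix formulation; this direct version is
# the package's reference form for a single grouping.
logrankChisq <- function(time, event, group) {
  group <- as.integer(factor(group))
  k <- max(group)
  if (k < 2L) statError("log-rank needs at least 2 groups")
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) statError("log-rank needs at least one event")
  J <- length(dt)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (j in seq_len(J)) {
    at <- time >= dt[j]
    nj <- sum(at)
    dj <- sum(event == 1 & time == dt[j])
    ngj <- vapply(seq_len(k), function(g) sum(at & group == g), numeric(1))
    dgj <- vapply(seq_len(k), function(g)
      sum(event == 1 & time == dt[j] & group == g), numeric(1))
    O <- O + dgj
    E <- E + dj * ngj / nj
    if (nj > 1) {
      cj <- dj * (nj - dj) / (nj - 1)
      p <- ngj / nj
      V <- V + cj * (diag(p, k) - tcrossprod(p))
    }
  }
  u <- (O - E)[-k]
  Vm <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(drop(t(u) %*% solve(Vm, u)), error = function(e) 0)
  list(chisq = as.numeric(chisq), df = k - 1L, O = O, E = E)
}

# Selection correction for the best-P two-cutpoint search: a Sidak bound
# over the feasible cutpoint pairs actually scanned. Classical corrections
# for a maximally selected statistic address a single cutpoint; applied to
# the two-cutpoint maximum they still reject far above nominal under the
# null, so the package reports the conservative exact-enumeration bound
# instead (see the methods vignette for the calibration).
correctedSearchP <- function(pMin, nCandidates) {
  if (nCandidates <= 1L) return(pMin)
  min(1, 1 - (1 - pMin)^nCandidates)
}

#' Exhaustive best-P two-cutpoint search
#'
#' Scans every ordered pair (cut1 < cut2) of observed distinct values whose
#' induced three groups (I: v <= cut1, II: cut1 < v <= cut2, III: v > cut2)
#' all contain at least \code{ceiling(minFrac * n)} patients, computes the
#' 2-df log-rank chi-square of the three groups, and returns the maximizing
#' pair. Ties in the statistic are broken toward the smaller cut1, then the
#' smaller cut2. The search is exact (full enumeration), implemented with an
#' incremental prefix formulation over the value-ordered cohort so the whole
#' grid costs a few matrix products.
#'
#' The returned \code{pValue} is the raw tail probability of the maximized
#' statistic and is anti-conservative because the cutpoints were chosen to
#' minimize it; \code{pValueCorrected} applies a conservative selection
#' correction over the searched grid (Sidak bound across the feasible pairs)
#' and is the value to use for honest inference.
#'
#' @param values numeric marker values, one per patient (>= 3 distinct).
#' @param times,events follow-up times and event indicators (1 = event).
#' @param minFrac minimum group size as a fraction of the cohort
#'   (default 0.10).
#' @param parameterName label stored in the result.
#' @return a [CutpointResult-class].
#' @export
searchCutpoints <- function(values, times, events, minFrac = 0.10,
                            parameterName = "value") {
  n <- length(values)
  stopifnot(length(times) == n, length(events) == n)
  if (anyNA(values) || anyNA(times) || anyNA(events))
    dataError("missing values are not allowed in the cutpoint search")
  vs <- sort(unique(values))
  if (length(vs) < 3L)
    statError("cohort too small or too tied: need >= 3 distinct values")
  if (n * minFrac < 2)
    statError("cohort too small: n * minFrac must be >= 2")
  floorN <- ceiling(minFrac * n)

  ord <- order(values)
  tOrd <- times[ord]; eOrd <- events[ord]
  dt <- sort(unique(times[events == 1]))
  if (!length(dt)) statError("no events in cohort: log-rank undefined")
  J <- length(dt)

  # prefix machinery over the value-ordered cohort; prefix boundaries are
  # the cumulative counts of each distinct value
  cnt <- cumsum(tabulate(match(values, vs), nbins = length(vs)))
  M <- length(vs)
  atRisk <- outer(tOrd, dt, ">=")                      # n x J
  Ncum <- apply(atRisk, 2L, cumsum)                    # prefix at-risk
  evAt <- outer(tOrd, dt, "==") & (eOrd == 1)
  Dcum <- apply(evAt, 2L, cumsum)
  nj <- Ncum[n, ]
  dj <- Dcum[n, ]
  cj <- ifelse(nj > 1, dj * (nj - dj) / (nj - 1), 0)

  Np <- Ncum[cnt, , drop = FALSE]                      # M x J
  Q <- sweep(Np, 2L, nj, "/")
  Ovec <- cumsum(eOrd)[cnt]
  Evec <- drop(Np %*% (dj / nj))
  Avec <- drop(Q %*% cj)
  Bvec <- drop((Q * Q) %*% cj)
  G <- tcrossprod(sweep(Q, 2L, sqrt(cj), "*"))         # M x M cross terms

  # feasible pairs of prefix indices (m1 < m2); cut values vs[m1], vs[m2]
  m1ok <- which(cnt >= floorN & cnt <= n - 2L * floorN)
  if (!length(m1ok))
    statError("no feasible cutpoint pair under the minimum group fraction")
  pairs <- do.call(rbind, lapply(m1ok, function(m1) {
    m2 <- which(cnt - cnt[m1] >= floorN & n - cnt >= floorN)
    m2 <- m2[m2 > m1 & m2 < M]
    if (length(m2)) cbind(m1, m2) else NULL
  }))
  if (is.null(pairs))
    statError("no feasible cutpoint pair under the minimum group fraction")
  # order by (cut1, cut2) so which.max's first-maximum rule implements the
  # smaller-cut1-then-smaller-cut2 tie-break
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  m1 <- pairs[, 1L]; m2 <- pairs[, 2L]

  u1 <- Ovec[m1] - Evec[m1]
  u2 <- (Ovec[m2] - Ovec[m1]) - (Evec[m2] - Evec[m1])
  V11 <- Avec[m1] - Bvec[m1]
  g12 <- G[cbind(m1, m2)]
  V22 <- (Avec[m2] - Avec[m1]) - (Bvec[m2] - 2 * g12 + Bvec[m1])
  V12 <- -(g12 - Bvec[m1])
  det <- V11 * V22 - V12^2
  chis <- ifelse(det > 1e-10 * pmax(V11 * V22, 1e-300),
                 (u1^2 * V22 - 2 * u1 * u2 * V12 + u2^2 * V11) / det, 0)

  best <- which.max(chis)
  cut1 <- vs[m1[best]]; cut2 <- vs[m2[best]]
  chisq <- chis[best]
  gr <- assignGrades(values, cut1, cut2)
  p <- pchisq(chisq, df = 2, lower.tail = FALSE)
  new("CutpointResult", parameterName = as.character(parameterName),
      cut1 = cut1, cut2 = cut2, grades = gr,
      logrankChisq = as.numeric(chisq), pValue = p,
      pValueCorrected = correctedSearchP(p, nrow(pairs)),
      groupSizes = as.integer(table(gr)), nCandidates = nrow(pairs))
}

#' Assign three-level grades from two cutpoints
#'
#' Boundary convention: a value equal to a cutpoint belongs to the lower
#' grade (v <= cut1 is grade I, cut1 < v <= cut2 grade II, v > cut2 grade
#' III), applied uniformly across the package.
#'
#' @param values numeric vector (may be empty).
#' @param cut1,cut2 cutpoints with cut1 < cut2; alternatively pass a
#'   [CutpointResult-class] as \code{cut1}.
#' @return factor with levels I, II, III.
#' @export
assignGrades <- function(values, cut1, cut2 = NULL) {
  if (is(cut1, "CutpointResult")) {
    cp <- cutpoints(cut1); cut2 <- cp[2L]; cut1 <- cp[1L]
  }
  stopifnot(cut1 < cut2)
  g <- ifelse(values <= cut1, "I", ifelse(values <= cut2, "II", "III"))
  factor(g, levels = c("I", "II", "III"))
}

#' Sum grade scores into an integrated parameter
#'
#' Grade I scores 1, II scores 2, III scores 3; the integrated parameter is
#' the sum over its parameter set (3..9 for the three negatively prognostic
#' parameters, 4..12 for the four positively prognostic ones). Missing grades
#' are an error — no imputation.
#'
#' @param gradesByParameter data frame or named list; each element a grade
#'   factor (levels I/II/III) or integer vector in 1..3, one value per
#'   patient.
#' @param parameterSet character vector naming the columns to sum.
#' @return integer score vector.
#' @export
integrateGrades <- function(gradesByParameter, parameterSet) {
  missing <- setdiff(parameterSet, names(gradesByParameter))
  if (length(missing))
    dataError(paste("no grades for parameter(s):",
                    paste(missing, collapse = ", ")))
  cols <- lapply(parameterSet, function(nm) {
    g <- gradesByParameter[[nm]]
    gi <- if (is.factor(g)) as.integer(g) else as.integer(g)
    if (anyNA(gi) || any(gi < 1L | gi > 3L))
      dataError(sprintf("parameter '%s' has missing or out-of-range grades", nm))
    gi
  })
  as.integer(Reduce(`+`, cols))
}

#' Divide integrated scores into three tiles
#'
#' Applies the same exhaustive best-P two-cutpoint search to the integer
#' score and relabels the resulting grades low/middle/high. Tile assignment
#' is monotone in the score by construction.
#'
#' @inheritParams searchCutpoints
#' @param scores integer score vector.
#' @return list with \code{tiles} (factor low/middle/high) and \code{result}
#'   (the underlying [CutpointResult-class]).
#' @export
tileScores <- function(scores, times, events, minFrac = 0.10,
                       parameterName = "integrated_score") {
  res <- searchCutpoints(scores, times, events, minFrac = minFrac,
                         parameterName = parameterName)
  tiles <- factor(c("low", "middle", "high")[as.integer(grades(res))],
                  levels = c("low", "middle", "high"))
  list(tiles = tiles, result = res)
}
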