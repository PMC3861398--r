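# Evaluation layer: Kaplan-Meier / log-rank, Pearson chi-square association,
# ROC for five-year recurrence, multivariate Cox regression. Standard model
# fitting is delegated to the survival package; the ROC machinery
# (dichotomization rule, trapezoidal AUC, Hanley-McNeil interval) is local.

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param data data frame with columns \code{time} and \code{event}.
#' @param group factor/vector of group membership (>= 2 non-empty groups).
#' @return list with \code{curves} (per group: data frame of \code{time},
#'   \code{surv}, \code{n_risk}), \code{chisq}, \code{df} and \code{p} from
#'   the (k-1)-df log-rank test.
#' @export
kmLogrank <- function(data, group) {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  group <- factor(group)
  if (nlevels(group) < 2L)
    statError("log-rank comparison needs at least 2 groups")
  if (any(table(group) == 0L))
    statError("empty group in log-rank comparison")
  if (sum(data$event) == 0)
    statError("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(data, g = group))
  df <- nlevels(group) - 1L
  fits <- lapply(levels(group), function(lv) {
    d <- data[group == lv, ]
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk)
  })
  names(fits) <- levels(group)
  list(curves = fits, chisq = as.numeric(sd$chisq), df = df,
       p = pchisq(as.numeric(sd$chisq), df, lower.tail = FALSE))
}

#' Kaplan-Meier estimate for a single sample
#'
#' @param time,event follow-up times and event indicators.
#' @return data frame with \code{time}, \code{surv}, \code{n_risk},
#'   \code{n_event}; the product-limit estimate starts at 1 and is
#'   non-increasing.
#' @export
kmCurve <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
             n_event = sf$n.event)
}

#' Pearson chi-square association between two categorical gradings
#'
#' @param gradeA,gradeB factors (or vectors coercible to factors) with at
#'   least 2 levels each; a level with zero observed count (zero marginal)
#'   is an error.
#' @return list with \code{chisq}, \code{df}, \code{p} and the contingency
#'   \code{table}.
#' @export
chisqAssociation <- function(gradeA, gradeB) {
  a <- factor(gradeA); b <- factor(gradeB)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    statError("both gradings must have at least 2 levels")
  tab <- table(a, b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    statError("zero marginal in contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = as.numeric(ct$statistic), df = as.integer(ct$parameter),
       p = as.numeric(ct$p.value), table = tab)
}

#' ROC analysis of a marker for recurrence within a horizon
#'
#' Dichotomizes the outcome at \code{horizon} months: positives are patients
#' with an event at or before the horizon; negatives are event-free with
#' follow-up reaching the horizon (events after the horizon count as
#' negative). Patients censored before the horizon carry no usable label and
#' are excluded; their count is always reported. The ROC curve sweeps all
#' thresholds of the marker (higher value = predicted positive); the AUC is
#' the trapezoidal area, its CI uses the Hanley-McNeil variance, and the
#' p-value tests AUC = 0.5 two-sided.
#'
#' @param marker numeric marker values.
#' @param time,event follow-up times (months) and event indicators.
#' @param horizon dichotomization horizon in months (default 60 = 5 years).
#' @return list with \code{auc}, \code{ci95}, \code{p_value}, \code{n_pos},
#'   \code{n_neg}, \code{n_excluded} and the curve (\code{fpr}, \code{tpr}).
#' @export
rocForRecurrence <- function(marker, time, event, horizon = 60) {
  n <- length(marker)
  stopifnot(length(time) == n, length(event) == n)
  pos <- event == 1 & time <= horizon
  neg <- time >= horizon & !pos
  excl <- !(pos | neg)
  nPos <- sum(pos); nNeg <- sum(neg)
  if (nPos == 0L || nNeg == 0L)
    statError("a class is empty after horizon dichotomization")
  x <- marker[pos]; y <- marker[neg]
  # trapezoidal ROC over all distinct thresholds, descending
  th <- sort(unique(c(x, y)), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(x >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(y >= t), numeric(1)))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
        (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg)
  se <- sqrt(max(v, 0))
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  pz <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  list(auc = auc, ci95 = ci, p_value = pz, n_pos = nPos, n_neg = nNeg,
       n_excluded = sum(excl), fpr = fpr, tpr = tpr)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; Wald confidence intervals
#' and p-values. Graded or tiled variables should be entered as ordinal 1/2/3
#' codes so each hazard ratio is per one grade/tile step; pass
#' \code{ordinal = FALSE} to expand factors to dummy variables instead.
#' If the number of events falls below five per covariate the fit proceeds
#' with a warning (logged, not fatal); non-convergence or a monotone
#' likelihood (infinite coefficient) is an explicit error.
#'
#' @param data data frame containing \code{time}, \code{event} and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param ordinal convert factor covariates to ordinal integer codes
#'   (default TRUE, matching a one-HR-per-variable presentation).
#' @return list with \code{table} (per covariate: \code{hr}, \code{lo},
#'   \code{hi}, \code{p}), \code{loglik}, \code{n}, \code{n_events}.
#' @export
coxMultivariate <- function(data, covariates, ordinal = TRUE) {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  missingCov <- setdiff(covariates, names(data))
  if (length(missingCov))
    dataError(paste("covariates absent from data:",
                    paste(missingCov, collapse = ", ")))
  d <- data[, c("time", "event", covariates)]
  if (ordinal)
    for (cv in covariates)
      if (is.factor(d[[cv]])) d[[cv]] <- as.integer(d[[cv]])
  nEvents <- sum(d$event == 1)
  if (nEvents < 5 * length(covariates))
    warning(sprintf("only %d events for %d covariates (guideline: >= 5 per covariate)",
                    nEvents, length(covariates)))
  constant <- vapply(covariates, function(cv)
    length(unique(d[[cv]])) < 2L, logical(1))
  if (any(constant))
    statError(paste("degenerate design: covariate(s) constant:",
                    paste(covariates[constant], collapse = ", ")))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(survival::coxph(fml, data = d, ties = "efron"),
                  warning = function(w) {
                    if (grepl("converge|infinite|beta may be infinite",
                              conditionMessage(w)))
                      statError(paste("Cox fit did not converge:",
                                      conditionMessage(w)))
                    suppressWarnings(survival::coxph(fml, data = d,
                                                     ties = "efron"))
                  })
  sm <- summary(fit)
  co <- sm$coefficients
  if (any(!is.finite(co[, "coef"])) || any(!is.finite(co[, "se(coef)"])) ||
      any(co[, "se(coef)"] > 1e3))
    statError("Cox fit degenerate: monotone likelihood / infinite coefficient")
  tab <- data.frame(covariate = rownames(co),
                    hr = exp(co[, "coef"]),
                    lo = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    hi = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"], row.names = NULL)
  list(table = tab, loglik = as.numeric(fit$loglik[2L]), n = nrow(d),
       n_events = nEvents)
}
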