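test_that("KM curves behave at the boundaries", {
  # no events: curve stays flat at 1; a group comparison is degenerate
  d <- data.frame(time = c(5, 10, 15, 20), event = c(0, 0, 0, 0))
  expect_true(all(kmCurve(d$time, d$event)$surv == 1))
  expect_error(kmLogrank(rbind(d, d), rep(c("a", "b"), each = 4)),
               "at least one event")
  # two identical groups (copied records): chi-square vanishes by symmetry
  de <- data.frame(time = c(5, 10, 15, 20), event = c(1, 1, 0, 1))
  res <- kmLogrank(rbind(de, de), rep(c("a", "b"), each = 4))
  expect_lt(res$chisq, 1e-10)
  # KM on uncensored data equals the empirical survivor function
  set.seed(3)
  t2 <- rexp(200, 0.05)
  km <- kmCurve(t2, rep(1L, 200))
  emp <- vapply(km$time, function(tt) mean(t2 > tt), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 1e-12) && km$surv[1] <= 1)
  expect_error(kmLogrank(d, rep("a", 4)), "2 groups")
})

test_that("log-rank is invariant under group relabeling and detects HR = 2", {
  set.seed(31)
  d <- rbind(expCohort(300, 0.02), expCohort(300, 0.04))
  grp <- rep(c("x", "y"), each = 300)
  a <- kmLogrank(d, grp)
  b <- kmLogrank(d, rep(c("y", "x"), each = 300))
  expect_equal(a$chisq, b$chisq, tolerance = 1e-12)
  # power at true HR = 2, n = 500/arm
  hits <- 0L
  for (rep in 1:10) {
    dd <- rbind(expCohort(500, 0.02), expCohort(500, 0.04))
    if (kmLogrank(dd, rep(0:1, each = 500))$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("Pearson chi-square matches closed forms", {
  # identical balanced vectors: chisq = n (k - 1)
  g <- factor(rep(c("I", "II", "III"), each = 30))
  res <- chisqAssociation(g, g)
  expect_equal(res$chisq, 90 * 2, tolerance = 1e-9)
  # diagonal 2x2 with counts (10,0,0,10): chisq = 20
  a <- factor(rep(c("p", "q"), each = 10))
  expect_equal(chisqAssociation(a, a)$chisq, 20, tolerance = 1e-12)
  # zero marginal is an error
  z <- factor(rep("p", 20), levels = c("p", "q"))
  expect_error(chisqAssociation(z, a), "zero marginal|2 levels")
  expect_error(chisqAssociation(factor(rep("p", 20)), a), "2 levels")
  # independence null: rejection rate near nominal
  set.seed(8)
  rej <- mean(replicate(200, {
    chisqAssociation(factor(sample(1:3, 300, TRUE)),
                     factor(sample(1:3, 300, TRUE)))$p < 0.05
  }))
  expect_gt(rej, 0.005); expect_lt(rej, 0.12)
})

test_that("ROC handles separation, censoring exclusions and the rank identity", {
  # perfectly ordered marker
  d <- data.frame(time = c(rep(20, 10), rep(80, 10)),
                  event = rep(c(1L, 0L), c(10, 10)))
  r <- rocForRecurrence(c(71:80, 31:40), d$time, d$event)
  expect_equal(r$auc, 1)
  expect_equal(r$n_pos, 10L); expect_equal(r$n_neg, 10L)
  # censored before the horizon are excluded and counted
  d2 <- data.frame(time = c(20, 30, 80, 90, 40), event = c(1, 1, 0, 0, 0))
  r2 <- rocForRecurrence(c(5, 4, 1, 2, 3), d2$time, d2$event)
  expect_equal(r2$n_excluded, 1L)
  expect_error(rocForRecurrence(1:5, rep(10, 5), rep(0, 5)), "empty")
  # independent marker, large n: AUC near 1/2
  set.seed(10)
  dn <- expCohort(2000, 0.02)
  rn <- rocForRecurrence(rnorm(2000), dn$time, dn$event)
  expect_lt(abs(rn$auc - 0.5), 0.04)
  expect_true(rn$ci95[1] <= rn$auc && rn$auc <= rn$ci95[2])
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic exactly", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(30:120, 1)
    marker <- if (rep %% 2) rnorm(n) else sample(1:6, n, TRUE)  # with ties
    ev <- rbinom(n, 1, 0.4)
    time <- ifelse(ev == 1, runif(n, 1, 59), runif(n, 60, 90))
    r <- rocForRecurrence(marker, time, ev)
    expect_equal(r$auc, rankAuc(marker, ev == 1), tolerance = 1e-12)
  }
})

test_that("Cox recovers parameters and matches the log-rank score test", {
  set.seed(5)
  # score test at beta = 0 with one binary covariate equals log-rank
  d <- expCohort(400, rep(c(0.02, 0.03), each = 200))
  d$x <- rep(0:1, each = 200)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  lr <- survival::survdiff(survival::Surv(time, event) ~ x, data = d)
  expect_equal(as.numeric(fit$score), as.numeric(lr$chisq), tolerance = 1e-8)
  # degenerate design: constant covariate
  d$z <- 1
  expect_error(coxMultivariate(d, "z"), "constant")
  # recovery of HR = 1.5 on a binary arm
  set.seed(6)
  d2 <- rbind(expCohort(3000, 0.02), expCohort(3000, 0.03))
  d2$x <- rep(0:1, each = 3000)
  cm <- coxMultivariate(d2, "x")
  expect_gt(cm$table$hr[1], 1.32); expect_lt(cm$table$hr[1], 1.7)
  expect_true(cm$table$lo[1] < cm$table$hr[1] &&
              cm$table$hr[1] < cm$table$hi[1])
  few <- data.frame(time = c(5, 10, 15, 20, 6, 11, 16, 21),
                    event = c(1, 1, 0, 0, 1, 1, 0, 0),
                    x = rep(0:1, each = 4))
  expect_warning(coxMultivariate(few, "x"), "events")
})
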