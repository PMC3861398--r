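test_that("search matches the naive enumeration oracle", {
  set.seed(321)
  for (rep in 1:5) {
    n <- 60
    v <- rnorm(n)
    d <- expCohort(n, 0.02 * exp(0.7 * v))
    a <- searchCutpoints(v, d$time, d$event)
    b <- naiveCutpointSearch(v, d$time, d$event)
    expect_equal(a@cut1, b$cut1)
    expect_equal(a@cut2, b$cut2)
    expect_equal(a@logrankChisq, b$chisq, tolerance = 1e-9)
  }
})

test_that("well-separated risk clusters are recovered between clusters", {
  # three value clusters with strongly ordered survival (cluster 3 recurs
  # first, cluster 1 stays event-free): the optimum must fall between the
  # clusters, for any draw of the values
  for (seed in c(55, 7, 23)) {
    set.seed(seed)
    v <- c(runif(20, 0.9, 1.1), runif(20, 4.9, 5.1), runif(20, 8.9, 9.1))
    time <- rep(c(60, 30, 5), each = 20)
    event <- rep(c(0L, 1L, 1L), each = 20)
    res <- searchCutpoints(v, time, event)
    expect_gte(res@cut1, max(v[1:20]) - 1e-12)
    expect_lt(res@cut1, min(v[21:40]))
    expect_gte(res@cut2, max(v[21:40]) - 1e-12)
    expect_lt(res@cut2, min(v[41:60]))
    expect_equal(as.integer(res@groupSizes), c(20L, 20L, 20L))
    b <- naiveCutpointSearch(v, time, event)
    expect_equal(res@cut1, b$cut1)
    expect_equal(res@cut2, b$cut2)
  }
})

test_that("degenerate inputs are rejected", {
  d <- expCohort(30, 0.02)
  expect_error(searchCutpoints(rep(1, 30), d$time, d$event), "distinct")
  expect_error(searchCutpoints(c(rep(1, 28), 2, 3), d$time, d$event),
               "feasible")
  expect_error(searchCutpoints(rnorm(30), d$time, rep(0, 30)), "no events")
})

test_that("grade assignment follows the boundary convention", {
  g <- assignGrades(c(1, 2, 2.5, 3, 3.0001), cut1 = 2, cut2 = 3)
  expect_equal(as.character(g), c("I", "I", "II", "II", "III"))
  expect_length(assignGrades(numeric(), 1, 2), 0L)
  expect_error(assignGrades(1:3, 5, 2))
})

test_that("monotone transforms leave the grading unchanged", {
  set.seed(9)
  v <- rnorm(50)
  d <- expCohort(50, 0.02 * exp(0.6 * v))
  g1 <- grades(searchCutpoints(v, d$time, d$event))
  for (f in list(function(x) exp(x), function(x) 3 * x - 7,
                 function(x) rank(x))) {
    g2 <- grades(searchCutpoints(f(v), d$time, d$event))
    expect_identical(g2, g1)
  }
})

test_that("no returned group falls below the minimum fraction", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(40:120, 1)
    v <- rnorm(n)
    d <- expCohort(n, 0.02 * exp(0.5 * v))
    res <- searchCutpoints(v, d$time, d$event, minFrac = 0.15)
    expect_true(all(res@groupSizes >= ceiling(0.15 * n)))
  }
})

test_that("integrated scores sum the grade codes", {
  g <- data.frame(number = factor(c("I", "I", "II"), c("I", "II", "III")),
                  circularity = factor(c("I", "II", "III"), c("I", "II", "III")),
                  total_perimeter = factor(c("I", "III", "I"), c("I", "II", "III")))
  s <- integrateGrades(g, c("number", "circularity", "total_perimeter"))
  expect_identical(s, c(3L, 6L, 6L))
  g4 <- data.frame(a = rep(3L, 2), b = rep(3L, 2), c = rep(3L, 2),
                   d = rep(3L, 2))
  expect_identical(integrateGrades(g4, c("a", "b", "c", "d")), c(12L, 12L))
  expect_error(integrateGrades(g, c("number", "missing_param")), "no grades")
  gna <- g; gna$circularity[2] <- NA
  expect_error(integrateGrades(gna, names(g)), "missing")
})

test_that("score tiling is monotone and recovers clustered scores", {
  set.seed(13)
  s <- rep(c(3L, 6L, 9L), each = 25)
  d <- expCohort(75, rep(c(0.003, 0.02, 0.10), each = 25), censRate = 0.002)
  tl <- tileScores(s, d$time, d$event)
  expect_identical(as.character(tl$tiles),
                   c("low", "middle", "high")[match(s, c(3, 6, 9))])
  # monotone in score by construction
  ord <- order(s)
  expect_true(all(diff(as.integer(tl$tiles)[ord]) >= 0))
  expect_error(tileScores(rep(5L, 40), d$time[1:40], d$event[1:40]),
               "distinct")
})
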