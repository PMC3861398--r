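# Independent oracles and small fixture builders, deliberately implemented
# with different algorithms than the package code they check.

# Naive best-P two-cutpoint search: double loop over all value pairs,
# log-rank recomputed from scratch by survival::survdiff for each candidate.
naiveCutpointSearch <- function(values, time, event, minFrac = 0.10) {
  n <- length(values)
  vs <- sort(unique(values))
  fl <- ceiling(minFrac * n)
  best <- list(chisq = -Inf, cut1 = NA, cut2 = NA)
  for (i in seq_along(vs)) {
    for (j in seq_along(vs)) {
      if (j <= i) next
      g <- ifelse(values <= vs[i], 1L, ifelse(values <= vs[j], 2L, 3L))
      if (any(tabulate(g, 3L) < fl)) next
      ch <- tryCatch(
        survival::survdiff(survival::Surv(time, event) ~ g)$chisq,
        error = function(e) NA_real_)
      if (is.na(ch)) next
      if (ch > best$chisq) best <- list(chisq = ch, cut1 = vs[i], cut2 = vs[j])
    }
  }
  best
}

# Rank-statistic AUC: Mann-Whitney U / (n_pos * n_neg) with midranks for ties.
rankAuc <- function(marker, labelPos) {
  x <- marker[labelPos]; y <- marker[!labelPos]
  r <- rank(c(x, y))
  u <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  u / (length(x) * length(y))
}

# Brute-force Otsu: exhaustive scan of all 256-bin split points maximizing
# between-class variance, returning the center of the winning bin.
bruteOtsu <- function(v) {
  h <- hist(as.vector(v), breaks = seq(0, 1, length.out = 257), plot = FALSE)
  counts <- h$counts; mids <- h$mids
  best <- -Inf; bestk <- NA_integer_
  for (k in 1:255) {
    w1 <- sum(counts[1:k]); w2 <- sum(counts) - w1
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(counts[1:k] * mids[1:k]) / w1
    m2 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w2
    bc <- w1 * w2 * (m1 - m2)^2
    if (bc > best) { best <- bc; bestk <- k }
  }
  h$breaks[bestk + 1]
}

# Double-loop 4-neighbour boundary scan (independent of the package's
# vectorized shift implementation).
loopBoundary4 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c]) next
    nb <- c(if (r > 1) mask[r - 1, c] else FALSE,
            if (r < H) mask[r + 1, c] else FALSE,
            if (c > 1) mask[r, c - 1] else FALSE,
            if (c < W) mask[r, c + 1] else FALSE,
            FALSE)
    if (r == 1 || r == H || c == 1 || c == W || !all(nb[1:4])) out[r, c] <- TRUE
  }
  out
}

# Fixture masks
mkDisk <- function(r, pad = 5L) {
  n <- 2L * r + 2L * pad
  cx <- r + pad
  outer(seq_len(n), seq_len(n), function(y, x) (x - cx)^2 + (y - cx)^2 <= r^2)
}

mkSquare <- function(side = 10L, pad = 2L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  m
}

segFromMask <- function(mask) labelNests(mask, minSize = 1L)

# Independent exponential-cohort builder for survival tests.
expCohort <- function(n, hazard, censRate = 0.008, horizon = 60) {
  te <- rexp(n, hazard)
  tc <- rexp(n, censRate)
  data.frame(time = pmin(te, tc, horizon),
             event = as.integer(te <= pmin(tc, horizon)))
}
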