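# Independent oracles used across the suite. Each recomputes a quantity by
# a different route than the implementation under test.

# Closed-form spark excess evaluated on an arbitrarily fine grid,
# duplicating the generative formula (unit-peak rise*decay product)
# without going through simulate_trace().
oracle_spark_excess <- function(t, onset, amplitude, rise_tau, decay_tau) {
  s <- t - onset
  raw <- ifelse(s <= 0, 0, (1 - exp(-s / rise_tau)) * exp(-s / decay_tau))
  tp <- rise_tau * log(1 + decay_tau / rise_tau)
  peak <- (1 - exp(-tp / rise_tau)) * exp(-tp / decay_tau)
  amplitude * raw / peak
}

# Midpoint Riemann sum of the piecewise-linear interpolant of (v - 1)
# clipped at 0, oversampled `factor` times per frame interval.
oracle_riemann_auc <- function(times, values, factor = 100L) {
  excess <- pmax(values - 1, 0)
  grid <- seq(times[1], times[length(times)],
              length.out = factor * (length(times) - 1) + 1)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  f <- stats::approx(times, excess, xout = mid)$y
  sum(f * diff(grid))
}

# Spearman rank correlation from the explicit definition: average ranks,
# then the Pearson product-moment formula written out as sums.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# One-way ANOVA F from explicit between/within sums of squares.
oracle_anova_F <- function(values, labels) {
  groups <- split(values, labels)
  gm <- mean(values)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(values) - length(groups)
  (ss_between / df1) / (ss_within / df2)
}

# First index opening a run of `min_run` consecutive values above `thr`
# (brute-force scan independent of detect_sparks' state machine).
oracle_first_crossing <- function(v, thr, min_run = 2L) {
  above <- v > thr
  for (i in seq_len(length(v) - min_run + 1L)) {
    if (all(above[i:(i + min_run - 1L)])) return(i)
  }
  NA_integer_
}

# Convenience: a clean raw trace carrying explicit samples.
make_trace <- function(values, interval = 4, egg_id = "t1") {
  fluorescence_trace(egg_id, (seq_along(values) - 1) * interval, values)
}
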