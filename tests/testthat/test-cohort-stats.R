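# Small hand-built cohort: four eggs with known profiles and outcomes.
make_mini_cohort <- function() {
  mk <- function(id, amp) {
    if (is.na(amp)) {
      profile_trace(make_trace(rep(100, 12), egg_id = id))
    } else {
      p <- spark_sim_params(n_frames = 12, spark_onsets = 24,
                            spark_amplitudes = amp, noise_sd = 0)
      profile_trace(simulate_trace(p, egg_id = id)$trace)
    }
  }
  profiles <- list(e1 = mk("e1", NA), e2 = mk("e2", 1), e3 = mk("e3", 2),
                   e4 = mk("e4", 3))
  records <- tibble::tibble(
    egg_id = c("e1", "e2", "e3", "e4"),
    treatment = "Ca-Iono",
    outcome = c("unactivated", "non-blastocyst", "morula", "blastocyst"),
    fertilized = NA,
    cell_count = c(NA, NA, 32L, 51L)
  )
  list(records = records, profiles = profiles)
}

test_that("outcome grouping follows the analysis mode", {
  mc <- make_mini_cohort()
  g1 <- assign_groups(mc$records, mc$profiles, mode = "collapsed")
  expect_equal(g1$group, c("unactivated", "non-blastocyst", "non-blastocyst",
                           "blastocyst"))
  g3 <- assign_groups(mc$records, mc$profiles, mode = "staged")
  expect_equal(g3$group[3], "morula")
  # first-spark parameters joined per egg; sparkless egg carries NA
  expect_true(is.na(g1$amplitude[1]))
  expect_equal(g1$amplitude[2:4], c(1, 2, 3), tolerance = 0.05)
})

test_that("records without profiles raise an error naming the eggs", {
  mc <- make_mini_cohort()
  expect_error(assign_groups(mc$records, mc$profiles[c("e1", "e2")]),
               "e3.*e4|e3, e4")
})

test_that("reference normalization rescales group means to the reference", {
  vals <- c(2, 2, 4, 4, 6, 6)
  labs <- rep(c("unactivated", "non-blastocyst", "blastocyst"), each = 2)
  out <- normalize_to_reference(vals, labs)
  expect_equal(out$rel_mean[match(c("unactivated", "non-blastocyst",
                                    "blastocyst"), out$group)],
               c(0.5, 1, 1.5))
  # reference alone
  solo <- normalize_to_reference(c(3, 5), rep("non-blastocyst", 2))
  expect_equal(solo$rel_mean, 1)
  # scale invariance
  out10 <- normalize_to_reference(10 * vals, labs)
  expect_equal(out$rel_mean, out10$rel_mean)
  expect_equal(out$rel_sem, out10$rel_sem)
  expect_error(normalize_to_reference(vals, labs, reference = "morula"),
               "empty")
})

test_that("group tests match their classical definitions", {
  x <- c(5, 6, 7, 5, 6, 7)
  lab <- rep(c("a", "b"), each = 3)
  expect_equal(compare_groups(x, lab, test = "t")$statistic, 0)
  expect_equal(compare_groups(x, lab, test = "welch_t")$statistic, 0)

  tab <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(compare_groups(tab, test = "chi2")$statistic, 0)

  vals <- c(3.1, 4.2, 2.8, 5.5, 6.1, 5.0, 7.9, 8.2, 9.1)
  labs <- rep(c("g1", "g2", "g3"), each = 3)
  res <- compare_groups(vals, labs, test = "anova")
  expect_equal(res$statistic, oracle_anova_F(vals, labs), tolerance = 1e-12)

  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b"), test = "welch_t"),
               "n >= 2")
})

test_that("z scores follow the sample-SD definition", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  x <- rnorm(40, 12, 7)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(5 * x + 11), z, tolerance = 1e-12)
  expect_error(zscore(rep(4, 6)), "SD = 0")
  expect_error(zscore(3), "n >= 2")
})

test_that("amplitude-cell correlation matches the explicit rank formula", {
  expect_equal(correlate_amp_cells(1:5, c(10, 20, 30, 40, 50))$spearman_r, 1)
  expect_equal(correlate_amp_cells(1:5, c(50, 40, 30, 20, 10))$spearman_r, -1)

  amp <- c(1.2, 2.0, 2.0, 2.8, 3.5, 4.1)  # one tie
  cells <- c(22, 31, 28, 35, 47, 52)
  res <- correlate_amp_cells(amp, cells)
  expect_equal(res$spearman_r, oracle_spearman(amp, cells), tolerance = 1e-12)
  # z-transform cannot change the rank correlation
  expect_equal(stats::cor(zscore(amp), zscore(cells), method = "spearman"),
               res$spearman_r, tolerance = 1e-12)
  # OLS on z-scored pairs: slope equals the Pearson correlation
  expect_equal(res$slope, stats::cor(amp, cells), tolerance = 1e-12)
  expect_lt(abs(res$intercept), 1e-12)
  expect_error(correlate_amp_cells(1:2, 1:2), "at least 3")
})

test_that("median split halves a cohort with distinct amplitudes", {
  grouped <- tibble::tibble(
    egg_id = sprintf("e%d", 1:8),
    amplitude = c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4),
    outcome = c("non-blastocyst", "blastocyst", "non-blastocyst",
                "non-blastocyst", "non-blastocyst", "non-blastocyst",
                "blastocyst", "blastocyst")
  )
  sel <- percentile_select(grouped)
  expect_equal(sel$n_top, 4)
  expect_equal(sel$n_bottom, 4)
  expect_equal(sel$rate_top, 0.5)
  expect_equal(sel$rate_bottom, 0.25)
  expect_equal(sel$rate_ratio, 2)
})

test_that("median ties go to the configured arm", {
  grouped <- tibble::tibble(
    egg_id = sprintf("e%d", 1:6),
    amplitude = c(1, 1.5, 2, 2, 2.5, 3),
    outcome = rep("non-blastocyst", 6)
  )
  bot <- percentile_select(grouped, ties = "bottom")
  expect_equal(bot$n_bottom, 4)  # ties (= median 2) in the bottom arm
  top <- percentile_select(grouped, ties = "top")
  expect_equal(top$n_top, 4)
  # arm sizes differ by at most the number of tied eggs
  expect_lte(abs(bot$n_top - bot$n_bottom), 2)
})

test_that("selection rejects sparkless eggs and degenerate arms", {
  grouped <- tibble::tibble(egg_id = c("a", "b"), amplitude = c(NA, 1),
                            outcome = c("unactivated", "blastocyst"))
  expect_error(percentile_select(grouped), "first spark")
  tiny <- tibble::tibble(egg_id = c("a", "b"), amplitude = c(1, 2),
                         outcome = rep("blastocyst", 2))
  expect_error(percentile_select(tiny), ">= 2")
})

test_that("a null amplitude slope leaves the arms statistically even", {
  co <- simulate_cohort(
    2000,
    outcome = outcome_model_params(logistic_beta0 = -1, logistic_beta1 = 0),
    seed = 61
  )
  profiles <- lapply(co$traces, profile_trace)
  grouped <- assign_groups(co$records, profiles)
  sel <- percentile_select(grouped[!is.na(grouped$amplitude), ])
  expect_gt(sel$p_value, 0.001)
})

test_that("fertilization rate reports fraction and rounded percent", {
  recs <- tibble::tibble(egg_id = sprintf("e%d", 1:10), treatment = "IVF",
                         fertilized = rep(c(TRUE, FALSE), c(4, 6)))
  fr <- fertilization_rate(recs)
  expect_equal(fr$fraction, 0.4)
  expect_equal(fr$percent, 40)
  recs$fertilized <- FALSE
  expect_equal(fertilization_rate(recs)$percent, 0)
  recs$fertilized <- TRUE
  expect_equal(fertilization_rate(recs)$percent, 100)
  expect_error(fertilization_rate(tibble::tibble(treatment = character(0))),
               "no IVF")
})

test_that("pipeline recovers the generative rank correlation (20 seeds, n=40)", {
  # amplitude -> cell-count link is monotone with small noise; the
  # pipeline estimate should sit inside the central 95% Monte-Carlo band
  # of the generative (ground-truth) correlation
  # single-spark cohorts: the generative cell count is tied to the first
  # spark's amplitude, and with slowly decaying sparks a second spark can
  # merge into the first detection window, which would break the premise
  om <- outcome_model_params(cellcount_noise_sd = 2, logistic_beta1 = 1.5)
  singles <- spark_dist_params(p_multi = 0)
  gen <- numeric(20); est <- numeric(20)
  for (s in 1:20) {
    co <- simulate_cohort(40, spark_dist = singles, outcome = om,
                          seed = 300 + s)
    gen[s] <- co$truth$gen_spearman
    profiles <- lapply(co$traces, profile_trace)
    grouped <- assign_groups(co$records, profiles, mode = "staged")
    with_cells <- grouped[!is.na(grouped$cell_count) & !is.na(grouped$amplitude), ]
    est[s] <- correlate_amp_cells(with_cells$amplitude,
                                  with_cells$cell_count)$spearman_r
  }
  band <- stats::quantile(gen, c(0.025, 0.975))
  expect_gte(mean(est), band[[1]])
  expect_lte(mean(est), band[[2]])
  # and estimates track truth tightly seed by seed
  expect_lt(stats::median(abs(est - gen)), 0.1)
})
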