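test_that("sparkless noiseless trace is constant at baseline", {
  p <- spark_sim_params(baseline_level = 100, bleach_rate = 0, noise_sd = 0)
  sim <- simulate_trace(p)
  expect_equal(sim$trace$values, rep(100, 75))
  expect_equal(sim$trace$times, (0:74) * 4)
  expect_equal(sim$truth$spark_count, 0)
})

test_that("noiseless spark matches the closed form on a 100x finer grid", {
  p <- spark_sim_params(baseline_level = 250, spark_onsets = 128,
                        spark_amplitudes = 3, noise_sd = 0)
  sim <- simulate_trace(p)
  norm_excess <- sim$trace$values / 250 - 1

  dense_t <- seq(0, 296, by = 0.04)
  dense <- oracle_spark_excess(dense_t, 128, 3, p$rise_tau_s, p$decay_tau_s)
  # the sampled peak cannot exceed the continuous-form peak, and the
  # 4-s grid undershoots it by only a sliver
  expect_lte(max(norm_excess), max(dense) + 1e-12)
  expect_gt(max(norm_excess), 0.98 * max(dense))
  expect_equal(max(dense), 3, tolerance = 1e-6)
  # on the acquisition grid itself the match is exact
  on_grid <- oracle_spark_excess(sim$trace$times, 128, 3,
                                 p$rise_tau_s, p$decay_tau_s)
  expect_equal(norm_excess, on_grid, tolerance = 1e-12)
})

test_that("zero-noise zero-bleach traces equal baseline plus summed spark excess", {
  p <- spark_sim_params(baseline_level = 500,
                        spark_onsets = c(60, 160, 240),
                        spark_amplitudes = c(1.5, 2.5, 0.8), noise_sd = 0)
  sim <- simulate_trace(p)
  expected <- 500 * (1 +
    oracle_spark_excess(sim$trace$times, 60, 1.5, 4, 40) +
    oracle_spark_excess(sim$trace$times, 160, 2.5, 4, 40) +
    oracle_spark_excess(sim$trace$times, 240, 0.8, 4, 40))
  expect_lt(max(abs(sim$trace$values - expected)) / max(expected), 1e-9)
})

test_that("simulators are bit-identical under a fixed seed", {
  p <- spark_sim_params(spark_onsets = 100, spark_amplitudes = 2,
                        noise_sd = 30, poisson_noise = TRUE, seed = 11)
  expect_identical(simulate_trace(p)$trace$values,
                   simulate_trace(p)$trace$values)

  a <- simulate_cohort(20, seed = 7)
  b <- simulate_cohort(20, seed = 7)
  expect_identical(a$records, b$records)
  expect_identical(lapply(a$traces, `[[`, "values"),
                   lapply(b$traces, `[[`, "values"))

  pim <- spark_sim_params(n_frames = 10, spark_onsets = 24,
                          spark_amplitudes = 1, noise_sd = 10, seed = 3)
  s1 <- simulate_image_series(pim, frame_dim = c(64, 64),
                              center = c(31.5, 31.5), radius = 15)
  s2 <- simulate_image_series(pim, frame_dim = c(64, 64),
                              center = c(31.5, 31.5), radius = 15)
  expect_identical(s1$stack$data, s2$stack$data)

  n1 <- simulate_nucleus_stack(10, noise_sd = 5, seed = 9)
  n2 <- simulate_nucleus_stack(10, noise_sd = 5, seed = 9)
  expect_identical(n1$stack, n2$stack)
})

test_that("enlarging a cohort does not perturb earlier eggs' draws", {
  small <- simulate_cohort(10, seed = 21)
  big <- simulate_cohort(25, seed = 21)
  expect_identical(small$records, big$records[1:10, ])
  expect_identical(small$traces[["egg_003"]]$values,
                   big$traces[["egg_003"]]$values)
})

test_that("onset inside the F0 window is rejected", {
  expect_error(spark_sim_params(spark_onsets = 10, spark_amplitudes = 1),
               "F0")
  expect_error(spark_sim_params(n_frames = 5), "n_frames")
  expect_error(spark_sim_params(spark_onsets = 100, spark_amplitudes = -1),
               "amplitudes")
  expect_error(spark_sim_params(spark_onsets = c(100, 200),
                                spark_amplitudes = 1), "equal length")
})

test_that("with a null amplitude slope, outcome is independent of amplitude", {
  co <- simulate_cohort(
    2000,
    outcome = outcome_model_params(logistic_beta0 = -1, logistic_beta1 = 0),
    seed = 31
  )
  sparked <- co$truth$per_egg[co$truth$per_egg$spark_count > 0, ]
  hi <- sparked$first_amplitude > stats::median(sparked$first_amplitude)
  tab <- table(hi, sparked$outcome == "blastocyst")
  res <- compare_groups(tab, test = "chi2")
  expect_gt(res$p_value, 0.001)
})

test_that("a positive amplitude slope raises blastocyst amplitudes (10 seeds)", {
  wins <- vapply(1:10, function(s) {
    co <- simulate_cohort(500, seed = 100 + s)
    pe <- co$truth$per_egg[co$truth$per_egg$spark_count > 0, ]
    mean(pe$first_amplitude[pe$outcome == "blastocyst"]) >
      mean(pe$first_amplitude[pe$outcome != "blastocyst"])
  }, logical(1))
  expect_true(all(wins))
})

test_that("noiseless cell counts are rank-perfect in amplitude", {
  co <- simulate_cohort(
    30,
    outcome = outcome_model_params(cellcount_noise_sd = 0,
                                   cellcount_alpha1 = 200),
    seed = 41
  )
  pe <- co$truth$per_egg[!is.na(co$truth$per_egg$cell_count), ]
  expect_gte(nrow(pe), 3)
  # the deterministic link is monotone; with a slope steep relative to the
  # integer rounding granularity the counts are distinct and rank-perfect
  ord <- order(pe$first_amplitude)
  expect_true(all(diff(pe$cell_count[ord]) >= 0))
  expect_equal(stats::cor(pe$first_amplitude, pe$cell_count,
                          method = "spearman"), 1)
})

test_that("empirical blastocyst fraction matches the logistic expectation", {
  om <- outcome_model_params()
  co <- simulate_cohort(5000, outcome = om, seed = 51)
  pe <- co$truth$per_egg[co$truth$per_egg$spark_count > 0, ]
  p_hat <- mean(pe$outcome == "blastocyst")
  p_exp <- mean(stats::plogis(om$logistic_beta0 +
                              om$logistic_beta1 * pe$first_amplitude))
  se <- sqrt(p_exp * (1 - p_exp) / nrow(pe))
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("image-series ring trace matches the direct trace simulation", {
  p <- spark_sim_params(spark_onsets = 128, spark_amplitudes = 2.2,
                        noise_sd = 0)
  img <- simulate_image_series(p, center = c(63.5, 63.5), radius = 30,
                               ring_width = 5)
  direct <- simulate_trace(p)
  ring <- make_ring(roi_spec("interior", img$truth$center, img$truth$radius),
                    img$truth$ring_width)
  tr <- extract_trace(img$stack, ring)
  n_img <- normalize_trace(tr)$values
  n_dir <- normalize_trace(direct$trace)$values
  expect_lt(abs(max(n_img) - max(n_dir)) / (max(n_dir) - 1), 0.02)
  # peak within one frame of the ground-truth peak time
  t_peak <- tr$times[which.max(tr$values)]
  expect_lte(abs(t_peak - img$truth$peak_times[1]), 4)
})

test_that("sparkless zero-noise image stacks are constant over time", {
  p <- spark_sim_params(n_frames = 8, noise_sd = 0)
  img <- simulate_image_series(p, frame_dim = c(64, 64),
                               center = c(31.5, 31.5), radius = 15)
  for (t in 2:8) expect_identical(img$stack$data[, , t], img$stack$data[, , 1])
})

test_that("hemisphere mode confines spark excess to one half-plane", {
  p <- spark_sim_params(n_frames = 10, spark_onsets = 24,
                        spark_amplitudes = 2, noise_sd = 0)
  img <- simulate_image_series(p, frame_dim = c(64, 64),
                               center = c(31.5, 31.5), radius = 15,
                               hemisphere = TRUE)
  diffmap <- img$stack$data[, , 9] - img$stack$data[, , 1]
  xs <- matrix(rep(0:63, each = 64), nrow = 64)
  expect_true(all(diffmap[xs < 31.5] == 0))
  expect_gt(sum(diffmap[xs >= 31.5]), 0)
})

test_that("out-of-bounds egg geometry errors name the offending dimension", {
  p <- spark_sim_params(n_frames = 8)
  expect_error(simulate_image_series(p, frame_dim = c(64, 64),
                                     center = c(60, 31.5), radius = 15),
               "in x")
  expect_error(simulate_image_series(p, frame_dim = c(64, 64),
                                     center = c(31.5, 2), radius = 15),
               "in y")
})

test_that("nucleus stacks record ground truth and handle the empty case", {
  e <- simulate_nucleus_stack(0, dim_yxz = c(32, 32, 10), seed = 1)
  expect_equal(e$count, 0L)
  expect_equal(max(e$stack), 0)
  expect_equal(count_nuclei(e$stack), 0L)

  s80 <- simulate_nucleus_stack(80, seed = 2)
  expect_equal(nrow(s80$centers), 80)
  expect_equal(s80$count, 80L)
})

test_that("impossible nucleus packing fails with advice", {
  expect_error(simulate_nucleus_stack(500, dim_yxz = c(32, 32, 12),
                                      seed = 1, max_tries = 2000),
               "larger frame")
})
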