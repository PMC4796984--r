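#' Closed-form zinc-spark excess shape
#'
#' Temporal profile of a single spark's fluorescence excess over baseline:
#' a saturating rise multiplied by an exponential decay,
#' `(1 - exp(-s/rise_tau)) * exp(-s/decay_tau)` for time-since-onset
#' `s >= 0` and 0 before onset, rescaled so its maximum equals 1. With unit
#' peak, a spark of amplitude `a` contributes exactly `a` to F/F0 - 1 at
#' its peak, which occurs `rise_tau * log(1 + decay_tau/rise_tau)` seconds
#' after onset.
#'
#' @param t Numeric vector of times, seconds.
#' @param onset Spark onset time, seconds.
#' @param rise_tau,decay_tau Time constants, seconds.
#' @return Numeric vector in `[0, 1]`, same length as `t`.
#' @export
spark_shape <- function(t, onset, rise_tau, decay_tau) {
  s <- t - onset
  raw <- ifelse(s <= 0, 0, (1 - exp(-s / rise_tau)) * exp(-s / decay_tau))
  t_peak <- rise_tau * log(1 + decay_tau / rise_tau)
  peak <- (1 - exp(-t_peak / rise_tau)) * exp(-t_peak / decay_tau)
  raw / peak
}

#' Time from spark onset to peak
#'
#' @inheritParams spark_shape
#' @return Seconds from onset to the shape maximum.
#' @export
spark_peak_delay <- function(rise_tau, decay_tau) {
  rise_tau * log(1 + decay_tau / rise_tau)
}

#' Simulate a single-egg zinc fluorescence trace
#'
#' Generates the mean ROI intensity an annular extracellular ROI would
#' report: a dye baseline carrying zero or more spark transients, linear
#' photobleaching, and optional Poisson (shot) and Gaussian (read) noise.
#' Each spark adds `baseline_level * amplitude * spark_shape(t)` before
#' bleaching/noise, so the noiseless normalized trace peaks at
#' `1 + amplitude` (amplitudes are in F/F0 - 1 units).
#'
#' @param params A [spark_sim_params()] object.
#' @param egg_id Identifier stored on the returned trace.
#' @return A list with elements:
#'   \describe{
#'     \item{trace}{raw (un-normalized) [fluorescence_trace()]}
#'     \item{truth}{ground truth: `spark_count`, `onsets`, `amplitudes`
#'       (realized peak F/F0 - 1), `peak_times` (onset plus the
#'       closed-form peak delay)}
#'   }
#' @export
simulate_trace <- function(params, egg_id = "egg_1") {
  validate_spark_sim_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  idx <- seq_len(params$n_frames) - 1L
  times <- idx * params$frame_interval_s
  clean <- rep(params$baseline_level, params$n_frames)
  for (k in seq_along(params$spark_onsets)) {
    clean <- clean + params$baseline_level * params$spark_amplitudes[k] *
      spark_shape(times, params$spark_onsets[k],
                  params$rise_tau_s, params$decay_tau_s)
  }
  clean <- clean * (1 - params$bleach_rate * idx)
  vals <- clean
  if (params$poisson_noise) vals <- stats::rpois(length(vals), lambda = vals)
  if (params$noise_sd > 0) {
    vals <- vals + stats::rnorm(length(vals), sd = params$noise_sd)
  }
  truth <- list(
    spark_count = length(params$spark_onsets),
    onsets = params$spark_onsets,
    amplitudes = params$spark_amplitudes,
    peak_times = params$spark_onsets +
      spark_peak_delay(params$rise_tau_s, params$decay_tau_s)
  )
  list(
    trace = fluorescence_trace(egg_id, times, vals),
    truth = truth
  )
}

# Per-egg deterministic substream: each egg's draws depend only on the run
# seed and its own index, so enlarging a cohort never perturbs earlier eggs.
egg_seed <- function(seed, i) (as.integer(seed) + 7919L * as.integer(i)) %% 2147483647L

#' Simulate an outcome-labelled cohort of eggs
#'
#' Draws per-egg spark occurrence, count, onset and amplitude from
#' `spark_dist`, simulates one raw trace per egg, and assigns developmental
#' outcomes through the generative outcome model: sparkless eggs are
#' unactivated with probability `outcome$p_unactivated_given_no_spark`
#' (otherwise scored non-blastocyst); sparked eggs reach blastocyst with
#' probability `plogis(beta0 + beta1 * first-spark amplitude)`, and failing
#' that arrest as morula with probability `p_morula_given_nonblast` or
#' earlier. Morulae and blastocysts receive cell counts
#' `alpha0 + alpha1 * amplitude + N(0, cellcount_noise_sd)`, rounded and
#' floored at 1.
#'
#' @param n_eggs Number of eggs (>= 2).
#' @param spark_dist A [spark_dist_params()] object.
#' @param outcome An [outcome_model_params()] object.
#' @param trace_params A [spark_sim_params()] template; its spark fields
#'   are overwritten per egg, all acquisition/noise fields are kept.
#' @param treatment Treatment label stored on every record.
#' @param seed Integer run seed; expanded into per-egg substreams.
#' @return A list with elements:
#'   \describe{
#'     \item{traces}{named list of raw [fluorescence_trace()] objects}
#'     \item{records}{tibble of egg records: `egg_id, treatment, outcome,
#'       fertilized, cell_count`}
#'     \item{truth}{list: per-egg tibble (`egg_id, spark_count,
#'       first_onset_s, first_amplitude, outcome, cell_count`), full onset/
#'       amplitude lists, and `gen_spearman`, the realized rank correlation
#'       between true first-spark amplitude and true cell count among
#'       embryos with counts}
#'   }
#' @export
simulate_cohort <- function(n_eggs,
                            spark_dist = spark_dist_params(),
                            outcome = outcome_model_params(),
                            trace_params = spark_sim_params(),
                            treatment = c("Ca-Iono", "Iono", "IVF"),
                            seed = 1L) {
  treatment <- match.arg(treatment)
  if (n_eggs < 2) stop("n_eggs must be >= 2", call. = FALSE)
  stopifnot(inherits(spark_dist, "spark_dist_params"),
            inherits(outcome, "outcome_model_params"))
  total_s <- (trace_params$n_frames - 1) * trace_params$frame_interval_s
  f0_end <- 5 * trace_params$frame_interval_s

  traces <- vector("list", n_eggs)
  rec <- vector("list", n_eggs)
  tru <- vector("list", n_eggs)
  onsets_all <- vector("list", n_eggs)
  amps_all <- vector("list", n_eggs)

  for (i in seq_len(n_eggs)) {
    set.seed(egg_seed(seed, i))
    id <- sprintf("egg_%03d", i)
    has_spark <- stats::runif(1) < spark_dist$p_spark
    onsets <- numeric(0)
    amps <- numeric(0)
    if (has_spark) {
      n_sp <- if (stats::runif(1) < spark_dist$p_multi) sample(2:4, 1) else 1L
      first <- min(max(stats::rnorm(1, spark_dist$onset_mean_s,
                                    spark_dist$onset_sd_s), f0_end),
                   total_s * 0.6)
      gaps <- if (n_sp > 1) {
        cumsum(spark_dist$intersparkinterval_s +
                 stats::rexp(n_sp - 1, rate = 1 / spark_dist$intersparkinterval_s))
      } else numeric(0)
      onsets <- pmin(c(first, first + gaps), total_s)
      amps <- stats::rlnorm(n_sp, spark_dist$amp_meanlog, spark_dist$amp_sdlog)
    }
    p_i <- trace_params
    p_i$spark_onsets <- onsets
    p_i$spark_amplitudes <- amps
    p_i$rise_tau_s <- spark_dist$rise_tau_s
    p_i$decay_tau_s <- spark_dist$decay_tau_s
    p_i$seed <- NULL  # noise drawn from the per-egg stream set above
    sim <- simulate_trace(p_i, egg_id = id)
    traces[[i]] <- sim$trace

    if (!has_spark) {
      out_i <- if (stats::runif(1) < outcome$p_unactivated_given_no_spark) {
        "unactivated"
      } else "non-blastocyst"
      cells <- NA_integer_
    } else {
      a1 <- amps[1]
      p_bl <- stats::plogis(outcome$logistic_beta0 + outcome$logistic_beta1 * a1)
      if (stats::runif(1) < p_bl) {
        out_i <- "blastocyst"
      } else if (stats::runif(1) < outcome$p_morula_given_nonblast) {
        out_i <- "morula"
      } else {
        out_i <- "non-blastocyst"
      }
      cells <- if (out_i %in% c("morula", "blastocyst")) {
        max(1L, as.integer(round(outcome$cellcount_alpha0 +
                                   outcome$cellcount_alpha1 * a1 +
                                   stats::rnorm(1, sd = outcome$cellcount_noise_sd))))
      } else NA_integer_
    }
    rec[[i]] <- tibble::tibble(
      egg_id = id, treatment = treatment, outcome = out_i,
      fertilized = if (treatment == "IVF") has_spark else NA,
      cell_count = cells
    )
    tru[[i]] <- tibble::tibble(
      egg_id = id, spark_count = length(onsets),
      first_onset_s = if (length(onsets)) onsets[1] else NA_real_,
      first_amplitude = if (length(amps)) amps[1] else NA_real_,
      outcome = out_i, cell_count = cells
    )
    onsets_all[[i]] <- onsets
    amps_all[[i]] <- amps
  }

  names(traces) <- vapply(traces, function(tr) tr$egg_id, character(1))
  records <- do.call(rbind, rec)
  per_egg <- do.call(rbind, tru)
  with_cells <- !is.na(per_egg$cell_count)
  gen_spearman <- if (sum(with_cells) >= 3) {
    stats::cor(per_egg$first_amplitude[with_cells],
               per_egg$cell_count[with_cells], method = "spearman")
  } else NA_real_
  list(
    traces = traces,
    records = records,
    truth = list(per_egg = per_egg, onsets = onsets_all,
                 amplitudes = amps_all, gen_spearman = gen_spearman)
  )
}
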