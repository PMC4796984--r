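#' Simulation parameters for a single zinc-spark trace
#'
#' Bundles the acquisition and signal-model constants used by
#' [simulate_trace()] and [simulate_image_series()]. Defaults follow the
#' standard live-imaging protocol for mouse egg activation: one frame every
#' 4 seconds for 5 minutes (75 frames).
#'
#' @param n_frames Number of frames acquired. Must be at least 6 so that a
#'   five-frame F0 baseline window leaves at least one data frame.
#' @param frame_interval_s Time between frames in seconds.
#' @param baseline_level Resting dye fluorescence in arbitrary intensity
#'   units (the F0 level before bleaching and noise).
#' @param bleach_rate Linear photobleaching as fraction of signal lost per
#'   frame; frame i is scaled by `1 - bleach_rate * i`.
#' @param spark_onsets Numeric vector of spark onset times in seconds.
#'   Onsets must lie at or after the end of the five-frame baseline window
#'   (`5 * frame_interval_s`) and within the recording.
#' @param spark_amplitudes Numeric vector, same length as `spark_onsets`:
#'   realized peak height of each spark in F/F0 - 1 units (fold over
#'   baseline at the peak).
#' @param rise_tau_s Time constant of the saturating rise, seconds.
#' @param decay_tau_s Time constant of the exponential decay, seconds.
#' @param noise_sd Gaussian read-noise standard deviation, intensity units.
#' @param poisson_noise If `TRUE`, photon shot noise is applied by drawing
#'   each sample from a Poisson distribution with the noiseless value as
#'   its mean (before Gaussian noise is added).
#' @param seed Optional integer seed; fixing it makes the simulated trace
#'   bit-identical across runs.
#'
#' @return An object of class `spark_sim_params`.
#' @seealso [simulate_trace()], [simulate_image_series()]
#' @export
spark_sim_params <- function(n_frames = 75L,
                             frame_interval_s = 4,
                             baseline_level = 1000,
                             bleach_rate = 0,
                             spark_onsets = numeric(0),
                             spark_amplitudes = numeric(0),
                             rise_tau_s = 4,
                             decay_tau_s = 40,
                             noise_sd = 0,
                             poisson_noise = FALSE,
                             seed = NULL) {
  p <- list(
    n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s,
    baseline_level = baseline_level,
    bleach_rate = bleach_rate,
    spark_onsets = as.numeric(spark_onsets),
    spark_amplitudes = as.numeric(spark_amplitudes),
    rise_tau_s = rise_tau_s,
    decay_tau_s = decay_tau_s,
    noise_sd = noise_sd,
    poisson_noise = isTRUE(poisson_noise),
    seed = seed
  )
  class(p) <- "spark_sim_params"
  validate_spark_sim_params(p)
  p
}

validate_spark_sim_params <- function(p) {
  stopifnot(inherits(p, "spark_sim_params"))
  if (p$n_frames < 6L) {
    stop("n_frames must be >= 6: the F0 baseline uses five frames and at ",
         "least one data frame must follow", call. = FALSE)
  }
  if (p$frame_interval_s <= 0) stop("frame_interval_s must be positive", call. = FALSE)
  if (p$baseline_level <= 0) stop("baseline_level must be positive", call. = FALSE)
  if (p$bleach_rate < 0 || p$bleach_rate * (p$n_frames - 1) >= 1) {
    stop("bleach_rate must be in [0, 1/(n_frames-1)): linear bleaching may not ",
         "drive the signal to zero within the recording", call. = FALSE)
  }
  if (length(p$spark_onsets) != length(p$spark_amplitudes)) {
    stop("spark_onsets and spark_amplitudes must have equal length", call. = FALSE)
  }
  if (any(p$spark_amplitudes <= 0)) stop("spark amplitudes must be > 0", call. = FALSE)
  total <- (p$n_frames - 1) * p$frame_interval_s
  f0_end <- 5 * p$frame_interval_s
  if (any(p$spark_onsets < f0_end)) {
    stop("spark onset inside the first five frames would corrupt the F0 ",
         "baseline window; onsets must be >= ", f0_end, " s", call. = FALSE)
  }
  if (any(p$spark_onsets > total)) {
    stop("spark onsets must lie within the recording (<= ", total, " s)",
         call. = FALSE)
  }
  if (p$rise_tau_s <= 0 || p$decay_tau_s <= 0) {
    stop("rise_tau_s and decay_tau_s must be positive", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(p)
}

#' Generative outcome-model parameters for simulated cohorts
#'
#' Parameters of the stand-in stochastic process that links a simulated
#' egg's zinc-spark amplitude to its developmental outcome and, for embryos
#' reaching the morula or blastocyst stage, its total cell number. Eggs
#' that release no spark become unactivated with probability
#' `p_unactivated_given_no_spark`; sparked eggs reach the blastocyst stage
#' with probability `plogis(logistic_beta0 + logistic_beta1 * amplitude)`,
#' and the remainder arrest as morulae (with probability
#' `p_morula_given_nonblast`) or earlier. Cell counts follow
#' `cellcount_alpha0 + cellcount_alpha1 * amplitude` plus Gaussian noise,
#' rounded to positive integers.
#'
#' Defaults are chosen so that typical amplitudes (log-normal around 2
#' F/F0-1 units) yield morulae near 30 cells and blastocysts near 50 cells,
#' the range reported for imaged embryos, with non-imaged controls above
#' `control_cells_min`.
#'
#' @param p_unactivated_given_no_spark Probability that a sparkless egg is
#'   scored unactivated (no pronucleus by 8 h).
#' @param logistic_beta0,logistic_beta1 Intercept and per-amplitude-unit
#'   slope of the blastocyst logistic model; `logistic_beta1 > 0` encodes
#'   positive dependence of outcome on spark amplitude.
#' @param p_morula_given_nonblast Probability that a sparked egg that fails
#'   to reach blastocyst arrests at the morula stage (so acquires a cell
#'   count) rather than earlier.
#' @param cellcount_alpha0,cellcount_alpha1 Intercept (cells) and slope
#'   (cells per amplitude unit) of the cell-count model.
#' @param cellcount_noise_sd Gaussian noise on cell counts, cells.
#' @param morula_cells_mean,blastocyst_cells_mean Nominal stage means
#'   (cells), used as documentation anchors for the defaults.
#' @param control_cells_min Minimum cell count of non-imaged control
#'   embryos (cells).
#'
#' @return An object of class `outcome_model_params`.
#' @seealso [simulate_cohort()]
#' @export
outcome_model_params <- function(p_unactivated_given_no_spark = 0.8,
                                 logistic_beta0 = -3,
                                 logistic_beta1 = 1,
                                 p_morula_given_nonblast = 0.5,
                                 cellcount_alpha0 = 10,
                                 cellcount_alpha1 = 12,
                                 cellcount_noise_sd = 4,
                                 morula_cells_mean = 30,
                                 blastocyst_cells_mean = 50,
                                 control_cells_min = 80) {
  probs <- c(p_unactivated_given_no_spark, p_morula_given_nonblast)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cellcount_noise_sd < 0) stop("cellcount_noise_sd must be >= 0", call. = FALSE)
  structure(
    list(
      p_unactivated_given_no_spark = p_unactivated_given_no_spark,
      logistic_beta0 = logistic_beta0,
      logistic_beta1 = logistic_beta1,
      p_morula_given_nonblast = p_morula_given_nonblast,
      cellcount_alpha0 = cellcount_alpha0,
      cellcount_alpha1 = cellcount_alpha1,
      cellcount_noise_sd = cellcount_noise_sd,
      morula_cells_mean = morula_cells_mean,
      blastocyst_cells_mean = blastocyst_cells_mean,
      control_cells_min = control_cells_min
    ),
    class = "outcome_model_params"
  )
}

#' Distribution of spark occurrence and shape across a simulated cohort
#'
#' @param p_spark Probability that an egg releases at least one spark.
#' @param p_multi Probability, given at least one spark, of releasing
#'   multiple (2-4) sparks; default matches the observed 7-of-42 fraction
#'   of multi-spark fertilized eggs.
#' @param amp_meanlog,amp_sdlog Log-normal parameters of the first-spark
#'   amplitude (F/F0 - 1 units). The amplitude distribution across eggs is
#'   unreported in the literature; log-normal is a modelling choice for a
#'   positive, right-skewed quantity.
#' @param onset_mean_s,onset_sd_s Normal parameters of first-spark onset
#'   latency in seconds; the default 128 s mean matches the one directly
#'   observed sperm-entry-to-spark latency (2 min 8 s).
#' @param intersparkinterval_s Minimum spacing between successive sparks of
#'   one egg, seconds.
#' @param rise_tau_s,decay_tau_s Spark shape time constants, seconds.
#'
#' @return An object of class `spark_dist_params`.
#' @export
spark_dist_params <- function(p_spark = 0.85,
                              p_multi = 7 / 42,
                              amp_meanlog = log(2),
                              amp_sdlog = 0.4,
                              onset_mean_s = 128,
                              onset_sd_s = 30,
                              intersparkinterval_s = 40,
                              rise_tau_s = 4,
                              decay_tau_s = 40) {
  if (p_spark < 0 || p_spark > 1 || p_multi < 0 || p_multi > 1) {
    stop("p_spark and p_multi must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      p_spark = p_spark, p_multi = p_multi,
      amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
      onset_mean_s = onset_mean_s, onset_sd_s = onset_sd_s,
      intersparkinterval_s = intersparkinterval_s,
      rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s
    ),
    class = "spark_dist_params"
  )
}
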