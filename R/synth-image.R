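#' Simulate a zinc-spark time-lapse image stack
#'
#' Renders the single-egg geometry seen in extracellular-dye imaging: the
#' background carries the dye baseline, the cell interior excludes dye and
#' sits at `interior_frac` of baseline, and each spark's excess is emitted
#' from an annular shell at the egg perimeter with the same temporal shape
#' as [simulate_trace()] — so a mean-intensity trace over the true ring,
#' normalized to its first-five-frame mean, reproduces the direct trace
#' simulation. Linear bleaching scales whole frames; Poisson and Gaussian
#' noise are applied per pixel.
#'
#' @param params A [spark_sim_params()]; `baseline_level` is the per-pixel
#'   dye background in counts.
#' @param center Egg center `(x, y)`, 0-based pixels.
#' @param radius Egg radius, pixels.
#' @param ring_width Width of the emitting perimeter shell, pixels.
#' @param frame_dim Frame size `(width, height)` in pixels.
#' @param interior_frac Interior intensity as a fraction of baseline
#'   (dye-excluding cytoplasm; default 0.25).
#' @param hemisphere If `TRUE`, spark emission is confined to the half of
#'   the ring with pixel x-coordinate >= the center's (the cortical
#'   polarization seen when zinc release localizes opposite sperm entry).
#' @param egg_id Identifier used for ground truth.
#' @return List: `stack` (an [image_stack()]), `truth` (as in
#'   [simulate_trace()], plus `center`, `radius`, `ring_width`).
#' @export
simulate_image_series <- function(params, center = c(63.5, 63.5), radius = 30,
                                  ring_width = 5, frame_dim = c(128, 128),
                                  interior_frac = 0.25, hemisphere = FALSE,
                                  egg_id = "egg_1") {
  validate_spark_sim_params(params)
  width <- frame_dim[1]; height <- frame_dim[2]
  outer <- radius + ring_width
  lims <- c(x_min = center[1] - outer, x_max = center[1] + outer,
            y_min = center[2] - outer, y_max = center[2] + outer)
  if (lims["x_min"] < 0 || lims["x_max"] > width - 1) {
    stop("egg disk plus ring exceeds frame in x (needs [",
         round(lims["x_min"], 1), ", ", round(lims["x_max"], 1),
         "], frame width ", width, ")", call. = FALSE)
  }
  if (lims["y_min"] < 0 || lims["y_max"] > height - 1) {
    stop("egg disk plus ring exceeds frame in y (needs [",
         round(lims["y_min"], 1), ", ", round(lims["y_max"], 1),
         "], frame height ", height, ")", call. = FALSE)
  }
  if (!is.null(params$seed)) set.seed(params$seed)

  interior <- roi_spec("interior", center, radius)
  ring <- make_ring(interior, ring_width)
  m_int <- roi_mask(interior, width, height)
  m_ring <- roi_mask(ring, width, height)
  emit <- m_ring
  if (hemisphere) {
    xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
    emit <- emit & (xs >= center[1])
  }

  base_frame <- matrix(params$baseline_level, height, width)
  base_frame[m_int] <- interior_frac * params$baseline_level

  idx <- seq_len(params$n_frames) - 1L
  times <- idx * params$frame_interval_s
  excess_t <- rep(0, params$n_frames)
  for (k in seq_along(params$spark_onsets)) {
    excess_t <- excess_t + params$baseline_level * params$spark_amplitudes[k] *
      spark_shape(times, params$spark_onsets[k],
                  params$rise_tau_s, params$decay_tau_s)
  }

  data <- array(0, dim = c(height, width, params$n_frames))
  for (t in seq_len(params$n_frames)) {
    fr <- base_frame
    fr[emit] <- fr[emit] + excess_t[t]
    fr <- fr * (1 - params$bleach_rate * idx[t])
    if (params$poisson_noise) {
      fr <- matrix(stats::rpois(length(fr), lambda = pmax(fr, 0)), height, width)
    }
    if (params$noise_sd > 0) {
      fr <- fr + matrix(stats::rnorm(length(fr), sd = params$noise_sd),
                        height, width)
    }
    data[, , t] <- fr
  }

  meta <- image_stack_meta(params$n_frames, params$frame_interval_s,
                           width = width, height = height)
  truth <- list(
    spark_count = length(params$spark_onsets),
    onsets = params$spark_onsets,
    amplitudes = params$spark_amplitudes,
    peak_times = params$spark_onsets +
      spark_peak_delay(params$rise_tau_s, params$decay_tau_s),
    center = center, radius = radius, ring_width = ring_width
  )
  list(stack = image_stack(data, meta), truth = truth)
}
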