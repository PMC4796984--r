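#' Normalize a trace to F/F0
#'
#' F0 is the mean of the first `n_baseline` raw measurements (five by
#' convention, taken before any spark), and every sample is divided by it,
#' so the mean of the first five normalized values is exactly 1. The
#' baseline window is fixed at the start of the recording; if spark
#' detection later finds an event starting inside it, the profile is
#' flagged rather than the baseline re-anchored (see [profile_trace()]).
#'
#' @param trace A raw [fluorescence_trace()].
#' @param n_baseline Number of leading frames averaged into F0.
#' @return The normalized trace with `$normalized = TRUE` and `$F0` set.
#' @export
normalize_trace <- function(trace, n_baseline = 5L) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (trace$normalized) {
    stop("trace is already normalized; refusing to normalize twice",
         call. = FALSE)
  }
  if (length(trace$values) < n_baseline + 1L) {
    stop("trace has ", length(trace$values), " samples; at least ",
         n_baseline + 1L, " required", call. = FALSE)
  }
  F0 <- mean(trace$values[seq_len(n_baseline)])
  if (F0 <= 0) stop("F0 = ", F0, " is not positive; cannot normalize", call. = FALSE)
  trace$values <- trace$values / F0
  trace$normalized <- TRUE
  trace$F0 <- F0
  trace
}

#' Detect spark events in a normalized trace
#'
#' Threshold-crossing detection against the pre-spark baseline: the
#' baseline noise `sigma_b` is the standard deviation of the first five
#' normalized values, floored at a robust whole-trace noise estimate
#' (median absolute successive difference scaled for Gaussian noise, which
#' transients barely perturb) and at `sigma_floor` so noiseless traces
#' still have a usable threshold — a five-sample SD alone frequently
#' underestimates the noise and admits spurious two-frame events. An event
#' starts at the first of at least
#' `min_rise_frames` consecutive frames exceeding `1 + k_sigma * sigma_b`
#' and ends at the first frame after the peak falling below
#' `1 + end_sigma * sigma_b`; a trace that ends mid-event is right-censored
#' at the last frame. Events separated by at least one sub-threshold frame
#' are distinct.
#'
#' @param trace A normalized [fluorescence_trace()].
#' @param k_sigma Start-threshold multiplier (default 3).
#' @param min_rise_frames Consecutive supra-threshold frames required to
#'   declare an event (default 2).
#' @param end_sigma End-threshold multiplier (default 1).
#' @param sigma_floor Lower bound on `sigma_b` (default 1e-6).
#' @return A data.frame of event windows with 1-based frame indices:
#'   `start_idx, peak_idx, end_idx, censored`, ordered in time. Zero rows
#'   when no event is found.
#' @export
detect_sparks <- function(trace, k_sigma = 3, min_rise_frames = 2L,
                          end_sigma = 1, sigma_floor = 1e-6) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (!trace$normalized) stop("detect_sparks expects a normalized trace", call. = FALSE)
  v <- trace$values
  n <- length(v)
  sigma_b <- max(stats::sd(v[1:5]), robust_noise_sd(v), sigma_floor)
  thr_start <- 1 + k_sigma * sigma_b
  thr_end <- 1 + end_sigma * sigma_b

  out <- list()
  i <- 1L
  while (i <= n - min_rise_frames + 1L) {
    run <- v[i:(i + min_rise_frames - 1L)] > thr_start
    if (all(run)) {
      start <- i
      # advance to the peak: scan until the value drops below the end
      # threshold or the trace runs out
      j <- start
      while (j < n && v[j + 1L] >= thr_end) j <- j + 1L
      censored <- (j == n) && v[n] >= thr_end
      end <- if (censored) n else min(j + 1L, n)
      seg <- v[start:end]
      peak <- start + which.max(seg) - 1L  # which.max: earliest on ties
      out[[length(out) + 1L]] <- data.frame(
        start_idx = start, peak_idx = peak, end_idx = end,
        censored = censored
      )
      i <- end + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start_idx = integer(0), peak_idx = integer(0),
                      end_idx = integer(0), censored = logical(0)))
  }
  do.call(rbind, out)
}

#' Profile one detected spark event
#'
#' Computes the four spark parameters on a window of the normalized trace:
#' amplitude (maximum peak height above baseline, `max(F/F0) - 1`),
#' integrated intensity (trapezoidal area under `F/F0 - 1` with negative
#' excursions clipped to 0, in (F/F0-1)-seconds), duration (end minus
#' start, seconds) and rate of rise (amplitude divided by the rising time,
#' peak minus start). On a plateau peak the earlier frame is taken as the
#' peak; when the peak coincides with the window start the rising time is
#' 0 and the rate of rise is reported missing.
#'
#' @param trace A normalized [fluorescence_trace()].
#' @param window One row of the [detect_sparks()] output (or any list with
#'   `start_idx`, `end_idx` and optionally `censored`, 1-based inclusive).
#' @return A one-row tibble (class `spark_event` rows): `start_s, peak_s,
#'   end_s, F0, amplitude, integrated_intensity, duration_s,
#'   rising_time_s, rate_of_rise, censored`.
#' @export
profile_event <- function(trace, window) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (!trace$normalized) stop("profile_event expects a normalized trace", call. = FALSE)
  s <- as.integer(window$start_idx)
  e <- as.integer(window$end_idx)
  if (is.na(s) || is.na(e) || e < s) stop("empty or invalid event window", call. = FALSE)
  if (s < 1L || e > length(trace$values)) {
    stop("event window outside the trace", call. = FALSE)
  }
  v <- trace$values[s:e]
  t <- trace$times[s:e]
  peak_rel <- which.max(v)  # earliest frame on ties
  amplitude <- v[peak_rel] - 1
  excess <- pmax(v - 1, 0)
  auc <- if (length(t) > 1) pracma::trapz(t, excess) else 0
  rising <- t[peak_rel] - t[1]
  tibble::tibble(
    start_s = t[1],
    peak_s = t[peak_rel],
    end_s = t[length(t)],
    F0 = trace$F0,
    amplitude = amplitude,
    integrated_intensity = auc,
    duration_s = t[length(t)] - t[1],
    rising_time_s = rising,
    rate_of_rise = if (rising > 0) amplitude / rising else NA_real_,
    censored = isTRUE(window$censored)
  )
}

#' Detect and profile all sparks of one egg
#'
#' Normalizes a raw trace (unless already normalized), detects events and
#' profiles each, returning the egg's spark profile. F0 must be measured
#' before any spark; if the first event's rise reaches back into the F0
#' baseline window the profile is flagged `invalid_baseline` instead of
#' silently accepting a contaminated F0. The rise is traced back from the
#' detected start through every preceding frame still above the end
#' threshold (`1 + end_sigma * sigma_b`), so slow onsets that straddle the
#' window boundary are caught even though the formal start threshold is
#' crossed later.
#'
#' @param trace A raw or normalized [fluorescence_trace()].
#' @param n_baseline Baseline frames for F0 (default 5).
#' @param ... Passed to [detect_sparks()].
#' @return An object of class `spark_profile`: list with `egg_id`,
#'   `events` (tibble, one row per event ordered by start time),
#'   `spark_count`, `first_event` (one-row tibble or `NULL`),
#'   `invalid_baseline` flag, and the normalized `trace`.
#' @export
profile_trace <- function(trace, n_baseline = 5L, ...) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (!trace$normalized) trace <- normalize_trace(trace, n_baseline)
  windows <- detect_sparks(trace, ...)
  events <- if (nrow(windows)) {
    do.call(rbind, lapply(seq_len(nrow(windows)),
                          function(i) profile_event(trace, windows[i, ])))
  } else {
    profile_event_empty()
  }
  invalid <- FALSE
  if (nrow(windows)) {
    dots <- list(...)
    end_sigma <- dots$end_sigma %||% 1
    sigma_floor <- dots$sigma_floor %||% 1e-6
    sigma_b <- max(stats::sd(trace$values[1:5]),
                   robust_noise_sd(trace$values), sigma_floor)
    thr_end <- 1 + end_sigma * sigma_b
    onset <- windows$start_idx[1]
    while (onset > 1L && trace$values[onset - 1L] >= thr_end) onset <- onset - 1L
    invalid <- onset <= n_baseline
  }
  structure(
    list(egg_id = trace$egg_id, events = events,
         spark_count = nrow(events),
         first_event = if (nrow(events)) events[1, ] else NULL,
         invalid_baseline = invalid, trace = trace),
    class = "spark_profile"
  )
}

# Robust per-frame noise estimate: successive differences of iid Gaussian
# noise have SD sigma*sqrt(2), and their median absolute value is
# sigma*sqrt(2)*qnorm(0.75); isolated transients contribute only a few
# large differences, which the median ignores.
robust_noise_sd <- function(v) {
  stats::median(abs(diff(v))) / (sqrt(2) * stats::qnorm(0.75))
}

profile_event_empty <- function() {
  tibble::tibble(
    start_s = numeric(0), peak_s = numeric(0), end_s = numeric(0),
    F0 = numeric(0), amplitude = numeric(0),
    integrated_intensity = numeric(0), duration_s = numeric(0),
    rising_time_s = numeric(0), rate_of_rise = numeric(0),
    censored = logical(0)
  )
}

#' @export
print.spark_profile <- function(x, ...) {
  cat(sprintf("<spark_profile> egg %s | %d spark(s)%s\n", x$egg_id,
              x$spark_count,
              if (x$invalid_baseline) " | INVALID BASELINE" else ""))
  if (x$spark_count) print(x$events)
  invisible(x)
}

#' First spark of a profile
#'
#' The earliest event by start time, the event used when relating spark
#' parameters to developmental outcome, or `NULL` for sparkless eggs.
#'
#' @param profile A [profile_trace()] result.
#' @return One-row event tibble, or `NULL` when no spark was detected.
#' @export
first_spark <- function(profile) {
  stopifnot(inherits(profile, "spark_profile"))
  if (profile$spark_count == 0) return(NULL)
  ord <- order(profile$events$start_s)
  profile$events[ord[1], ]
}

#' Tabulate spark events across a cohort
#'
#' @param profiles Named list of [profile_trace()] results.
#' @return Tidy tibble, one row per event: `egg_id, event_index` plus all
#'   [profile_event()] columns and `invalid_baseline`.
#' @export
events_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (!p$spark_count) return(NULL)
    ev <- p$events
    tibble::tibble(egg_id = p$egg_id,
                   event_index = seq_len(nrow(ev)) - 1L,
                   ev, invalid_baseline = p$invalid_baseline)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- tibble::tibble(egg_id = character(0), event_index = integer(0),
                          profile_event_empty(), invalid_baseline = logical(0))
  }
  out
}
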