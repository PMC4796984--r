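#' Construct a fluorescence trace
#'
#' A fluorescence trace is one egg's mean ROI intensity sampled over time
#' in a single channel — the unit consumed by [normalize_trace()] and the
#' spark profiler.
#'
#' @param egg_id Character identifier of the egg.
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing, starting at 0 for the first frame.
#' @param values Numeric vector of intensities, same length as `times`.
#' @param channel Channel label, `"zinc_extracellular"` or
#'   `"calcium_intracellular"`.
#' @param normalized Whether `values` are already F/F0-normalized.
#' @param F0 Baseline fluorescence used for normalization (`NA` until
#'   [normalize_trace()] is applied).
#'
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(egg_id, times, values,
                               channel = c("zinc_extracellular",
                                           "calcium_intracellular"),
                               normalized = FALSE, F0 = NA_real_) {
  channel <- match.arg(channel)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 6L) {
    stop("a trace needs at least 6 samples (five-frame F0 window plus data)",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  structure(
    list(egg_id = as.character(egg_id), times = times, values = values,
         channel = channel, normalized = isTRUE(normalized), F0 = F0),
    class = "fluorescence_trace"
  )
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_trace> egg %s | %d frames @ %.3g s | channel %s | %s\n",
    x$egg_id, length(x$times), if (length(x$times) > 1) diff(x$times[1:2]) else NA,
    x$channel,
    if (x$normalized) sprintf("normalized (F0 = %.4g)", x$F0) else "raw"
  ))
  invisible(x)
}

#' @export
length.fluorescence_trace <- function(x) length(x$times)

#' Write traces to a tidy CSV
#'
#' One row per frame with columns `egg_id, frame, time_s, intensity,
#' channel`. Frame indices are 0-based.
#'
#' @param traces A `fluorescence_trace` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(egg_id = tr$egg_id,
               frame = seq_along(tr$times) - 1L,
               time_s = tr$times,
               intensity = tr$values,
               channel = tr$channel)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read traces from a tidy CSV
#'
#' Inverse of [write_traces_csv()]. Traces are returned raw (not
#' normalized) in frame order.
#'
#' @param path CSV path with columns `egg_id, frame, time_s, intensity,
#'   channel`.
#' @return Named list of `fluorescence_trace` objects.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("egg_id", "frame", "time_s", "intensity", "channel")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$egg_id), function(d) {
    d <- d[order(d$frame), ]
    fluorescence_trace(d$egg_id[1], d$time_s, d$intensity,
                       channel = d$channel[1])
  })
  out[order(names(out))]
}
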