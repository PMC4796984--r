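#!/usr/bin/env Rscript
# Stage 2: normalize every trace to F/F0, detect spark events and compute
# the four profile parameters per event. Reads the stage-1 traces, writes
# results/events.csv.

library(zincspark)

traces <- read_traces_csv("results/traces.csv")
profiles <- lapply(traces, profile_trace)
ev <- events_table(profiles)
write.csv(ev, "results/events.csv", row.names = FALSE)

counts <- vapply(profiles, function(p) p$spark_count, integer(1))
cat(sprintf("profiled %d eggs: %d sparkless, %d single-spark, %d multi-spark\n",
            length(profiles), sum(counts == 0), sum(counts == 1),
            sum(counts > 1)))
cat(sprintf("%d events total; median amplitude %.2f, median duration %.0f s\n",
            nrow(ev), median(ev$amplitude), median(ev$duration_s)))
if (any(vapply(profiles, function(p) p$invalid_baseline, logical(1)))) {
  cat("WARNING: some profiles have events rising out of the F0 window\n")
}
cat("wrote results/events.csv\n")
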