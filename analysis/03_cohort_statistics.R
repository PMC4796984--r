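#!/usr/bin/env Rscript
# Stage 3: cohort statistics. Groups eggs by developmental outcome,
# compares first-spark parameters between blastocyst and non-blastocyst
# embryos (relative to the non-blastocyst mean), correlates amplitude with
# embryo cell number on Z scores, and evaluates the median-split
# prospective selection. Reads stage-1/2 outputs, writes
# results/group_summary.csv and results/cohort_report.json.

library(zincspark)

records <- tibble::as_tibble(read.csv("results/records.csv"))
traces <- read_traces_csv("results/traces.csv")
profiles <- lapply(traces, profile_trace)

grouped <- assign_groups(records, profiles, mode = "collapsed")
sparked <- grouped[!is.na(grouped$amplitude), ]
comp <- sparked[sparked$group %in% c("blastocyst", "non-blastocyst"), ]

summaries <- list()
for (param in c("amplitude", "integrated_intensity", "duration_s",
                "rate_of_rise")) {
  s <- normalize_to_reference(comp[[param]], comp$group)
  t <- compare_groups(comp[[param]], comp$group, test = "welch_t")
  s$parameter <- param
  s$p_value <- t$p_value
  summaries[[param]] <- s
  cat(sprintf("%-22s blastocyst/non-blastocyst = %.2f (Welch t, p = %.2g)\n",
              param, s$rel_mean[s$group == "blastocyst"], t$p_value))
}
summary_tab <- do.call(rbind, summaries)
write.csv(summary_tab, "results/group_summary.csv", row.names = FALSE)

staged <- assign_groups(records, profiles, mode = "staged")
with_cells <- staged[!is.na(staged$cell_count) & !is.na(staged$amplitude), ]
corr <- correlate_amp_cells(with_cells$amplitude, with_cells$cell_count)
cat(sprintf("amplitude vs cell number: Spearman R = %.4f (n = %d); ",
            corr$spearman_r, corr$n))
cat(sprintf("z-score fit slope %.3f, intercept %.3g\n", corr$slope,
            corr$intercept))

sel <- percentile_select(sparked)
cat(sprintf("median split at amplitude %.2f: top %d/%d (%.0f%%) vs bottom %d/%d (%.0f%%) blastocysts, fold %.2f (chi2 p = %.3g)\n",
            sel$cutoff, sel$blastocysts_top, sel$n_top, sel$pct_top,
            sel$blastocysts_bottom, sel$n_bottom, sel$pct_bottom,
            sel$rate_ratio, sel$p_value))

report <- list(groups = as.list(table(grouped$group)),
               correlation = corr, selection = sel)
jsonlite::write_json(report, "results/cohort_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/group_summary.csv, results/cohort_report.json\n")
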