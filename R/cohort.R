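#' Group eggs by developmental outcome
#'
#' Joins per-egg outcome records with spark profiles and assigns the
#' analysis grouping. In `"collapsed"` mode (amplitude/integrated-intensity
#' group comparisons) the three groups are unactivated, non-blastocyst and
#' blastocyst, with morulae counted as non-blastocyst; in `"staged"` mode
#' (cell-number analyses) morula and blastocyst stay distinct.
#'
#' @param records Tibble of egg records (`egg_id, treatment, outcome`,
#'   optionally `fertilized`, `cell_count`).
#' @param profiles Named list of [profile_trace()] results; every record
#'   must have a matching profile (an empty profile is valid).
#' @param mode `"collapsed"` or `"staged"`.
#' @return The records tibble with columns `group`, `spark_count`, and the
#'   first-spark parameters (`amplitude`, `integrated_intensity`,
#'   `duration_s`, `rate_of_rise`; `NA` for sparkless eggs).
#' @export
assign_groups <- function(records, profiles, mode = c("collapsed", "staged")) {
  mode <- match.arg(mode)
  missing_ids <- setdiff(records$egg_id, names(profiles))
  if (length(missing_ids)) {
    stop("records without a matching profile: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  known <- c("unactivated", "non-blastocyst", "morula", "blastocyst")
  bad <- setdiff(unique(records$outcome), known)
  if (length(bad)) stop("unknown outcome label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  group <- records$outcome
  if (mode == "collapsed") group[group == "morula"] <- "non-blastocyst"

  fs <- lapply(records$egg_id, function(id) first_spark(profiles[[id]]))
  pick <- function(field) {
    vapply(fs, function(ev) if (is.null(ev)) NA_real_ else ev[[field]], numeric(1))
  }
  tibble::tibble(
    records,
    group = group,
    spark_count = vapply(records$egg_id,
                         function(id) profiles[[id]]$spark_count, integer(1)),
    amplitude = pick("amplitude"),
    integrated_intensity = pick("integrated_intensity"),
    duration_s = pick("duration_s"),
    rate_of_rise = pick("rate_of_rise")
  )
}

#' Reference-normalized group summaries
#'
#' Per-group mean and SEM of a spark parameter, re-expressed relative to a
#' reference group whose normalized mean is exactly 1 (group comparisons
#' are conventionally presented relative to the non-blastocyst group).
#' SEMs are scaled by the same factor, so the display is invariant to
#' rescaling the raw values.
#'
#' @param values Numeric vector of per-egg parameter values.
#' @param labels Group label per value.
#' @param reference Reference group name (default `"non-blastocyst"`).
#' @return Tibble: `group, n, mean, sem, rel_mean, rel_sem`.
#' @export
normalize_to_reference <- function(values, labels, reference = "non-blastocyst") {
  keep <- !is.na(values)
  values <- values[keep]; labels <- labels[keep]
  if (!reference %in% labels) {
    stop("reference group '", reference, "' is empty", call. = FALSE)
  }
  groups <- split(values, labels)
  ref_mean <- mean(groups[[reference]])
  if (ref_mean == 0) stop("reference group mean is zero; cannot normalize",
                          call. = FALSE)
  mns <- vapply(groups, mean, numeric(1))
  sems <- vapply(groups, function(g) {
    if (length(g) > 1) stats::sd(g) / sqrt(length(g)) else NA_real_
  }, numeric(1))
  tibble::tibble(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = unname(mns),
    sem = unname(sems),
    rel_mean = unname(mns / ref_mean),
    rel_sem = unname(sems / ref_mean)
  )
}

#' Standard two-group / k-group / contingency comparisons
#'
#' Thin dispatcher over the classical tests used for cohort comparisons:
#' Student's or Welch's t (two-sided), one-way ANOVA, and the chi-square
#' test of homogeneity (no continuity correction by default).
#'
#' @param values Numeric vector (t/anova) or a contingency table/matrix
#'   (chi2).
#' @param labels Group labels parallel to `values` (ignored for chi2).
#' @param test `"t"` (pooled), `"welch_t"`, `"anova"`, or `"chi2"`.
#' @param correct Continuity correction for chi2 (default `FALSE`).
#' @return List: `test`, `statistic`, `p_value`, `df` (named as
#'   appropriate).
#' @export
compare_groups <- function(values, labels = NULL,
                           test = c("welch_t", "t", "anova", "chi2"),
                           correct = FALSE) {
  test <- match.arg(test)
  if (test == "chi2") {
    if (is.null(dim(values))) stop("chi2 requires a contingency table", call. = FALSE)
    res <- stats::chisq.test(values, correct = correct)
    return(list(test = "chi2", statistic = unname(res$statistic),
                p_value = res$p.value, df = unname(res$parameter)))
  }
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- factor(labels[keep])
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("every group needs n >= 2 for variance-based tests; got ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
         call. = FALSE)
  }
  if (test %in% c("t", "welch_t")) {
    if (nlevels(labels) != 2) stop("t-tests require exactly two groups", call. = FALSE)
    res <- stats::t.test(values ~ labels, var.equal = (test == "t"))
    list(test = test, statistic = unname(res$statistic),
         p_value = res$p.value, df = unname(res$parameter))
  } else {
    if (nlevels(labels) < 2) stop("ANOVA requires at least two groups", call. = FALSE)
    fit <- stats::aov(values ~ labels)
    tab <- summary(fit)[[1]]
    list(test = "anova", statistic = tab[["F value"]][1],
         p_value = tab[["Pr(>F)"]][1],
         df = c(df1 = tab[["Df"]][1], df2 = tab[["Df"]][2]))
  }
}

#' Z-score standardization
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation (n-1
#' denominator), the standardization used to put spark amplitude and
#' embryo cell number on a common scale.
#'
#' @param x Numeric vector, `n >= 2`, non-constant.
#' @return Numeric vector of z scores (mean 0, sample SD 1).
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("zscore needs n >= 2", call. = FALSE)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) stop("zscore undefined for constant input (SD = 0)",
                               call. = FALSE)
  (x - mean(x)) / s
}

#' Correlate first-spark amplitude with embryo cell number
#'
#' Spearman rank correlation (average ranks on ties) between paired
#' amplitudes and cell counts, plus an ordinary least-squares line fitted
#' to the z-scored pairs — the standardized display conventionally used
#' for this association. Rank correlation is invariant under the
#' z-transform, so `spearman_r` applies to raw and standardized data
#' alike.
#'
#' @param amplitudes First-spark amplitudes of embryos with cell counts.
#' @param cell_counts Total cell numbers, paired with `amplitudes`.
#' @return List: `spearman_r`, `slope`, `intercept` (on z scores), `n`.
#' @export
correlate_amp_cells <- function(amplitudes, cell_counts) {
  keep <- !is.na(amplitudes) & !is.na(cell_counts)
  amplitudes <- amplitudes[keep]; cell_counts <- cell_counts[keep]
  if (length(amplitudes) != length(cell_counts)) {
    stop("amplitudes and cell_counts must be paired", call. = FALSE)
  }
  if (length(amplitudes) < 3) stop("need at least 3 pairs", call. = FALSE)
  r <- stats::cor(amplitudes, cell_counts, method = "spearman")
  za <- zscore(amplitudes)
  zc <- zscore(cell_counts)
  fit <- stats::lm(zc ~ za)
  list(spearman_r = r,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(amplitudes))
}

#' Percentile-split prospective selection
#'
#' Splits activated eggs at the median (50th percentile) of their
#' first-spark amplitude into a bottom and a top arm, and compares the
#' arms' blastocyst rates. Eggs exactly at the median go to the bottom arm
#' (the conservative direction for a claim that the top arm does better);
#' the tie rule is configurable.
#'
#' @param grouped Tibble from [assign_groups()] (needs `amplitude` and
#'   `outcome`); unactivated/sparkless eggs must be excluded beforehand —
#'   rows with `NA` amplitude raise an error.
#' @param ties `"bottom"` (default) or `"top"`: which arm receives eggs
#'   whose amplitude equals the median.
#' @param probs Split quantile (default 0.5).
#' @return List: `cutoff`, per-arm `n`, blastocyst counts and rates (and
#'   percents), `rate_ratio` (top/bottom), and the 2x2 chi-square
#'   `statistic`/`p_value` (no continuity correction).
#' @export
percentile_select <- function(grouped, ties = c("bottom", "top"), probs = 0.5) {
  ties <- match.arg(ties)
  if (any(is.na(grouped$amplitude))) {
    stop("all eggs entering selection must have a first spark; exclude ",
         "unactivated/sparkless eggs first", call. = FALSE)
  }
  amp <- grouped$amplitude
  cutoff <- unname(stats::quantile(amp, probs))
  bottom <- if (ties == "bottom") amp <= cutoff else amp < cutoff
  n_bot <- sum(bottom); n_top <- sum(!bottom)
  if (n_bot < 2 || n_top < 2) {
    stop("each selection arm needs >= 2 eggs (got bottom=", n_bot,
         ", top=", n_top, ")", call. = FALSE)
  }
  is_bl <- grouped$outcome == "blastocyst"
  bl_bot <- sum(is_bl[bottom]); bl_top <- sum(is_bl[!bottom])
  rate_bot <- bl_bot / n_bot; rate_top <- bl_top / n_top
  tab <- matrix(c(bl_top, n_top - bl_top, bl_bot, n_bot - bl_bot),
                nrow = 2, byrow = TRUE,
                dimnames = list(arm = c("top", "bottom"),
                                outcome = c("blastocyst", "other")))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(cutoff = cutoff,
       n_top = n_top, n_bottom = n_bot,
       blastocysts_top = bl_top, blastocysts_bottom = bl_bot,
       rate_top = rate_top, rate_bottom = rate_bot,
       pct_top = 100 * rate_top, pct_bottom = 100 * rate_bot,
       rate_ratio = if (rate_bot > 0) rate_top / rate_bot else Inf,
       statistic = unname(chi$statistic), p_value = chi$p.value)
}

#' Fertilization rate of an imaged IVF cohort
#'
#' Fraction of imaged eggs with confirmed fertilization (pronucleus
#' formation and subsequent development), also reported as a
#' nearest-integer percent.
#'
#' @param records Egg records with a logical `fertilized` column
#'   (IVF-treatment rows are used; others ignored).
#' @return List: `n`, `n_fertilized`, `fraction`, `percent` (rounded).
#' @export
fertilization_rate <- function(records) {
  ivf <- records[records$treatment == "IVF", , drop = FALSE]
  if (nrow(ivf) == 0) stop("no IVF records in cohort", call. = FALSE)
  n_fert <- sum(ivf$fertilized, na.rm = TRUE)
  frac <- n_fert / nrow(ivf)
  list(n = nrow(ivf), n_fertilized = n_fert,
       fraction = frac, percent = round(100 * frac))
}
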