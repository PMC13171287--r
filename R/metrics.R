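#' ON/OFF firing-rate ratio of a unit
#'
#' For each trial, the unit's firing rate during decoded ON bins is divided
#' by its rate during decoded OFF bins; the per-trial ratios are then
#' averaged. Trials lacking either phase, and trials with a zero OFF rate,
#' are excluded from the average and counted (never mapped to infinity).
#'
#' @param spike_times_by_trial list of per-trial spike time vectors (ms).
#' @param states_by_trial list of per-trial ON/OFF sequences: integer 0/1
#'   vectors (1 = ON) or `state_trajectory` objects with `labels`.
#' @param intervals_by_trial list of per-trial `c(start, end)` windows the
#'   state sequences were decoded on.
#' @param bin_ms state bin width (10 ms).
#' @return List with `ratio` (trial-averaged, `NA` when no valid trial),
#'   `per_trial`, `n_used`, `n_excluded`.
#' @export
on_off_ratio <- function(spike_times_by_trial, states_by_trial,
                         intervals_by_trial, bin_ms = 10) {
  K <- length(spike_times_by_trial)
  stopifnot(length(states_by_trial) == K, length(intervals_by_trial) == K)
  per_trial <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    s <- states_by_trial[[k]]
    if (inherits(s, "state_trajectory")) {
      if (is.null(s$labels)) stop("trajectory lacks ON/OFF labels")
      on <- s$labels == "ON"
    } else on <- as.logical(s)
    iv <- intervals_by_trial[[k]]
    counts <- bin_spikes(spike_times_by_trial[[k]], iv, bin_ms)
    n_bins <- min(length(counts), length(on))
    counts <- counts[seq_len(n_bins)]; on <- on[seq_len(n_bins)]
    if (!any(on) || all(on)) next                       # missing phase
    rate_on <- sum(counts[on]) / (sum(on) * bin_ms)
    rate_off <- sum(counts[!on]) / (sum(!on) * bin_ms)
    if (rate_off == 0) next                             # undefined ratio
    per_trial[k] <- rate_on / rate_off
  }
  used <- !is.na(per_trial)
  list(ratio = if (any(used)) mean(per_trial[used]) else NA_real_,
       per_trial = per_trial, n_used = sum(used), n_excluded = sum(!used))
}

#' Attention modulation index
#'
#' `attMI = (A_RF - A_away) / (A_RF + A_away)` on mean activity in the
#' analysis window; bounded in `[-1, 1]`, positive when attending the
#' receptive field raises firing.
#'
#' @param a_rf,a_away mean activity (e.g. firing rate) under the two pooled
#'   attention conditions; nonnegative.
#' @return Scalar index; `NA` (flagged by warning) when both activities are 0.
#' @export
attention_modulation_index <- function(a_rf, a_away) {
  if (a_rf < 0 || a_away < 0) stop("activities must be nonnegative")
  if (a_rf + a_away == 0) {
    warning("attMI undefined: no activity in either condition")
    return(NA_real_)
  }
  (a_rf - a_away) / (a_rf + a_away)
}

#' Mean firing rate of a unit per trial in a window
#'
#' @param session a `spike_session`.
#' @param unit_id unit.
#' @param window an [analysis_window()].
#' @param condition attention condition or `NULL`.
#' @return Numeric vector of per-trial rates in Hz.
#' @export
unit_trial_rates <- function(session, unit_id, window, condition = NULL) {
  unit <- get_unit(session, unit_id)
  trials <- session_trials(session, condition)
  vapply(seq_len(nrow(trials)), function(i) {
    iv <- resolve_window(window, trials[i, ])
    1000 * sum(unit$spike_times >= iv[1] & unit$spike_times < iv[2]) /
      (iv[2] - iv[1])
  }, numeric(1))
}

#' attMI of a session unit
#'
#' @inheritParams unit_trial_rates
#' @param window analysis window for "neural activity" (default
#'   cue-to-dimming).
#' @return List with `attMI`, `a_rf`, `a_away`.
#' @export
unit_attmi <- function(session, unit_id, window = NULL) {
  if (is.null(window))
    window <- analysis_window("cue_to_dimming", session$monkey_profile)
  a_rf <- mean(unit_trial_rates(session, unit_id, window, "attend_RF"))
  a_away <- mean(unit_trial_rates(session, unit_id, window, "attend_away"))
  list(attMI = attention_modulation_index(a_rf, a_away),
       a_rf = a_rf, a_away = a_away)
}

#' Spike-count noise correlation of a unit pair
#'
#' Pearson correlation of two units' per-trial spike counts, computed by
#' direct sums.
#'
#' @param counts_i,counts_j per-trial counts of the two units (same trials).
#' @return Scalar correlation in `[-1, 1]`; `NA` (warning) on zero variance.
#' @export
noise_correlation <- function(counts_i, counts_j) {
  if (length(counts_i) != length(counts_j))
    stop("count vectors must cover the same trials")
  xc <- counts_i - mean(counts_i); yc <- counts_j - mean(counts_j)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) {
    warning("zero count variance: noise correlation undefined")
    return(NA_real_)
  }
  sum(xc * yc) / sqrt(sxx * syy)
}

#' Noise correlations of all single-unit pairs in a session
#'
#' Counts are taken in the 500-0 ms window before the first dimming,
#' separately per attention condition.
#'
#' @param session a `spike_session`.
#' @param condition attention condition.
#' @param unit_ids units to pair (default: all single units).
#' @param min_trials minimum trial count (10).
#' @return data.frame with `unit_i`, `unit_j`, `condition`, `r`, `n_trials`.
#' @export
session_noise_correlations <- function(session, condition,
                                       unit_ids = NULL, min_trials = 10L) {
  if (is.null(unit_ids))
    unit_ids <- vapply(Filter(function(tr) tr$kind == "single_unit",
                              session$spike_trains), `[[`, character(1),
                       "unit_id")
  w <- analysis_window("pre_dimming", session$monkey_profile)
  trials <- session_trials(session, condition)
  if (nrow(trials) < min_trials)
    stop("need at least ", min_trials, " trials for noise correlations")
  counts <- vapply(unit_ids, function(id) {
    unit <- get_unit(session, id)
    vapply(seq_len(nrow(trials)), function(i) {
      iv <- resolve_window(w, trials[i, ])
      sum(unit$spike_times >= iv[1] & unit$spike_times < iv[2])
    }, numeric(1))
  }, numeric(nrow(trials)))
  pairs <- utils::combn(seq_along(unit_ids), 2)
  data.frame(
    unit_i = unit_ids[pairs[1, ]], unit_j = unit_ids[pairs[2, ]],
    condition = condition,
    r = apply(pairs, 2, function(p)
      suppressWarnings(noise_correlation(counts[, p[1]], counts[, p[2]]))),
    n_trials = nrow(trials), stringsAsFactors = FALSE)
}

#' Rate matching between attention conditions
#'
#' Iteratively removes the lowest-activity trial from whichever condition has
#' the lower mean until the relative difference of the condition means
#' (denominator: their average) falls below `tolerance`, or a floor of
#' `floor_n` trials per condition is reached, in which case the unit is
#' flagged unmatched (and must be excluded from matched analyses, never
#' silently retained).
#'
#' @param rates_a,rates_b per-trial activity (mean rate) in the two
#'   conditions.
#' @param tolerance relative difference target (0.02).
#' @param floor_n minimum trials retained per condition (10).
#' @return List with `keep_a`, `keep_b` (retained indices), `matched` flag,
#'   `rel_diff`, `n_removed`.
#' @export
rate_match <- function(rates_a, rates_b, tolerance = 0.02, floor_n = 10L) {
  keep_a <- seq_along(rates_a); keep_b <- seq_along(rates_b)
  rel_diff <- function() {
    ma <- mean(rates_a[keep_a]); mb <- mean(rates_b[keep_b])
    denom <- (ma + mb) / 2
    if (denom == 0) 0 else abs(ma - mb) / denom
  }
  n_removed <- 0L
  matched <- TRUE
  while (rel_diff() >= tolerance) {
    lower_is_a <- mean(rates_a[keep_a]) < mean(rates_b[keep_b])
    if ((lower_is_a && length(keep_a) <= floor_n) ||
        (!lower_is_a && length(keep_b) <= floor_n)) {
      matched <- FALSE
      break
    }
    if (lower_is_a) keep_a <- keep_a[-which.min(rates_a[keep_a])]
    else keep_b <- keep_b[-which.min(rates_b[keep_b])]
    n_removed <- n_removed + 1L
  }
  list(keep_a = keep_a, keep_b = keep_b, matched = matched,
       rel_diff = rel_diff(), n_removed = n_removed)
}

#' Correlations between coupling and state/attention metrics
#'
#' Pearson correlation (with p-value and r^2) of the Fisher-z coupling
#' against the ON/OFF rate ratio and against attMI, optionally within groups
#' (area, condition).
#'
#' @param units data.frame with columns `Z`, `on_off_ratio`, `attMI` and
#'   optional grouping columns.
#' @param group_by character vector of grouping column names (default none).
#' @return data.frame with one row per group and metric pair: `r`, `p`,
#'   `r_squared`, `n`.
#' @export
metric_correlations <- function(units, group_by = character()) {
  one_group <- function(df, label) {
    rows <- lapply(c(on_off_ratio = "on_off_ratio", attMI = "attMI"),
                   function(col) {
      ok <- stats::complete.cases(df$Z, df[[col]])
      if (sum(ok) < 3) stop("need at least 3 units with defined metrics")
      if (stats::sd(df$Z[ok]) == 0 || stats::sd(df[[col]][ok]) == 0)
        stop("degenerate variance in metric correlation")
      ct <- stats::cor.test(df$Z[ok], df[[col]][ok])
      data.frame(group = label, metric = col, r = unname(ct$estimate),
                 p = ct$p.value, r_squared = unname(ct$estimate)^2,
                 n = sum(ok), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  if (!length(group_by)) return(one_group(units, "all"))
  key <- interaction(units[group_by], drop = TRUE)
  do.call(rbind, lapply(levels(key), function(lv)
    one_group(units[key == lv, , drop = FALSE], lv)))
}

#' Regression of pair noise correlation on the two units' coupling
#'
#' Least-squares fit `r_ij ~ Z_i + Z_j + Z_i:Z_j` (or the symmetrised design
#' `r_ij ~ (Z_i + Z_j) + Z_i * Z_j`, invariant under swapping the pair).
#'
#' @param pairs data.frame with columns `r`, `Z_i`, `Z_j`.
#' @param symmetric use the swap-invariant design.
#' @return List with `coefficients`, `r_squared`, `fit` (the `lm` object).
#' @export
paircoupling_regression <- function(pairs, symmetric = FALSE) {
  if (nrow(pairs) < 10) stop("need at least 10 pairs")
  df <- data.frame(r = pairs$r, zi = pairs$Z_i, zj = pairs$Z_j)
  fit <- if (symmetric)
    stats::lm(r ~ I(zi + zj) + I(zi * zj), data = df)
  else
    stats::lm(r ~ zi + zj + zi:zj, data = df)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  list(coefficients = stats::coef(fit),
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Nonparametric comparison of metric distributions
#'
#' Thin wrapper over the standard tests: Wilcoxon signed-rank (paired),
#' Wilcoxon rank-sum (unpaired two groups), or Kruskal-Wallis with
#' Bonferroni-corrected pairwise rank-sum post hocs (three or more groups).
#'
#' @param values numeric vector (two-sample case: first sample, or all values
#'   when `groups` given).
#' @param values_b second sample (two-sample case).
#' @param groups factor of group labels (k-sample case).
#' @param paired use the signed-rank test (two-sample only).
#' @return List with `method`, `p_value` and, for k samples, `post_hoc`
#'   (Bonferroni-adjusted pairwise p matrix).
#' @export
compare_conditions <- function(values, values_b = NULL, groups = NULL,
                               paired = FALSE) {
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    kw <- stats::kruskal.test(values, groups)
    ph <- suppressWarnings(stats::pairwise.wilcox.test(
      values, groups, p.adjust.method = "bonferroni", exact = FALSE))
    return(list(method = "kruskal_wallis", p_value = kw$p.value,
                post_hoc = ph$p.value))
  }
  if (is.null(values_b)) stop("supply values_b or groups")
  if (paired && all(values == values_b))
    return(list(method = "wilcoxon_signed_rank", p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(values, values_b,
                                            paired = paired, exact = FALSE))
  list(method = if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum",
       p_value = wt$p.value)
}
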