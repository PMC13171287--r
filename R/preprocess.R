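#' Bin spike times over a half-open interval
#'
#' @param spike_times numeric spike times (ms) or a [spike_train()].
#' @param interval `c(start, end)` in ms; spikes in `[start, end)` are kept.
#' @param bin_ms bin width; the interval is covered by
#'   `ceiling((end - start) / bin_ms)` half-open bins.
#' @return Integer vector of per-bin counts; the sum equals the number of
#'   spikes inside the interval.
#' @export
bin_spikes <- function(spike_times, interval, bin_ms = 1) {
  if (inherits(spike_times, "spike_train")) spike_times <- spike_times$spike_times
  if (bin_ms <= 0) stop("bin_ms must be positive")
  if (length(interval) != 2L || !(interval[2] > interval[1]))
    stop("interval must be c(start, end) with end > start")
  n_bins <- ceiling((interval[2] - interval[1]) / bin_ms)
  inside <- spike_times >= interval[1] & spike_times < interval[2]
  idx <- floor((spike_times[inside] - interval[1]) / bin_ms) + 1
  idx[idx > n_bins] <- n_bins  # guard against floating-point edge
  tabulate(idx, nbins = n_bins)
}

# unit-area Gaussian kernel truncated at +-4 sigma
gaussian_kernel <- function(half_width_ms, bin_ms = 1) {
  sigma <- half_width_ms / bin_ms
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(seq(-r, r), 0, sigma)
  k / sum(k)
}

#' Smooth a binned signal with a Gaussian kernel
#'
#' The kernel "half-width" is interpreted as the Gaussian standard deviation
#' sigma (ms), truncated at +-4 sigma and renormalised to unit area; a
#' constant signal therefore maps to the same constant away from the edges
#' and total mass is conserved up to edge effects (zero padding).
#'
#' @param x numeric signal at `bin_ms` resolution.
#' @param half_width_ms kernel sigma in ms (> 0).
#' @param bin_ms bin width of `x`.
#' @param mean_subtract subtract the post-smoothing mean.
#' @return An object of class `smoothed_signal`: numeric values with
#'   attributes `kernel_half_width_ms` and `mean_subtracted`.
#' @export
gaussian_smooth <- function(x, half_width_ms = 12, bin_ms = 1,
                            mean_subtract = FALSE) {
  if (half_width_ms <= 0) stop("half_width_ms must be positive")
  k <- gaussian_kernel(half_width_ms, bin_ms)
  r <- (length(k) - 1L) / 2L
  if (length(x) < length(k))
    stop(sprintf("signal (%d bins) shorter than kernel support (%d bins)",
                 length(x), length(k)))
  full <- stats::convolve(as.numeric(x), rev(k), type = "open")
  y <- full[(r + 1L):(r + length(x))]
  if (mean_subtract) y <- y - mean(y)
  structure(y, kernel_half_width_ms = half_width_ms,
            mean_subtracted = mean_subtract, class = "smoothed_signal")
}

# channels kept in a population rate for a unit on target_channel:
# own channel always excluded; with min_separation 300 um on a 150 um probe
# the two adjacent contacts drop out as well (leakage control).
included_channels <- function(n_channels, target_channel, spacing_um,
                              min_separation_um) {
  ch <- seq_len(n_channels) - 1L
  dist <- abs(ch - target_channel) * spacing_um
  ch[ch != target_channel & dist >= min_separation_um]
}

#' Per-channel 1 ms count matrix for one interval
#'
#' Accumulates the single- and multi-unit spike trains of each contact into a
#' channels x bins count matrix, optionally leaving out one single unit
#' (so its own spikes never enter the population rate).
#'
#' @param session a `spike_session`.
#' @param interval `c(start, end)` ms.
#' @param bin_ms bin width (1 ms for population-coupling analyses).
#' @param exclude_unit unit id to leave out, or `NULL`.
#' @return Integer matrix, `n_channels` rows.
#' @export
channel_count_matrix <- function(session, interval, bin_ms = 1,
                                 exclude_unit = NULL) {
  n_bins <- ceiling((interval[2] - interval[1]) / bin_ms)
  m <- matrix(0L, nrow = session$n_channels, ncol = n_bins)
  for (tr in session$spike_trains) {
    if (!is.null(exclude_unit) && tr$unit_id == exclude_unit) next
    m[tr$channel_index + 1L, ] <- m[tr$channel_index + 1L, ] +
      bin_spikes(tr$spike_times, interval, bin_ms)
  }
  m
}

#' Population rate seen by one unit
#'
#' Sums the 1 ms spike counts of all included contacts -- every contact at
#' distance `>= min_contact_separation_um` from the unit's contact, the
#' unit's own contact always excluded -- then smooths with a unit-area
#' Gaussian kernel and subtracts the mean.
#'
#' @param session a `spike_session`.
#' @param unit_id the target single unit.
#' @param interval `c(start, end)` ms.
#' @param min_contact_separation_um 150 (default: exclude own contact only)
#'   or 300 (leakage control: also drop adjacent contacts).
#' @param kernel_half_width_ms population smoothing sigma (12 ms).
#' @param smooth,mean_subtract set `FALSE` to obtain the raw summed counts.
#' @return A `smoothed_signal` (or raw numeric when `smooth = FALSE`) with
#'   attribute `included_channels` (0-based).
#' @export
population_rate <- function(session, unit_id, interval,
                            min_contact_separation_um = 150,
                            kernel_half_width_ms = 12,
                            smooth = TRUE, mean_subtract = TRUE) {
  unit <- get_unit(session, unit_id)
  keep <- included_channels(session$n_channels, unit$channel_index,
                            session$probe_spacing_um,
                            min_contact_separation_um)
  if (!length(keep)) stop("no channels remain after the separation filter")
  counts <- channel_count_matrix(session, interval, 1, exclude_unit = unit_id)
  pooled <- colSums(counts[keep + 1L, , drop = FALSE])
  out <- if (smooth)
    gaussian_smooth(pooled, kernel_half_width_ms, 1, mean_subtract = mean_subtract)
  else pooled
  attr(out, "included_channels") <- keep
  out
}

#' Trial energy of a signal segment
#'
#' The energy is the plain sum of the signal values between two sample
#' indices (inclusive); applied per trial to histograms or MUA envelopes it
#' indexes recording stability.
#'
#' @param values numeric vector.
#' @param i,j first and last index (inclusive); defaults cover the vector.
#' @return Scalar sum.
#' @export
energy <- function(values, i = 1L, j = length(values)) {
  if (j < i || i < 1L || j > length(values)) stop("empty or out-of-range interval")
  sum(values[i:j])
}

#' Select the largest stable run of trials
#'
#' Replaces the visual stability inspection with a reproducible rule: per
#' channel, a trial is stable when its energy lies within
#' `tolerance_sd` robust standard deviations (1.4826 * MAD) of the channel's
#' median energy; the returned range is the longest contiguous run of trials
#' stable on every channel simultaneously.
#'
#' @param energy_matrix trials x channels matrix of per-trial energies.
#' @param tolerance_sd band half-width in robust SD units (default 3).
#' @return List with `start`, `end` (trial indices, inclusive) and the
#'   logical `stable` matrix.
#' @export
select_stable_window <- function(energy_matrix, tolerance_sd = 3) {
  E <- as.matrix(energy_matrix)
  if (nrow(E) < 1L) stop("need at least one trial")
  stable <- matrix(TRUE, nrow(E), ncol(E))
  for (ch in seq_len(ncol(E))) {
    med <- stats::median(E[, ch])
    rsd <- stats::mad(E[, ch])
    stable[, ch] <- abs(E[, ch] - med) <= tolerance_sd * rsd
  }
  ok <- rowSums(stable) == ncol(E)
  runs <- rle(ok)
  if (!any(runs$values)) return(list(start = NA_integer_, end = NA_integer_,
                                     stable = stable))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  list(start = starts[best], end = ends[best], stable = stable)
}

#' Unit inclusion filter
#'
#' A unit is included when its mean firing rate reaches 5 Hz in at least one
#' analysis window of interest and the session holds at least 10 trials per
#' attention condition.
#'
#' @param session a `spike_session`.
#' @param unit_id unit to test.
#' @param windows list of [analysis_window()] objects (default: spontaneous
#'   and cue-to-dimming for the session's monkey profile).
#' @param min_rate_hz,min_trials thresholds (5 Hz, 10 trials).
#' @return List with `included`, `reasons` (character), `max_rate_hz`,
#'   `n_trials` per condition.
#' @export
inclusion_filter <- function(session, unit_id, windows = NULL,
                             min_rate_hz = 5, min_trials = 10L) {
  if (is.null(windows))
    windows <- list(analysis_window("spontaneous", session$monkey_profile),
                    analysis_window("cue_to_dimming", session$monkey_profile))
  unit <- get_unit(session, unit_id)
  rates <- vapply(windows, function(w) {
    tot_spikes <- 0; tot_ms <- 0
    for (i in seq_len(nrow(session$trials))) {
      iv <- resolve_window(w, session$trials[i, ])
      tot_spikes <- tot_spikes + sum(unit$spike_times >= iv[1] &
                                     unit$spike_times < iv[2])
      tot_ms <- tot_ms + (iv[2] - iv[1])
    }
    1000 * tot_spikes / tot_ms
  }, numeric(1))
  n_trials <- c(attend_RF = sum(session$trials$condition == "attend_RF"),
                attend_away = sum(session$trials$condition == "attend_away"))
  reasons <- character()
  if (max(rates) < min_rate_hz) reasons <- c(reasons, "rate")
  if (any(n_trials < min_trials)) reasons <- c(reasons, "trials")
  list(included = length(reasons) == 0L, reasons = reasons,
       max_rate_hz = max(rates), n_trials = n_trials)
}

#' Stimulus-response filter
#'
#' Keeps only units with a significant stimulus response: per-trial spike
#' counts in the baseline window are compared with the onset-response window
#' by a paired two-sided Wilcoxon signed-rank test at `alpha`.
#'
#' @param session a `spike_session`.
#' @param unit_id unit to test.
#' @param alpha significance level (0.05).
#' @return List with `included`, `p_value`, `n_trials`.
#' @export
response_filter <- function(session, unit_id, alpha = 0.05) {
  unit <- get_unit(session, unit_id)
  wb <- analysis_window("baseline", session$monkey_profile)
  wo <- analysis_window("onset_response", session$monkey_profile)
  n <- nrow(session$trials)
  if (n < 10L) stop("response filter needs at least 10 trials")
  count_in <- function(w, trial) {
    iv <- resolve_window(w, trial)
    sum(unit$spike_times >= iv[1] & unit$spike_times < iv[2])
  }
  baseline <- onset <- numeric(n)
  for (i in seq_len(n)) {
    baseline[i] <- count_in(wb, session$trials[i, ])
    onset[i] <- count_in(wo, session$trials[i, ])
  }
  d <- onset - baseline
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(onset, baseline, paired = TRUE,
                                        exact = FALSE)$p.value)
  list(included = is.finite(p) && p < alpha, p_value = p, n_trials = n)
}
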