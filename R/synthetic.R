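#' Configuration for the synthetic session generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a latent two-state (ON/OFF) first-order Markov process at 10 ms
#' resolution common to all probe contacts, per-channel Poisson multi-unit
#' counts with state-dependent rates, and single units spanning a
#' soloist-chorister continuum through the ON/OFF rate ratio `state_ratio`.
#' Attention (`attend_RF`) lengthens ON periods (larger `p_stay_on`) and
#' scales unit rates by `1 + attention_gain`.
#'
#' Defaults describe one laminar penetration: 16 contacts at 150 um spacing,
#' ~110 Hz multi-unit activity per contact (20 Hz OFF / 200 Hz ON, i.e. 0.2
#' and 2.0 counts per 10 ms bin), per-bin self-transition probability 0.98 in
#' both states (geometric dwell, mean 500 ms), attention raising `p_stay_on`
#' to 0.995, and 16 single units (base 15 Hz) cycling through state ratios
#' 1, 2, 4 and 8.
#'
#' @param n_channels number of probe contacts.
#' @param bin_ms latent-state bin width in ms (10 ms).
#' @param p_stay_off,p_stay_on named numeric vectors (`attend_RF`,
#'   `attend_away`) of per-bin self-transition probabilities in (0, 1).
#' @param channel_rates_off,channel_rates_on per-channel multi-unit rates in
#'   Hz during OFF and ON states; ON must dominate OFF elementwise.
#' @param units data.frame with columns `channel_index` (0-based),
#'   `base_rate_hz`, `state_ratio` (rho >= 1) and `attention_gain`.
#' @param n_trials named integer vector of trials per condition.
#' @param monkey_profile `"M1"` or `"M2"` (sets the task epoch delays).
#' @param area area label applied to all contacts (`"V1"` or `"V4"`).
#' @param intertrial_gap_ms,post_dimming_ms session layout paddings.
#' @param seed integer seed; the whole session is reproducible from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_channels = 16L,
                             bin_ms = 10,
                             p_stay_off = c(attend_RF = 0.98, attend_away = 0.98),
                             p_stay_on = c(attend_RF = 0.995, attend_away = 0.98),
                             channel_rates_off = rep(20, n_channels),
                             channel_rates_on = rep(200, n_channels),
                             units = default_unit_table(n_channels),
                             n_trials = c(attend_RF = 20L, attend_away = 20L),
                             monkey_profile = "M1",
                             area = "V1",
                             intertrial_gap_ms = 200,
                             post_dimming_ms = 200,
                             seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels), bin_ms = bin_ms,
              p_stay_off = p_stay_off, p_stay_on = p_stay_on,
              channel_rates_off = channel_rates_off,
              channel_rates_on = channel_rates_on,
              units = units, n_trials = n_trials,
              monkey_profile = monkey_profile, area = area,
              intertrial_gap_ms = intertrial_gap_ms,
              post_dimming_ms = post_dimming_ms, seed = as.integer(seed))
  conds <- c("attend_RF", "attend_away")
  for (p in c("p_stay_off", "p_stay_on")) {
    v <- cfg[[p]]
    if (!all(conds %in% names(v))) stop(p, " must name both conditions")
    if (any(v <= 0 | v >= 1)) stop(p, " probabilities must lie in (0, 1)")
  }
  if (any(cfg$channel_rates_off < 0) || any(cfg$channel_rates_on < 0))
    stop("channel rates must be nonnegative")
  if (length(cfg$channel_rates_off) != cfg$n_channels ||
      length(cfg$channel_rates_on) != cfg$n_channels)
    stop("channel rate vectors must have one entry per channel")
  if (any(cfg$channel_rates_on < cfg$channel_rates_off))
    stop("ON rates must be >= OFF rates on every channel")
  u <- cfg$units
  if (!all(c("channel_index", "base_rate_hz", "state_ratio", "attention_gain")
           %in% names(u)))
    stop("units table is missing required columns")
  if (any(u$state_ratio < 1)) stop("state_ratio must be >= 1")
  if (any(u$base_rate_hz < 0)) stop("base_rate_hz must be nonnegative")
  if (any(u$channel_index < 0 | u$channel_index >= cfg$n_channels))
    stop("unit channel_index outside probe")
  if (!all(conds %in% names(cfg$n_trials)) || any(cfg$n_trials < 1))
    stop("n_trials must name both conditions with at least one trial each")
  class(cfg) <- "generator_config"
  cfg
}

#' Default soloist-to-chorister unit table
#' @param n_channels probe size; one unit per contact, ratios cycling 1,2,4,8.
#' @return data.frame usable as the `units` field of [generator_config()].
#' @export
default_unit_table <- function(n_channels = 16L) {
  data.frame(channel_index = seq_len(n_channels) - 1L,
             base_rate_hz = 15,
             state_ratio = rep(c(1, 2, 4, 8), length.out = n_channels),
             attention_gain = 0.1)
}

#' Sample a latent ON/OFF state sequence
#'
#' First-order two-state Markov chain: the transition out of a state depends
#' only on the current state, so dwell times are geometric with mean
#' `1 / (1 - p_stay)` bins.
#'
#' @param p_stay_off,p_stay_on self-transition probabilities in (0, 1] (1 is
#'   allowed and makes the state absorbing).
#' @param pi0 length-2 initial distribution `(P(OFF), P(ON))`; `NULL` uses the
#'   stationary distribution.
#' @param n_bins sequence length (> 0).
#' @return Integer vector of 0 (OFF) / 1 (ON). Uses the global RNG.
#' @export
sample_state_sequence <- function(p_stay_off, p_stay_on, pi0 = NULL, n_bins) {
  if (n_bins <= 0) stop("n_bins must be positive")
  stopifnot(p_stay_off > 0, p_stay_off <= 1, p_stay_on > 0, p_stay_on <= 1)
  if (is.null(pi0)) pi0 <- stationary_on_off(p_stay_off, p_stay_on)
  if (abs(sum(pi0) - 1) > 1e-9 || any(pi0 < 0)) stop("pi0 must be a distribution")
  s <- integer(n_bins)
  u <- stats::runif(n_bins)
  s[1L] <- as.integer(u[1L] < pi0[2L])
  if (n_bins > 1L) {
    p_stay <- c(p_stay_off, p_stay_on)
    for (t in 2:n_bins) {
      stay <- u[t] < p_stay[s[t - 1L] + 1L]
      s[t] <- if (stay) s[t - 1L] else 1L - s[t - 1L]
    }
  }
  s
}

stationary_on_off <- function(p_stay_off, p_stay_on) {
  a <- 1 - p_stay_off  # OFF -> ON
  b <- 1 - p_stay_on   # ON -> OFF
  if (a + b == 0) return(c(0.5, 0.5))
  c(b, a) / (a + b)
}

#' Poisson channel counts conditioned on a state sequence
#'
#' @param states 0/1 state sequence.
#' @param rate_off_hz,rate_on_hz channel firing rates in Hz.
#' @param bin_ms bin width; the Poisson mean in a bin is
#'   `rate_hz * bin_ms / 1000`.
#' @return Integer vector of per-bin counts.
#' @export
generate_channel_counts <- function(states, rate_off_hz, rate_on_hz, bin_ms = 10) {
  if (rate_off_hz < 0 || rate_on_hz < 0) stop("rates must be nonnegative")
  lam <- c(rate_off_hz, rate_on_hz) * bin_ms / 1000
  stats::rpois(length(states), lam[states + 1L])
}

# ms-resolution spike times from per-bin counts: spikes are placed uniformly
# within their 10 ms bin (thinning a piecewise-constant rate).
spikes_from_counts <- function(counts, bin_ms, t0 = 0) {
  total <- sum(counts)
  if (total == 0L) return(numeric())
  bins <- rep(seq_along(counts) - 1L, counts)
  sort(t0 + bins * bin_ms + stats::runif(total) * bin_ms)
}

#' Unit ON/OFF rates implied by a base rate and state ratio
#'
#' `r_off = 2 * base / (1 + rho)` and `r_on = rho * r_off`, so that the
#' state-averaged rate at 50% ON occupancy equals the base rate; `rho = 1`
#' gives a state-independent (soloist) unit.
#'
#' @param base_rate_hz state-averaged target rate.
#' @param state_ratio rho >= 1.
#' @return Named vector `c(r_off, r_on)` in Hz.
#' @export
unit_state_rates <- function(base_rate_hz, state_ratio) {
  if (state_ratio < 1) stop("state_ratio must be >= 1")
  r_off <- 2 * base_rate_hz / (1 + state_ratio)
  c(r_off = r_off, r_on = state_ratio * r_off)
}

#' Generate single-unit spikes coupled to a latent state sequence
#'
#' Inhomogeneous Poisson spikes at ms resolution following the state-dependent
#' rate of [unit_state_rates()]; under `attend_RF` both rates are scaled by
#' `1 + attention_gain`.
#'
#' @param states 0/1 latent sequence.
#' @param base_rate_hz,state_ratio see [unit_state_rates()].
#' @param condition `"attend_RF"` or `"attend_away"`.
#' @param attention_gain multiplicative gain g >= 0 applied under `attend_RF`.
#' @param bin_ms latent bin width.
#' @param t0 time of the first bin edge (ms).
#' @return Numeric vector of spike times in ms.
#' @export
generate_unit_spikes <- function(states, base_rate_hz, state_ratio,
                                 condition = "attend_away", attention_gain = 0,
                                 bin_ms = 10, t0 = 0) {
  r <- unit_state_rates(base_rate_hz, state_ratio)
  if (condition == "attend_RF") r <- r * (1 + attention_gain)
  lam <- r * bin_ms / 1000
  counts <- stats::rpois(length(states), lam[states + 1L])
  spikes_from_counts(counts, bin_ms, t0)
}

#' Generate a full synthetic session with ground truth
#'
#' Lays out interleaved trials of both attention conditions with task epochs
#' drawn from the monkey-specific delay distributions (fixation onset, a fixed
#' stimulus-onset delay, a uniform cue delay and a uniform first-dimming
#' delay), samples one latent ON/OFF sequence per trial, and emits per-contact
#' multi-unit Poisson spike trains plus the configured single units. Single
#' units are never added to the multi-unit train of their host contact, so
#' excluding the host channel from the population rate removes the unit's own
#' spikes exactly.
#'
#' @param config a [generator_config()].
#' @return List with `session` (a [spike_session()]) and `truth` (per-trial
#'   latent sequences, true emission/transition parameters, unit table).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  delays <- if (config$monkey_profile == "M1")
    list(stim = 614, cue = c(618, 1131), dim = c(1162, 2133))
  else
    list(stim = 424, cue = c(618, 948), dim = c(1162, 1822))

  conds <- rep(c("attend_RF", "attend_away"),
               times = c(config$n_trials[["attend_RF"]],
                         config$n_trials[["attend_away"]]))
  # interleave deterministically so conditions are spread across the session
  conds <- conds[order(rep(seq_len(max(config$n_trials)), 2)[seq_along(conds)])]

  n_units <- nrow(config$units)
  mua_spikes <- vector("list", config$n_channels)
  unit_spikes <- vector("list", n_units)
  for (j in seq_len(config$n_channels)) mua_spikes[[j]] <- list()
  for (i in seq_len(n_units)) unit_spikes[[i]] <- list()

  t_cursor <- 0
  trials <- vector("list", length(conds))
  truth_states <- vector("list", length(conds))
  for (k in seq_along(conds)) {
    cond <- conds[k]
    t_start <- t_cursor
    fixation <- t_start + 200
    cue <- fixation + delays$stim + stats::runif(1, delays$cue[1], delays$cue[2])
    dimming <- cue + stats::runif(1, delays$dim[1], delays$dim[2])
    t_end <- dimming + config$post_dimming_ms
    n_bins <- ceiling((t_end - t_start) / config$bin_ms)
    states <- sample_state_sequence(config$p_stay_off[[cond]],
                                    config$p_stay_on[[cond]],
                                    pi0 = NULL, n_bins = n_bins)
    for (j in seq_len(config$n_channels)) {
      counts <- generate_channel_counts(states, config$channel_rates_off[j],
                                        config$channel_rates_on[j],
                                        config$bin_ms)
      mua_spikes[[j]][[k]] <- spikes_from_counts(counts, config$bin_ms, t_start)
    }
    for (i in seq_len(n_units)) {
      u <- config$units[i, ]
      unit_spikes[[i]][[k]] <- generate_unit_spikes(
        states, u$base_rate_hz, u$state_ratio, cond, u$attention_gain,
        config$bin_ms, t_start)
    }
    trials[[k]] <- data.frame(trial_id = sprintf("t%03d", k),
                              fixation_onset_ms = fixation,
                              cue_onset_ms = cue, first_dimming_ms = dimming,
                              condition = cond, stringsAsFactors = FALSE)
    truth_states[[k]] <- list(trial_id = sprintf("t%03d", k),
                              t_start_ms = t_start, states = states)
    t_cursor <- t_end + config$intertrial_gap_ms
  }
  trials <- do.call(rbind, trials)

  trains <- c(
    lapply(seq_len(config$n_channels), function(j)
      spike_train(sprintf("mua_ch%02d", j - 1L), j - 1L, "multi_unit",
                  unlist(mua_spikes[[j]], use.names = FALSE))),
    lapply(seq_len(n_units), function(i)
      spike_train(sprintf("su%02d", i), config$units$channel_index[i],
                  "single_unit", unlist(unit_spikes[[i]], use.names = FALSE))))

  session <- spike_session(
    sprintf("synthetic_seed%d", config$seed), config$monkey_profile, trains,
    trial_epochs(trials$trial_id, trials$fixation_onset_ms,
                 trials$cue_onset_ms, trials$first_dimming_ms,
                 trials$condition),
    n_channels = config$n_channels,
    areas = rep(config$area, config$n_channels))

  lambda <- rbind(OFF = config$channel_rates_off * config$bin_ms / 1000,
                  ON = config$channel_rates_on * config$bin_ms / 1000)
  truth <- list(
    states = truth_states,
    lambda_counts_per_bin = lambda,
    p_stay_off = config$p_stay_off, p_stay_on = config$p_stay_on,
    pi0 = list(
      attend_RF = stationary_on_off(config$p_stay_off[["attend_RF"]],
                                    config$p_stay_on[["attend_RF"]]),
      attend_away = stationary_on_off(config$p_stay_off[["attend_away"]],
                                      config$p_stay_on[["attend_away"]])),
    units = config$units, bin_ms = config$bin_ms)
  list(session = session, truth = truth)
}

#' Evaluate the parametric visual-response latency model
#'
#' `y(t) = d * exp(mu*alpha + 0.5*sigma^2*alpha^2 - alpha*t) *
#'  G(t, mu + sigma^2*alpha, sigma) + c * G(t, mu, sigma)` where `G` is the
#' cumulative Gaussian: the sum of an exponentially dissipating transient and
#' a sustained response.
#'
#' @param t time grid (ms).
#' @param mu,sigma Gaussian onset mean and SD (ms); `sigma > 0`.
#' @param alpha inverse dissipation time constant (1/ms); `alpha > 0`.
#' @param c_sustained,d_transient amplitudes of the two components.
#' @return Numeric vector `y(t)`.
#' @export
latency_model <- function(t, mu, sigma, alpha, c_sustained, d_transient) {
  if (sigma <= 0) stop("sigma must be positive")
  if (alpha <= 0) stop("alpha must be positive")
  d_transient * exp(mu * alpha + 0.5 * sigma^2 * alpha^2 - alpha * t) *
    stats::pnorm(t, mu + sigma^2 * alpha, sigma) +
    c_sustained * stats::pnorm(t, mu, sigma)
}

#' Generate a continuous test profile
#'
#' `kind = "latency_model"` evaluates [latency_model()] on a time grid with
#' optional Gaussian noise (uses the global RNG); `kind = "csd_test"` returns
#' a deterministic voltage-by-depth profile for exercising the CSD operator.
#'
#' @param kind `"latency_model"` or `"csd_test"`.
#' @param params named list. For `latency_model`: `t` (grid), `mu`, `sigma`,
#'   `alpha`, `c`, `d`, optional `noise_sd`. For `csd_test`: `depths_um` and
#'   `profile` in `"linear"`, `"quadratic"` or `"gaussian_sink"` (plus
#'   `sink_depth_um`, `sink_width_um` for the latter).
#' @return Numeric vector (signal over time, or voltage over depth).
#' @export
generate_continuous_profile <- function(kind = c("latency_model", "csd_test"),
                                        params) {
  kind <- match.arg(kind)
  if (kind == "latency_model") {
    need <- c("t", "mu", "sigma", "alpha", "c", "d")
    if (!all(need %in% names(params)))
      stop("latency_model needs params: ", paste(need, collapse = ", "))
    y <- latency_model(params$t, params$mu, params$sigma, params$alpha,
                       params$c, params$d)
    if (!is.null(params$noise_sd) && params$noise_sd > 0)
      y <- y + stats::rnorm(length(y), 0, params$noise_sd)
    y
  } else {
    if (!all(c("depths_um", "profile") %in% names(params)))
      stop("csd_test needs params: depths_um, profile")
    x <- params$depths_um
    switch(params$profile,
      linear = 2 + 0.001 * x,
      quadratic = x^2,
      gaussian_sink = -exp(-(x - params$sink_depth_um)^2 /
                             (2 * params$sink_width_um^2)),
      stop("unknown csd_test profile '", params$profile, "'"))
  }
}
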