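# Session fixtures built in code.

# small generator configuration for fast end-to-end tests
tiny_config <- function(seed = 1, n_trials = c(attend_RF = 3L, attend_away = 3L),
                        ...) {
  generator_config(
    n_channels = 4L,
    channel_rates_off = rep(20, 4), channel_rates_on = rep(200, 4),
    units = data.frame(channel_index = 0:3, base_rate_hz = 15,
                       state_ratio = c(1, 2, 4, 8), attention_gain = 0.1),
    n_trials = n_trials, seed = seed, ...)
}

# hand-built session: trials at regular spacing, unit spike times supplied
# per unit as a function(trial_row) -> spike times, or as a full vector
manual_session <- function(unit_specs, n_rf = 12L, n_away = 12L,
                           monkey_profile = "M1", n_channels = 4L) {
  n <- n_rf + n_away
  fixation <- 10000 * seq_len(n) + 200
  cue <- fixation + 1000
  dimming <- cue + 1500
  cond <- rep(c("attend_RF", "attend_away"), times = c(n_rf, n_away))
  trials <- trial_epochs(sprintf("t%02d", seq_len(n)), fixation, cue,
                         dimming, cond)
  trains <- lapply(seq_along(unit_specs), function(i) {
    spec <- unit_specs[[i]]
    times <- if (is.function(spec$times)) {
      sort(unlist(lapply(seq_len(n), function(k) spec$times(trials[k, ]))))
    } else spec$times
    spike_train(spec$unit_id, spec$channel_index,
                spec$kind %||% "single_unit", times)
  })
  spike_session("manual", monkey_profile, trains, trials,
                n_channels = n_channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
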