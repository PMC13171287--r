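test_that("bin_spikes counts over half-open bins and conserves spikes", {
  counts <- bin_spikes(c(1.2, 1.7), c(0, 3), 1)
  expect_equal(counts, c(0L, 2L, 0L))
  expect_equal(bin_spikes(numeric(), c(0, 5), 1), rep(0L, 5))
  # spike exactly at the interval end is excluded (half-open)
  expect_equal(sum(bin_spikes(c(0, 5), c(0, 5), 1)), 1L)

  set.seed(4)
  times <- sort(runif(1000, 0, 1000))
  expect_equal(sum(bin_spikes(times, c(0, 1000), 1)), 1000L)
  expect_error(bin_spikes(1, c(5, 5), 1), "end > start")
})

test_that("gaussian_smooth is unit-area, constant-preserving and matches a direct oracle", {
  x <- rep(3, 200)
  y <- gaussian_smooth(x, 12)
  interior <- 60:140
  expect_equal(as.numeric(y)[interior], rep(3, length(interior)),
               tolerance = 1e-9)

  imp <- c(rep(0, 100), 1, rep(0, 100))
  y <- as.numeric(gaussian_smooth(imp, 12))
  expect_lt(abs(sum(y) - 1), 1e-6)

  # two impulses 50 ms apart resolve into two peaks at the impulse bins
  x2 <- rep(0, 300); x2[c(120, 170)] <- 1
  y2 <- as.numeric(gaussian_smooth(x2, 12))
  peaks <- which(diff(sign(diff(y2))) == -2) + 1L
  peaks <- peaks[y2[peaks] > 0.1 * max(y2)]   # ignore FFT-noise ripples
  expect_equal(peaks, c(120, 170))

  # direct convolution oracle on a random vector
  set.seed(5)
  x3 <- rpois(400, 2)
  sigma <- 7
  r <- ceiling(4 * sigma)
  k <- dnorm(-r:r, 0, sigma); k <- k / sum(k)
  oracle <- vapply(seq_along(x3), function(i) {
    s <- 0
    for (j in -r:r) {
      src <- i - j
      if (src >= 1 && src <= length(x3)) s <- s + x3[src] * k[j + r + 1]
    }
    s
  }, numeric(1))
  expect_equal(as.numeric(gaussian_smooth(x3, sigma)), oracle,
               tolerance = 1e-10)

  expect_error(gaussian_smooth(rep(1, 10), 12), "shorter than kernel")
})

test_that("population_rate excludes the right contacts and matches a sum oracle", {
  # channels with constant 1, 2, 3 spikes per ms
  mk_times <- function(per_ms, t_end = 50)
    sort(rep(seq(0.5, t_end - 0.5, by = 1), per_ms))
  trains <- list(
    spike_train("su_target", 0, "single_unit", mk_times(1)),
    spike_train("m0", 0, "multi_unit", mk_times(1)),
    spike_train("m1", 1, "multi_unit", mk_times(2)),
    spike_train("m2", 2, "multi_unit", mk_times(3)))
  trials <- trial_epochs("a", 1, 5, 30, "attend_RF")
  trials <- rbind(trials, trial_epochs("b", 1.5, 5.5, 30.5, "attend_away"))
  ses <- spike_session("s", "M1", trains, trials, n_channels = 3)
  raw <- population_rate(ses, "su_target", c(0, 50), smooth = FALSE)
  expect_equal(as.numeric(raw), rep(5, 50))    # channel 0 excluded: 2 + 3
  expect_equal(attr(raw, "included_channels"), c(1L, 2L))

  # leakage control on a 16-contact probe: unit on contact 5 loses 4, 5, 6
  gen <- generate_session(generator_config(
    seed = 3, n_trials = c(attend_RF = 2L, attend_away = 2L)))
  pr <- population_rate(gen$session, "su06", c(0, 2000),
                        min_contact_separation_um = 300, smooth = FALSE)
  expect_false(any(c(4, 5, 6) %in% attr(pr, "included_channels")))
  expect_equal(length(attr(pr, "included_channels")), 13L)

  # brute-force per-bin oracle and the 150/300 additivity identity
  iv <- c(0, 1500)
  raw150 <- population_rate(gen$session, "su06", iv, 150, smooth = FALSE)
  raw300 <- population_rate(gen$session, "su06", iv, 300, smooth = FALSE)
  oracle <- rep(0, 1500)
  for (tr in gen$session$spike_trains) {
    if (tr$channel_index == 5) next
    tt <- tr$spike_times[tr$spike_times >= iv[1] & tr$spike_times < iv[2]]
    for (s in tt) oracle[floor(s) + 1] <- oracle[floor(s) + 1] + 1
  }
  expect_equal(as.numeric(raw150), oracle)
  adjacent <- rep(0, 1500)
  for (tr in gen$session$spike_trains) {
    if (!(tr$channel_index %in% c(4, 6)) || tr$kind != "multi_unit") next
    tt <- tr$spike_times[tr$spike_times >= iv[1] & tr$spike_times < iv[2]]
    for (s in tt) adjacent[floor(s) + 1] <- adjacent[floor(s) + 1] + 1
  }
  # single units on contacts 4/6 also belong to the adjacent contribution
  for (tr in gen$session$spike_trains) {
    if (!(tr$channel_index %in% c(4, 6)) || tr$kind != "single_unit") next
    tt <- tr$spike_times[tr$spike_times >= iv[1] & tr$spike_times < iv[2]]
    for (s in tt) adjacent[floor(s) + 1] <- adjacent[floor(s) + 1] + 1
  }
  expect_equal(as.numeric(raw150), as.numeric(raw300) + adjacent)
})

test_that("energy is the inclusive sum", {
  expect_equal(energy(c(1, 2, 3)), 6)
  expect_equal(energy(rep(0, 10)), 0)
  set.seed(6)
  v <- runif(50)
  i <- 7; j <- 31
  oracle <- 0
  for (k in i:j) oracle <- oracle + v[k]
  expect_equal(energy(v, i, j), oracle)
  expect_error(energy(v, 10, 5), "interval")
})

test_that("select_stable_window matches the brute-force oracle", {
  # all equal -> full range
  E <- matrix(5, nrow = 20, ncol = 3)
  w <- select_stable_window(E)
  expect_equal(c(w$start, w$end), c(1L, 20L))

  # step change with unequal halves, tight tolerance -> longer half
  E <- matrix(c(rep(10, 14), rep(20, 6)), ncol = 1)
  w <- select_stable_window(E, tolerance_sd = 0.5)
  expect_equal(c(w$start, w$end), oracle_stable_window(E, 0.5))
  expect_equal(c(w$start, w$end), c(1L, 14L))

  # one channel drifting linearly ends the range early
  set.seed(8)
  E <- cbind(rnorm(30, 100, 1), c(rnorm(18, 100, 1), 100 + 8 * (1:12)))
  w <- select_stable_window(E, tolerance_sd = 3)
  expect_equal(c(w$start, w$end), oracle_stable_window(E, 3))
  expect_lte(w$end, 20L)

  # random matrices against the oracle
  for (seed in 1:5) {
    set.seed(seed)
    E <- matrix(rnorm(60, 10), ncol = 3)
    w <- select_stable_window(E, 1)
    expect_equal(c(w$start, w$end), oracle_stable_window(E, 1))
  }
})

test_that("inclusion_filter applies the 5 Hz / 10 trials rules", {
  # deterministic rates: k spikes per 100 ms everywhere -> 10k Hz
  rate_spec <- function(hz) list(
    unit_id = paste0("u", hz), channel_index = 0,
    times = function(tr) seq(tr$fixation_onset_ms - 500,
                             tr$first_dimming_ms + 500, by = 1000 / hz))
  ses <- manual_session(list(rate_spec(4), rate_spec(6)))
  f4 <- inclusion_filter(ses, "u4")
  expect_false(f4$included)
  expect_equal(f4$reasons, "rate")
  f6 <- inclusion_filter(ses, "u6")
  expect_true(f6$included)
  expect_equal(f6$reasons, character())

  ses9 <- manual_session(list(rate_spec(6)), n_rf = 9L, n_away = 12L)
  f <- inclusion_filter(ses9, "u6")
  expect_false(f$included)
  expect_equal(f$reasons, "trials")
})

test_that("response_filter detects onset responses and controls type I error", {
  # onset window gains 10 spikes per trial over baseline
  resp <- list(unit_id = "resp", channel_index = 0,
               times = function(tr) c(tr$cue_onset_ms - 200 + 1:2 * 10,
                                      tr$cue_onset_ms + 60 + 1:12 * 15))
  flat <- list(unit_id = "flat", channel_index = 0,
               times = function(tr) c(tr$cue_onset_ms - 200 + 1:3 * 10,
                                      tr$cue_onset_ms + 60 + 1:3 * 10))
  ses <- manual_session(list(resp, flat), n_rf = 10L, n_away = 10L)
  expect_true(response_filter(ses, "resp")$included)
  expect_false(response_filter(ses, "flat")$included)

  # null simulation: baseline and onset exchangeable -> ~5% included
  set.seed(10)
  n_units <- 400
  null_unit <- function(i) list(
    unit_id = paste0("null", i), channel_index = 0,
    times = function(tr) sort(c(
      runif(rpois(1, 3), tr$cue_onset_ms - 250, tr$cue_onset_ms),
      runif(rpois(1, 3), tr$cue_onset_ms + 50, tr$cue_onset_ms + 300))))
  ses <- manual_session(lapply(seq_len(n_units), null_unit),
                        n_rf = 10L, n_away = 10L)
  hits <- sum(vapply(seq_len(n_units), function(i)
    response_filter(ses, paste0("null", i))$included, logical(1)))
  expect_gt(hits / n_units, 0.01)
  expect_lt(hits / n_units, 0.10)
})
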