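test_that("cross_correlation matches the direct-sum oracle at every lag", {
  set.seed(20)
  for (rep in 1:3) {
    x <- rnorm(200); y <- 0.4 * x + rnorm(200)
    x <- x - mean(x); y <- y - mean(y)
    norm <- 37
    cc <- cross_correlation(x, y, max_lag = 30, spike_norm = norm)
    expect_equal(cc$values, oracle_xcorr(x, y, 30, norm), tolerance = 1e-12)
  }

  # autocorrelation of an impulse train peaks at lag 0
  x <- rep(0, 100); x[c(10, 40, 77)] <- 1
  x <- x - mean(x)
  cc <- cross_correlation(x, x, max_lag = 20, spike_norm = 3)
  expect_equal(cc$lags[which.max(cc$values)], 0L)

  # silent unit: flagged undefined
  cc <- cross_correlation(rep(0, 50), rnorm(50), max_lag = 5, spike_norm = 0)
  expect_true(cc$undefined)
  expect_true(all(is.na(cc$values)))
  expect_error(cross_correlation(1:5, 1:6, 2, 1), "same length")
})

test_that("coupling_at_zero and normalized_coupling follow the formulas", {
  x <- c(1, -1, 1, -1)
  y <- c(1, 1, -1, -1)            # orthogonal to x, both zero-mean
  expect_equal(coupling_at_zero(x, y, 4), 0)
  expect_equal(coupling_at_zero(x, x, 2), sum(x^2) / 2)
  set.seed(21)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(coupling_at_zero(a, b, 10),
               oracle_xcorr(a, b, 0, 10), tolerance = 1e-12)
  expect_warning(expect_true(is.na(coupling_at_zero(a, b, 0))), "silent")

  expect_equal(normalized_coupling(a, 2 * a), 1)
  expect_equal(normalized_coupling(a, -a), -1)
  expect_equal(normalized_coupling(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0)
  expect_equal(normalized_coupling(a, b), oracle_pearson(a, b),
               tolerance = 1e-12)
  expect_warning(expect_true(is.na(normalized_coupling(rep(1, 5), 1:5))),
                 "zero variance")
})

test_that("fisher_z is atanh with domain checks", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_error(fisher_z(1), "undefined")
  expect_true(is.na(fisher_z(NA_real_)))
})

test_that("C_norm is invariant to affine gain of the population rate", {
  set.seed(22)
  x <- rnorm(500)
  y <- 0.3 * x + rnorm(500)
  base <- normalized_coupling(x, y)
  expect_equal(normalized_coupling(x, 5 * y), base, tolerance = 1e-12)
  expect_equal(normalized_coupling(x, 5 * y + 7), base, tolerance = 1e-12)
})

test_that("circular shifts of the unit train form a null around zero", {
  set.seed(23)
  n <- 20000
  states <- sample_state_sequence(0.98, 0.98, c(0.5, 0.5), n / 10)
  lam_pop <- rep(c(0.3, 3), c(1, 0))  # per-ms population rate by state
  state_ms <- rep(states, each = 10)
  pop <- rpois(n, ifelse(state_ms == 1, 3, 0.3))
  unit <- rpois(n, ifelse(state_ms == 1, 0.16, 0.02))
  sm <- function(v) as.numeric(gaussian_smooth(v, 12, mean_subtract = TRUE))
  shifts <- round(seq(2000, n - 2000, length.out = 25))
  null_c <- vapply(shifts, function(s)
    normalized_coupling(sm(c(unit[-(1:s)], unit[1:s])), sm(pop)),
    numeric(1))
  expect_lt(abs(mean(null_c)), 2 * sd(null_c) / sqrt(length(null_c)))
})

test_that("coupling rises along the soloist-chorister continuum", {
  # direct-signal simulation: shared two-state population, units with
  # increasing state ratio; median C_norm nondecreasing in rho,
  # soloists near zero, choristers above soloists in >= 95% of replicates
  sm <- function(v) as.numeric(gaussian_smooth(v, 12, mean_subtract = TRUE))
  run_pair <- function(seed, n_ms = 30000) {
    set.seed(seed)
    state_ms <- rep(sample_state_sequence(0.98, 0.98, c(0.5, 0.5), n_ms / 10),
                    each = 10)
    pop <- rpois(n_ms, ifelse(state_ms == 1, 3, 0.3))
    y <- sm(pop)
    vapply(c(1, 2, 4, 8), function(rho) {
      r <- unit_state_rates(15, rho) / 1000
      unit <- rpois(n_ms, ifelse(state_ms == 1, r["r_on"], r["r_off"]))
      normalized_coupling(sm(unit), y)
    }, numeric(1))
  }
  reps <- vapply(1:50, run_pair, numeric(4))
  med <- apply(reps, 1, median)
  expect_true(all(diff(med) >= 0))
  expect_gte(mean(reps[4, ] > reps[1, ]), 0.95)

  # soloist at 60 s of data: |C_norm| < 0.1
  set.seed(77)
  state_ms <- rep(sample_state_sequence(0.98, 0.98, c(0.5, 0.5), 6000),
                  each = 10)
  pop <- rpois(60000, ifelse(state_ms == 1, 3, 0.3))
  unit <- rpois(60000, 0.015)
  expect_lt(abs(normalized_coupling(sm(unit), sm(pop))), 0.1)
})

test_that("session-level coupling flags degenerate units and self-coupling", {
  gen <- generate_session(tiny_config(seed = 30,
    n_trials = c(attend_RF = 4L, attend_away = 4L)))
  ses <- gen$session
  # add a silent unit
  ses$spike_trains <- c(ses$spike_trains,
                        list(spike_train("silent", 0, "single_unit",
                                         numeric())))
  res <- session_population_coupling(ses, c("su01", "silent"),
                                     condition = "attend_away")
  expect_true(is.na(res$silent$C_norm))
  expect_equal(res$silent$spike_norm, 0)
  expect_false(is.na(res$su01$C_norm))

  # a unit duplicating the whole population proxy couples near 1
  w <- analysis_window("cue_to_dimming", "M1")
  trials <- session_trials(ses, "attend_away")
  iv <- resolve_window(w, trials[1, ])
  pop_raw <- population_rate(ses, "su01", iv, smooth = FALSE)
  # identical signals under a common kernel couple at exactly 1
  y_same <- as.numeric(gaussian_smooth(pop_raw, 12, mean_subtract = TRUE))
  expect_equal(normalized_coupling(y_same, y_same), 1)
  # the default asymmetric kernels (12 vs 12/sqrt(2)) stay near 1
  x <- as.numeric(gaussian_smooth(pop_raw, 12 / sqrt(2), mean_subtract = TRUE))
  expect_gt(normalized_coupling(x, y_same), 0.9)
})

test_that("leakage mode propagates to results", {
  gen <- generate_session(generator_config(
    seed = 31, n_trials = c(attend_RF = 2L, attend_away = 2L)))
  r150 <- unit_population_coupling(gen$session, "su06",
                                   condition = "attend_away")
  r300 <- unit_population_coupling(gen$session, "su06",
    condition = "attend_away",
    options = coupling_options(leakage_min_separation_um = 300))
  expect_equal(r150$leakage_mode, 150)
  expect_equal(r300$leakage_mode, 300)
  expect_false(isTRUE(all.equal(r150$C0, r300$C0)))
})
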