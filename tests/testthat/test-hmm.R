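test_that("emission log-probabilities match Poisson closed forms", {
  expect_equal(emission_logprob(0, 2), -2)
  expect_equal(emission_logprob(0, 0), 0)
  expect_equal(emission_logprob(3, 3), log(3^3 * exp(-3) / 6))
  expect_equal(emission_logprob(1, 0), -Inf)
  expect_error(emission_logprob(-1, 2), "nonnegative")
  expect_error(emission_logprob(1.5, 2), "integers")
})

test_that("forward_backward matches path enumeration and closed forms", {
  # S = 1: posterior identically 1, loglik is the iid Poisson sum
  m1 <- poisson_hmm(matrix(c(1.3, 0.4), 1, 2), matrix(1, 1, 1), 1)
  counts <- rbind(c(2, 0, 1), c(1, 1, 0))
  fb <- forward_backward(counts, m1)
  expect_equal(as.numeric(fb$gamma), rep(1, 3))
  expect_equal(fb$loglik, sum(dpois(counts, c(1.3, 0.4), log = TRUE)))

  # T = 1: posterior proportional to pi0 * emission
  m2 <- poisson_hmm(rbind(c(0.5, 0.2), c(2, 3)),
                    rbind(c(0.9, 0.1), c(0.2, 0.8)), c(0.3, 0.7))
  obs1 <- matrix(c(2L, 1L), 2, 1)
  fb1 <- forward_backward(obs1, m2)
  w <- c(0.3, 0.7) * c(exp(sum(dpois(c(2, 1), c(0.5, 0.2), log = TRUE))),
                       exp(sum(dpois(c(2, 1), c(2, 3), log = TRUE))))
  expect_equal(as.numeric(fb1$gamma), w / sum(w), tolerance = 1e-12)

  # random small instances against exhaustive enumeration
  set.seed(40)
  for (i in 1:5) {
    lambda <- matrix(runif(4, 0.2, 3), 2, 2)
    P <- rbind(rdir <- c(a <- runif(1, 0.5, 0.95), 1 - a),
               c(b <- runif(1, 0.05, 0.5), 1 - b))
    pi0 <- c(p <- runif(1, 0.2, 0.8), 1 - p)
    model <- poisson_hmm(lambda, P, pi0)
    counts <- matrix(rpois(10, 1.2), 2, 5)
    fb <- forward_backward(counts, model)
    expect_equal(fb$loglik, oracle_hmm_loglik(counts, lambda, P, pi0),
                 tolerance = 1e-9)
    expect_true(all(abs(colSums(fb$gamma) - 1) < 1e-12))
  }
})

test_that("loglik is invariant under phase relabelling", {
  set.seed(41)
  lambda <- rbind(c(0.2, 0.3), c(2, 1.5))
  P <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  pi0 <- c(0.4, 0.6)
  counts <- matrix(rpois(40, 1), 2, 20)
  ll <- forward_backward(counts, poisson_hmm(lambda, P, pi0))$loglik
  perm <- c(2, 1)
  ll_perm <- forward_backward(counts, poisson_hmm(
    lambda[perm, ], P[perm, perm], pi0[perm]))$loglik
  expect_equal(ll, ll_perm, tolerance = 1e-10)
})

test_that("em_fit closed forms: S = 1 and all-zero data", {
  set.seed(42)
  counts <- matrix(rpois(300, c(0.5, 2, 1)), 3, 100)
  fit <- em_fit(counts, 1)
  expect_equal(as.numeric(fit$lambda), rowMeans(counts))
  expect_true(fit$converged)

  zeros <- matrix(0L, 2, 50)
  fit0 <- em_fit(zeros, 1)
  expect_equal(as.numeric(fit0$lambda), c(0, 0))
  expect_equal(fit0$log_likelihood, 0)
})

test_that("EM log-likelihood is monotone and recovers two-state parameters", {
  set.seed(43)
  trials <- lapply(1:30, function(k) {
    st <- sample_state_sequence(0.98, 0.98, c(0.5, 0.5), 200)
    do.call(rbind, lapply(1:8, function(j)
      generate_channel_counts(st, 20, 200, 10)))
  })
  fit <- em_fit(trials, 2)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))

  ord <- order(rowMeans(fit$lambda))    # phase alignment: OFF first
  lam <- fit$lambda[ord, ]
  expect_true(all(abs(lam[1, ] - 0.2) / 0.2 < 0.1))
  expect_true(all(abs(lam[2, ] - 2.0) / 2.0 < 0.1))
  P <- fit$P[ord, ord]
  expect_lt(abs(P[1, 1] - 0.98), 0.01)
  expect_lt(abs(P[2, 2] - 0.98), 0.01)
})

test_that("parameter bias shrinks as data grows", {
  est_err <- function(n_trials, seed) {
    set.seed(seed)
    trials <- lapply(seq_len(n_trials), function(k) {
      st <- sample_state_sequence(0.95, 0.95, c(0.5, 0.5), 150)
      do.call(rbind, lapply(1:4, function(j)
        generate_channel_counts(st, 30, 150, 10)))
    })
    fit <- em_fit(trials, 2)
    lam <- fit$lambda[order(rowMeans(fit$lambda)), ]
    mean(abs(c(lam[1, ] - 0.3, lam[2, ] - 1.5)))
  }
  errs_small <- vapply(1:3, function(s) est_err(4, s), numeric(1))
  errs_large <- vapply(1:3, function(s) est_err(40, 100 + s), numeric(1))
  expect_lt(mean(errs_large), mean(errs_small))
})

test_that("multi_restart_fit is deterministic under seed and best-of-n", {
  set.seed(44)
  trials <- lapply(1:6, function(k) {
    st <- sample_state_sequence(0.95, 0.95, c(0.5, 0.5), 100)
    rbind(generate_channel_counts(st, 20, 200, 10),
          generate_channel_counts(st, 20, 200, 10))
  })
  set.seed(7); fit_a <- multi_restart_fit(trials, 2, n_restarts = 5)
  set.seed(7); fit_b <- multi_restart_fit(trials, 2, n_restarts = 5)
  expect_identical(fit_a$lambda, fit_b$lambda)
  expect_identical(fit_a$P, fit_b$P)
  lls <- attr(fit_a, "restart_logliks")
  expect_true(all(fit_a$log_likelihood >= lls - 1e-9))

  # S = 1 restarts collapse to the closed form every time
  set.seed(8)
  fit1 <- multi_restart_fit(trials, 1, n_restarts = 10)
  expect_equal(as.numeric(fit1$lambda),
               rowMeans(do.call(cbind, trials)))
})

test_that("viterbi matches exhaustive argmax and labels ON/OFF", {
  model <- poisson_hmm(matrix(c(1, 5), 2, 1),
                       rbind(c(0.9, 0.1), c(0.1, 0.9)), c(0.5, 0.5))
  obs <- matrix(c(0L, 0L, 6L, 7L), 1, 4)
  v <- viterbi(obs, model)
  oracle <- oracle_viterbi(obs, model$lambda, model$P, model$pi0)
  expect_equal(v$states, oracle$path)
  expect_equal(v$labels, c("OFF", "OFF", "ON", "ON"))

  set.seed(45)
  for (i in 1:5) {
    lambda <- matrix(runif(4, 0.2, 4), 2, 2)
    model <- poisson_hmm(lambda, rbind(c(0.8, 0.2), c(0.3, 0.7)),
                         c(0.5, 0.5))
    counts <- matrix(rpois(12, 1.5), 2, 6)
    v <- viterbi(counts, model)
    oracle <- oracle_viterbi(counts, lambda, model$P, model$pi0)
    expect_equal(v$states, oracle$path)
    # decoded path beats random alternative paths
    set.seed(100 + i)
    path_lp <- function(path) {
      lp <- log(model$pi0[path[1]]) +
        sum(dpois(counts[, 1], lambda[path[1], ], log = TRUE))
      for (t in 2:6) lp <- lp + log(model$P[path[t - 1], path[t]]) +
        sum(dpois(counts[, t], lambda[path[t], ], log = TRUE))
      lp
    }
    rand <- replicate(100, path_lp(sample(1:2, 6, replace = TRUE)))
    expect_true(all(path_lp(v$states) >= rand))
  }

  # S = 1 decodes a constant path
  m1 <- poisson_hmm(matrix(1.5, 1, 2), matrix(1, 1, 1), 1)
  expect_true(all(viterbi(rbind(0:3, 1:4), m1)$states == 1L))

  expect_error(label_on_off(poisson_hmm(matrix(1, 3, 1), diag(3), rep(1/3, 3))),
               "two-phase")
  expect_error(label_on_off(poisson_hmm(rbind(c(1, 2), c(2, 1)),
                                        diag(2), c(0.5, 0.5))),
               "tie")
  swapped <- label_on_off(poisson_hmm(rbind(c(2, 2), c(0.2, 0.2)),
                                      diag(2), c(0.5, 0.5)))
  expect_equal(swapped, c("ON", "OFF"))
})

test_that("cv_error anchors at S = 1 and matches a manual error oracle", {
  set.seed(46)
  trials <- lapply(1:8, function(k) matrix(rpois(2 * 60, c(1, 2)), 2, 60))
  set.seed(5)
  rep <- cv_error(trials, S_values = 1, folds = 4, n_restarts = 2)
  expect_equal(unname(rep$cv_norm["1"]), 1)

  # the raw one-phase error is sum over held-out trials of (n - train mean)^2
  set.seed(5)
  ord <- sample.int(8)
  fold_of <- integer(8); fold_of[ord] <- rep_len(1:4, 8)
  train_mean <- rowMeans(do.call(cbind, trials[fold_of != 1]))
  oracle <- vapply(1:2, function(j)
    sum(vapply(trials[fold_of == 1], function(m)
      sum((m[j, ] - train_mean[j])^2), numeric(1))), numeric(1))
  expect_equal(unname(rep$raw[1, , 1]), oracle, tolerance = 1e-10)
})

test_that("select_num_phases applies the 10% elbow rule", {
  set.seed(47)
  two_state <- lapply(1:16, function(k) {
    st <- sample_state_sequence(0.97, 0.97, c(0.5, 0.5), 150)
    do.call(rbind, lapply(1:6, function(j)
      generate_channel_counts(st, 20, 200, 10)))
  })
  set.seed(1)
  rep2 <- select_num_phases(two_state, S_range = 1:2, folds = 4,
                            n_restarts = 5)
  expect_lte(unname(rep2$cv_norm["2"]), 0.9)
  expect_equal(rep2$selected, 2)
  expect_true(rep2$pass)

  one_state <- lapply(1:16, function(k) matrix(rpois(6 * 150, 1.1), 6, 150))
  set.seed(2)
  rep1 <- select_num_phases(one_state, S_range = 1:2, folds = 4,
                            n_restarts = 5)
  expect_lt(unname(rep1$reductions["2"]), 0.10)
  expect_false(rep1$pass)
  expect_equal(rep1$selected, 1)

  rep_triv <- select_num_phases(two_state[1:4], S_range = 1, folds = 4,
                                n_restarts = 2)
  expect_equal(rep_triv$selected, 1)
  expect_true(is.na(rep_triv$pass))
})
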