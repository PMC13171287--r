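#' Construct a multichannel Poisson hidden Markov model
#'
#' Spike counts in 10 ms bins on each channel are modelled as Poisson with a
#' channel- and phase-specific mean (`lambda[s, j]`, the emission matrix),
#' conditionally independent across channels given a latent phase sequence
#' shared by all channels, which evolves as a first-order Markov chain with
#' transition matrix `P` and initial distribution `pi0`.
#'
#' @param lambda S x J emission matrix of mean counts per bin (rows = phases).
#' @param P S x S transition matrix; rows must sum to 1.
#' @param pi0 initial phase distribution.
#' @param log_likelihood,n_iterations,converged,loglik_trace fit diagnostics.
#' @param bin_ms bin width the counts were taken at (10 ms).
#' @return An object of class `poisson_hmm`.
#' @export
poisson_hmm <- function(lambda, P, pi0, log_likelihood = NA_real_,
                        n_iterations = NA_integer_, converged = NA,
                        loglik_trace = numeric(), bin_ms = 10) {
  lambda <- as.matrix(lambda)
  P <- as.matrix(P)
  S <- nrow(lambda)
  if (any(lambda < 0)) stop("emission means must be nonnegative")
  if (nrow(P) != S || ncol(P) != S) stop("P must be S x S")
  if (any(abs(rowSums(P) - 1) > 1e-12)) stop("rows of P must sum to 1")
  if (length(pi0) != S || abs(sum(pi0) - 1) > 1e-12 || any(pi0 < 0))
    stop("pi0 must be a distribution over the S phases")
  structure(list(S = S, lambda = lambda, P = P, pi0 = as.numeric(pi0),
                 log_likelihood = log_likelihood,
                 n_iterations = n_iterations, converged = converged,
                 loglik_trace = loglik_trace, bin_ms = bin_ms),
            class = "poisson_hmm")
}

#' Poisson emission log-probability
#'
#' `log P(n | s) = n log(lambda) - lambda - log(n!)`; the degenerate
#' `lambda = 0` gives probability 1 at `n = 0` and 0 elsewhere.
#'
#' @param n nonnegative integer count(s).
#' @param lambda mean count(s) per bin, `>= 0`.
#' @return Log-probabilities (vectorised).
#' @export
emission_logprob <- function(n, lambda) {
  if (any(n < 0)) stop("counts must be nonnegative")
  if (any(n != floor(n))) stop("counts must be integers")
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  stats::dpois(n, lambda, log = TRUE)
}

# S x T matrix of per-bin log emission probabilities with channels summed
# out; a tiny floor keeps lambda = 0 finite (effectively -Inf for n > 0).
emission_logmatrix <- function(counts, lambda) {
  counts <- rbind(counts)
  loglam <- log(pmax(lambda, 1e-300))
  term <- loglam %*% counts                       # S x T
  sweep(term, 1, rowSums(lambda)) -
    matrix(colSums(lgamma(counts + 1)), nrow(lambda), ncol(counts),
           byrow = TRUE)
}

as_trial_list <- function(counts) {
  if (is.list(counts)) lapply(counts, function(m) rbind(m)) else list(rbind(counts))
}

#' Forward-backward pass
#'
#' Scaled forward-backward recursion giving per-bin phase posteriors,
#' expected transition counts and the exact data log-likelihood for one
#' counts matrix under a fitted model.
#'
#' @param counts J x T matrix of per-channel spike counts (a vector is
#'   treated as one channel).
#' @param model a [poisson_hmm()].
#' @return List with `gamma` (S x T posteriors, columns sum to 1), `xi`
#'   (S x S expected transition counts) and `loglik`.
#' @export
forward_backward <- function(counts, model) {
  counts <- rbind(counts)
  logB <- emission_logmatrix(counts, model$lambda)
  .fb_core(logB, model$P, model$pi0)
}

default_em_init <- function(channel_means, S) {
  lambda <- outer(2 * seq_len(S) / (S + 1), channel_means)
  P <- matrix(if (S > 1) 0.1 / (S - 1) else 0, S, S)
  diag(P) <- if (S > 1) 0.9 else 1
  list(lambda = lambda, P = P, pi0 = rep(1 / S, S))
}

#' Fit a Poisson HMM by expectation maximisation
#'
#' Baum-Welch EM over a set of trials (independent sequences). Iterations
#' stop when the relative log-likelihood change `|new - old| / |old|` falls
#' below `tol_loglik` and the largest absolute elementwise change of the
#' emission and transition matrices falls below `tol_params`, or after
#' `max_iter` iterations. The log-likelihood is nondecreasing across
#' iterations (EM guarantee; recorded in `loglik_trace`). Emission means are
#' floored at `lambda_floor` as a numerical guard against `log(0)` on
#' channels silent in a phase.
#'
#' @param counts J x T matrix or list of such matrices (one per trial).
#' @param S number of latent phases (`S = 1` is the closed-form Poisson ML).
#' @param init optional list with `lambda`, `P`, `pi0`; default is a
#'   deterministic spread around the channel means.
#' @param tol_loglik,tol_params,max_iter termination rule (1e-3, 1e-5, 500).
#' @param lambda_floor numerical floor on emission means.
#' @return A fitted [poisson_hmm()].
#' @export
em_fit <- function(counts, S, init = NULL, tol_loglik = 1e-3,
                   tol_params = 1e-5, max_iter = 500, lambda_floor = 1e-8) {
  if (S < 1) stop("S must be at least 1")
  trials <- as_trial_list(counts)
  if (!length(trials) || !ncol(trials[[1L]])) stop("empty data")
  J <- nrow(trials[[1L]])
  all_counts <- do.call(cbind, trials)
  channel_means <- rowMeans(all_counts)

  if (S == 1L) {
    lambda <- matrix(channel_means, 1, J)
    ll <- sum(emission_logmatrix(all_counts, lambda))
    return(poisson_hmm(lambda, matrix(1, 1, 1), 1, log_likelihood = ll,
                       n_iterations = 0L, converged = TRUE,
                       loglik_trace = ll))
  }

  if (is.null(init)) init <- default_em_init(channel_means, S)
  lambda <- as.matrix(init$lambda); P <- as.matrix(init$P)
  pi0 <- as.numeric(init$pi0)
  ends <- as.integer(cumsum(vapply(trials, ncol, integer(1))))
  tall <- t(all_counts)                       # T_total x J, for the M-step
  # the lgamma(n+1) term is constant in the parameters: S x T, hoisted
  lgconst <- matrix(colSums(lgamma(all_counts + 1)), S, ncol(all_counts),
                    byrow = TRUE)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  ll_prev <- NA_real_
  emission_all <- function(lam)
    (log(pmax(lam, 1e-300)) %*% all_counts - rowSums(lam)) - lgconst
  while (iter < max_iter) {
    iter <- iter + 1L
    fb <- .fb_batch(emission_all(lambda), ends, P, pi0)
    g <- fb$gamma
    ll <- fb$loglik
    trace <- c(trace, ll)
    lambda_new <- pmax((g %*% tall) / rowSums(g), lambda_floor)
    rs <- rowSums(fb$xi)
    P_new <- P
    for (s in seq_len(S))
      P_new[s, ] <- if (rs[s] > 0) fb$xi[s, ] / rs[s] else rep(1 / S, S)
    pi0_new <- fb$pi_acc / length(trials)
    pi0_new <- pi0_new / sum(pi0_new)
    dpar <- max(abs(lambda_new - lambda), abs(P_new - P))
    lambda <- lambda_new; P <- P_new; pi0 <- pi0_new
    if (!is.na(ll_prev)) {
      rel <- abs(ll - ll_prev) / abs(ll_prev)
      if (rel < tol_loglik && dpar < tol_params) { converged <- TRUE; break }
    }
    ll_prev <- ll
  }
  final_ll <- .fb_batch(emission_all(lambda), ends, P, pi0)$loglik
  poisson_hmm(lambda, P, pi0, log_likelihood = final_ll,
              n_iterations = iter, converged = converged,
              loglik_trace = c(trace, final_ll))
}

rdirichlet1 <- function(S) {
  g <- stats::rgamma(S, 1)
  g / sum(g)
}

#' Best-of-n EM fit with random restarts
#'
#' Runs [em_fit()] `n_restarts` times with random initialisations -- flat
#' Dirichlet draws for `pi0` and each row of `P`, uniform draws on
#' `(0, 2 * channel mean)` for each emission entry -- and keeps the model
#' with the highest training log-likelihood. Seed the global RNG for a
#' reproducible selection.
#'
#' @inheritParams em_fit
#' @param n_restarts number of random restarts (10).
#' @return The best fitted [poisson_hmm()]; attribute `restart_logliks`
#'   records every restart's final log-likelihood.
#' @export
multi_restart_fit <- function(counts, S, n_restarts = 10, tol_loglik = 1e-3,
                              tol_params = 1e-5, max_iter = 500) {
  trials <- as_trial_list(counts)
  channel_means <- rowMeans(do.call(cbind, trials))
  best <- NULL
  lls <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- if (S == 1L) NULL else list(
      lambda = matrix(stats::runif(S * length(channel_means), 0,
                                   rep(2 * channel_means, each = S)),
                      S, length(channel_means)),
      P = t(vapply(seq_len(S), function(i) rdirichlet1(S), numeric(S))),
      pi0 = rdirichlet1(S))
    fit <- em_fit(trials, S, init = init, tol_loglik = tol_loglik,
                  tol_params = tol_params, max_iter = max_iter)
    lls[r] <- fit$log_likelihood
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  attr(best, "restart_logliks") <- lls
  best
}

#' Label the phases of a two-phase model as ON/OFF
#'
#' The phase with the larger mean emission across channels is ON.
#'
#' @param model a fitted two-phase [poisson_hmm()].
#' @return Character vector of length 2 (`"OFF"`/`"ON"`) in phase order.
#' @export
label_on_off <- function(model) {
  if (model$S != 2L) stop("ON/OFF labelling requires a two-phase model")
  m <- rowMeans(model$lambda)
  if (m[1L] == m[2L])
    stop("phases have identical mean emissions; resolve the tie manually")
  if (m[1L] > m[2L]) c("ON", "OFF") else c("OFF", "ON")
}

#' Viterbi decoding of the most likely phase path
#'
#' Log-space Viterbi recursion; ties are broken toward the lower phase
#' index for determinism.
#'
#' @param counts J x T count matrix for one trial.
#' @param model a fitted [poisson_hmm()].
#' @return An object of class `state_trajectory`: list with `states`
#'   (1-based phase indices), `labels` (`"ON"`/`"OFF"` per bin for two-phase
#'   models with distinguishable phases, else `NULL`) and `bin_ms`.
#' @export
viterbi <- function(counts, model) {
  counts <- rbind(counts)
  logB <- emission_logmatrix(counts, model$lambda)
  states <- .viterbi_core(logB, log(pmax(model$P, 1e-300)),
                          log(pmax(model$pi0, 1e-300)))
  labels <- NULL
  if (model$S == 2L && rowMeans(model$lambda)[1L] != rowMeans(model$lambda)[2L])
    labels <- label_on_off(model)[states]
  structure(list(states = states, labels = labels, bin_ms = model$bin_ms),
            class = "state_trajectory")
}

# decode a trial using every channel except j (leave-one-channel-out)
viterbi_loco <- function(counts, model, drop_channel) {
  sub <- poisson_hmm(model$lambda[, -drop_channel, drop = FALSE], model$P,
                     model$pi0, bin_ms = model$bin_ms)
  viterbi(counts[-drop_channel, , drop = FALSE], sub)$states
}

#' Leave-one-channel-out cross-validation error
#'
#' Fourfold cross-validation of the phase count: trials are shuffled once and
#' split into `folds` parts; each fold's model is fitted on the remaining
#' trials (best of `n_restarts` random restarts). On every held-out trial and
#' every channel `j`, the phase path is decoded by Viterbi from all channels
#' except `j`, and the squared error `sum_t (n_tj - lambda[s_t, j])^2` is
#' accumulated. Per-channel errors are normalised to the one-phase model's
#' error, averaged over channels, then over folds.
#'
#' @param trials list of J x T count matrices (>= `folds` trials).
#' @param S_values phase counts to evaluate (must include 1, the anchor).
#' @param folds number of folds (4).
#' @param n_restarts EM restarts per fold and phase count (10).
#' @param tol_loglik,tol_params,max_iter EM termination settings.
#' @return An object of class `cv_report`: `S_values`, `cv_norm` (named,
#'   `cv_norm["1"] == 1`), `per_fold` (S x folds channel-averaged normalised
#'   errors), `raw` (S x channels x folds array).
#' @export
cv_error <- function(trials, S_values = 1:2, folds = 4, n_restarts = 10,
                     tol_loglik = 1e-3, tol_params = 1e-5, max_iter = 500) {
  trials <- as_trial_list(trials)
  K <- length(trials)
  if (K < folds) stop("need at least as many trials as folds")
  if (!1 %in% S_values) S_values <- sort(c(1, S_values))
  S_values <- sort(unique(S_values))
  J <- nrow(trials[[1L]])
  ord <- sample.int(K)
  fold_of <- integer(K)
  fold_of[ord] <- rep_len(seq_len(folds), K)

  raw <- array(0, dim = c(length(S_values), J, folds),
               dimnames = list(S = S_values, channel = NULL, fold = NULL))
  for (f in seq_len(folds)) {
    train <- trials[fold_of != f]
    test <- trials[fold_of == f]
    for (si in seq_along(S_values)) {
      S <- S_values[si]
      fit <- if (S == 1L) em_fit(train, 1L)
             else multi_restart_fit(train, S, n_restarts = n_restarts,
                                    tol_loglik = tol_loglik,
                                    tol_params = tol_params,
                                    max_iter = max_iter)
      for (m in test) {
        for (j in seq_len(J)) {
          s_hat <- if (S == 1L) rep(1L, ncol(m))
                   else viterbi_loco(m, fit, j)
          raw[si, j, f] <- raw[si, j, f] + sum((m[j, ] - fit$lambda[s_hat, j])^2)
        }
      }
    }
  }
  normed <- raw
  for (si in seq_along(S_values)) normed[si, , ] <- raw[si, , ] / raw[1, , ]
  per_fold <- apply(normed, c(1, 3), mean)       # channels out
  cv_norm <- rowMeans(per_fold)                  # folds out
  names(cv_norm) <- S_values
  structure(list(S_values = S_values, cv_norm = cv_norm,
                 per_fold = per_fold, raw = raw, folds = folds),
            class = "cv_report")
}

#' Select the number of latent phases by the elbow rule
#'
#' Runs [cv_error()] over `S_range` and applies the inclusion rule: a
#' recording passes when adding a second phase reduces the normalised
#' cross-validation error by at least 10% while no later phase adds a
#' further reduction greater than 10%. The selected phase count is the last
#' one in the chain of consecutive >= 10% reductions (1 when the second
#' phase already fails).
#'
#' @inheritParams cv_error
#' @param S_range phase counts to compare (1:8 mirrors the full procedure;
#'   smaller ranges are accepted and `pass` is `NA` when the rule cannot be
#'   evaluated).
#' @param min_reduction elbow threshold (0.10).
#' @return The [cv_error()] report extended with `reductions`, `selected`
#'   and `pass`.
#' @export
select_num_phases <- function(trials, S_range = 1:8, folds = 4,
                              n_restarts = 10, min_reduction = 0.10,
                              tol_loglik = 1e-3, tol_params = 1e-5,
                              max_iter = 500) {
  rep <- cv_error(trials, S_values = S_range, folds = folds,
                  n_restarts = n_restarts, tol_loglik = tol_loglik,
                  tol_params = tol_params, max_iter = max_iter)
  cv <- rep$cv_norm
  nS <- length(cv)
  if (nS == 1L) {
    rep$reductions <- numeric(0)
    rep$selected <- rep$S_values[1L]
    rep$pass <- NA
    return(rep)
  }
  reductions <- 1 - cv[-1L] / cv[-nS]
  names(reductions) <- rep$S_values[-1L]
  gains <- reductions >= min_reduction
  selected <- if (!gains[1L]) rep$S_values[1L] else {
    chain <- cumprod(gains) == 1
    rep$S_values[-1L][max(which(chain))]
  }
  pass <- if (nS >= 2L)
    gains[1L] && (nS == 2L || all(reductions[-1L] < min_reduction))
  else NA
  rep$reductions <- reductions
  rep$selected <- selected
  rep$pass <- unname(pass)
  rep
}

#' Per-trial multi-unit count matrices for HMM fitting
#'
#' Bins the multi-unit train of every contact at `bin_ms` within the given
#' window of each trial of a condition, the format [em_fit()] and
#' [cv_error()] consume.
#'
#' @param session a `spike_session`.
#' @param window an [analysis_window()] (default cue-to-dimming).
#' @param condition attention condition, or `NULL` for all trials.
#' @param bin_ms count bin width (10 ms).
#' @param channels optional 0-based subset of contacts (channel grouping).
#' @return List of J x T integer matrices, named by trial id.
#' @export
hmm_count_trials <- function(session, window = NULL, condition = NULL,
                             bin_ms = 10, channels = NULL) {
  if (is.null(window))
    window <- analysis_window("cue_to_dimming", session$monkey_profile)
  if (is.null(channels)) channels <- seq_len(session$n_channels) - 1L
  trials <- session_trials(session, condition)
  mua <- Filter(function(tr) tr$kind == "multi_unit" &&
                  tr$channel_index %in% channels, session$spike_trains)
  out <- lapply(seq_len(nrow(trials)), function(i) {
    iv <- resolve_window(window, trials[i, ])
    do.call(rbind, lapply(mua, function(tr) bin_spikes(tr$spike_times, iv, bin_ms)))
  })
  names(out) <- trials$trial_id
  out
}
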