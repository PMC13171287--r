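# Independent brute-force oracles. These deliberately use plain loops and
# closed forms, never the package's vectorised code paths.

# O(N^2) direct-sum cross-correlation at every lag
oracle_xcorr <- function(x, y, max_lag, spike_norm) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  vals <- numeric(2 * max_lag + 1)
  for (li in seq_along(vals)) {
    k <- li - max_lag - 1L
    s <- 0
    for (nn in seq_len(n)) {
      m <- nn + k
      if (m >= 1 && m <= n) s <- s + (x[m] - xb) * (y[nn] - yb)
    }
    vals[li] <- s / spike_norm
  }
  vals
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - xb) * (y[i] - yb)
    sxx <- sxx + (x[i] - xb)^2
    syy <- syy + (y[i] - yb)^2
  }
  sxy / sqrt(sxx * syy)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# exhaustive path enumeration of the HMM likelihood (S^T paths)
oracle_hmm_loglik <- function(counts, lambda, P, pi0) {
  counts <- rbind(counts)
  S <- nrow(lambda); T <- ncol(counts)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  lp <- apply(paths, 1, function(path) {
    v <- log(pi0[path[1]]) + sum(dpois(counts[, 1], lambda[path[1], ], log = TRUE))
    if (T > 1) for (t in 2:T) {
      v <- v + log(P[path[t - 1], path[t]]) +
        sum(dpois(counts[, t], lambda[path[t], ], log = TRUE))
    }
    v
  })
  logsumexp(lp)
}

# exhaustive argmax path (first maximum in expand.grid order)
oracle_viterbi <- function(counts, lambda, P, pi0) {
  counts <- rbind(counts)
  S <- nrow(lambda); T <- ncol(counts)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  lp <- apply(paths, 1, function(path) {
    v <- log(pi0[path[1]]) + sum(dpois(counts[, 1], lambda[path[1], ], log = TRUE))
    if (T > 1) for (t in 2:T) {
      v <- v + log(P[path[t - 1], path[t]]) +
        sum(dpois(counts[, t], lambda[path[t], ], log = TRUE))
    }
    v
  })
  list(path = unname(paths[which.max(lp), ]), logp = max(lp),
       all_logp = lp)
}

# brute force over every contiguous trial run for the stability window
oracle_stable_window <- function(E, tolerance_sd = 3) {
  E <- as.matrix(E)
  ok <- rep(TRUE, nrow(E))
  for (ch in seq_len(ncol(E))) {
    med <- median(E[, ch]); rsd <- mad(E[, ch])
    ok <- ok & (abs(E[, ch] - med) <= tolerance_sd * rsd)
  }
  best <- c(NA_integer_, NA_integer_); best_len <- 0L
  for (i in seq_len(nrow(E))) for (j in i:nrow(E)) {
    if (all(ok[i:j]) && (j - i + 1L) > best_len) {
      best <- c(i, j); best_len <- j - i + 1L
    }
  }
  best
}
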