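#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursion for one observation sequence.
// logB: S x T matrix of per-bin emission log-probabilities (channels already
// summed out). P: S x S transition matrix (rows sum to 1). pi0: length S.
// Returns gamma (S x T posteriors), xi (S x S expected transition counts
// summed over t) and the sequence log-likelihood.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix logB, NumericMatrix P, NumericVector pi0) {
  const int S = logB.nrow(), T = logB.ncol();
  NumericMatrix b(S, T);        // emissions rescaled per column
  NumericVector coff(T);        // per-column log offsets
  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int s = 0; s < S; ++s) m = std::max(m, logB(s, t));
    if (!R_finite(m))
      stop("all emission log-probabilities are -Inf at bin %d", t + 1);
    coff[t] = m;
    for (int s = 0; s < S; ++s) b(s, t) = std::exp(logB(s, t) - m);
  }

  NumericMatrix alpha(S, T), beta(S, T);
  NumericVector c(T);           // scaling factors
  double ll = 0.0;

  for (int s = 0; s < S; ++s) alpha(s, 0) = pi0[s] * b(s, 0);
  double c0 = 0.0;
  for (int s = 0; s < S; ++s) c0 += alpha(s, 0);
  if (c0 <= 0) stop("zero forward mass at bin 1");
  for (int s = 0; s < S; ++s) alpha(s, 0) /= c0;
  c[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int r = 0; r < S; ++r) acc += alpha(r, t - 1) * P(r, s);
      double v = acc * b(s, t);
      alpha(s, t) = v;
      ct += v;
    }
    if (ct <= 0) stop("zero forward mass at bin %d", t + 1);
    for (int s = 0; s < S; ++s) alpha(s, t) /= ct;
    c[t] = ct;
  }
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + coff[t];

  for (int s = 0; s < S; ++s) beta(s, T - 1) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int r = 0; r < S; ++r)
        acc += P(s, r) * b(r, t + 1) * beta(r, t + 1);
      beta(s, t) = acc / c[t + 1];
    }

  NumericMatrix gamma(S, T);
  for (int t = 0; t < T; ++t) {
    double tot = 0.0;
    for (int s = 0; s < S; ++s) {
      gamma(s, t) = alpha(s, t) * beta(s, t);
      tot += gamma(s, t);
    }
    for (int s = 0; s < S; ++s) gamma(s, t) /= tot;
  }

  NumericMatrix xi(S, S);
  for (int t = 0; t < T - 1; ++t)
    for (int r = 0; r < S; ++r)
      for (int s = 0; s < S; ++s)
        xi(r, s) += alpha(r, t) * P(r, s) * b(s, t + 1) * beta(s, t + 1) /
                    c[t + 1];

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = ll);
}

// Batched E-step over many concatenated trials. logB holds the emission
// log-probabilities of all trials side by side; ends[k] is the 1-based
// column index where trial k ends. Returns the sufficient statistics the
// M-step needs: per-bin posteriors (gamma), expected transition counts
// summed within trials (xi), the summed first-bin posteriors (pi_acc) and
// the total log-likelihood.
// [[Rcpp::export(name = ".fb_batch")]]
List fb_batch(NumericMatrix logB, IntegerVector ends, NumericMatrix P,
              NumericVector pi0) {
  const int S = logB.nrow();
  const int n_trials = ends.size();
  NumericMatrix gamma_all(S, logB.ncol());
  NumericMatrix xi(S, S);
  NumericVector pi_acc(S);
  double ll_total = 0.0;
  std::vector<double> b;   // rescaled emissions for the current trial
  std::vector<double> alpha, beta, c, coff;

  int start = 0;
  for (int k = 0; k < n_trials; ++k) {
    const int T = ends[k] - start;
    b.assign(S * T, 0.0);
    coff.assign(T, 0.0);
    for (int t = 0; t < T; ++t) {
      double m = R_NegInf;
      for (int s = 0; s < S; ++s) m = std::max(m, logB(s, start + t));
      if (!R_finite(m))
        stop("all emission log-probabilities are -Inf at bin %d", start + t + 1);
      coff[t] = m;
      for (int s = 0; s < S; ++s)
        b[s + t * S] = std::exp(logB(s, start + t) - m);
    }
    alpha.assign(S * T, 0.0);
    beta.assign(S * T, 0.0);
    c.assign(T, 0.0);
    double c0 = 0.0;
    for (int s = 0; s < S; ++s) { alpha[s] = pi0[s] * b[s]; c0 += alpha[s]; }
    if (c0 <= 0) stop("zero forward mass");
    for (int s = 0; s < S; ++s) alpha[s] /= c0;
    c[0] = c0;
    for (int t = 1; t < T; ++t) {
      double ct = 0.0;
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int r = 0; r < S; ++r) acc += alpha[r + (t - 1) * S] * P(r, s);
        double v = acc * b[s + t * S];
        alpha[s + t * S] = v;
        ct += v;
      }
      if (ct <= 0) stop("zero forward mass");
      for (int s = 0; s < S; ++s) alpha[s + t * S] /= ct;
      c[t] = ct;
    }
    for (int t = 0; t < T; ++t) ll_total += std::log(c[t]) + coff[t];

    for (int s = 0; s < S; ++s) beta[s + (T - 1) * S] = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int r = 0; r < S; ++r)
          acc += P(s, r) * b[r + (t + 1) * S] * beta[r + (t + 1) * S];
        beta[s + t * S] = acc / c[t + 1];
      }

    for (int t = 0; t < T; ++t) {
      double tot = 0.0;
      for (int s = 0; s < S; ++s) tot += alpha[s + t * S] * beta[s + t * S];
      for (int s = 0; s < S; ++s)
        gamma_all(s, start + t) = alpha[s + t * S] * beta[s + t * S] / tot;
    }
    for (int s = 0; s < S; ++s) pi_acc[s] += gamma_all(s, start);
    for (int t = 0; t < T - 1; ++t)
      for (int r = 0; r < S; ++r)
        for (int s = 0; s < S; ++s)
          xi(r, s) += alpha[r + t * S] * P(r, s) * b[s + (t + 1) * S] *
                      beta[s + (t + 1) * S] / c[t + 1];
    start = ends[k];
  }
  return List::create(_["gamma"] = gamma_all, _["xi"] = xi,
                      _["pi_acc"] = pi_acc, _["loglik"] = ll_total);
}

// Log-space Viterbi. Ties broken toward the lower state index.
// Returns the 1-based most likely state path.
// [[Rcpp::export(name = ".viterbi_core")]]
IntegerVector viterbi_core(NumericMatrix logB, NumericMatrix logP,
                           NumericVector logpi) {
  const int S = logB.nrow(), T = logB.ncol();
  NumericMatrix delta(S, T);
  IntegerMatrix psi(S, T);
  for (int s = 0; s < S; ++s) delta(s, 0) = logpi[s] + logB(s, 0);
  for (int t = 1; t < T; ++t)
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf;
      int arg = 0;
      for (int r = 0; r < S; ++r) {
        double v = delta(r, t - 1) + logP(r, s);
        if (v > best) { best = v; arg = r; }   // strict > keeps lowest index
      }
      delta(s, t) = best + logB(s, t);
      psi(s, t) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int s = 0; s < S; ++s)
    if (delta(s, T - 1) > best) { best = delta(s, T - 1); arg = s; }
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(path[t], t);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
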