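#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// log-sum-exp of a raw buffer; -Inf-safe
static inline double lse(const double *x, int n) {
  double m = R_NegInf;
  for (int i = 0; i < n; ++i)
    if (x[i] > m) m = x[i];
  if (m == R_NegInf) return R_NegInf;
  double acc = 0.0;
  for (int i = 0; i < n; ++i)
    if (x[i] > R_NegInf) acc += std::exp(x[i] - m);
  return m + std::log(acc);
}

// Exact log-domain forward-backward over an S-state chain.
// log_emit: n x S per-position per-state emission log densities,
// log_pi: S initial log probabilities, log_A: S x S transition log probs
// (rows = from-state). Returns the chunk log-likelihood from both the
// forward and the backward recursion, per-position state posteriors and
// expected transition counts summed over positions.
// [[Rcpp::export]]
List fb_core(NumericMatrix log_emit, NumericVector log_pi,
             NumericMatrix log_A) {
  const int n = log_emit.nrow(), S = log_emit.ncol();
  if (n < 1) stop("empty chunk");
  NumericMatrix la(n, S), lb(n, S);
  std::vector<double> tmp(S);

  for (int s = 0; s < S; ++s) la(0, s) = log_pi[s] + log_emit(0, s);
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < S; ++s) {
      for (int sp = 0; sp < S; ++sp) tmp[sp] = la(t - 1, sp) + log_A(sp, s);
      la(t, s) = log_emit(t, s) + lse(tmp.data(), S);
    }
  }
  for (int s = 0; s < S; ++s) tmp[s] = la(n - 1, s);
  const double ll = lse(tmp.data(), S);
  if (!R_finite(ll)) stop("non-finite chunk log-likelihood");

  for (int s = 0; s < S; ++s) lb(n - 1, s) = 0.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int s = 0; s < S; ++s) {
      for (int sp = 0; sp < S; ++sp)
        tmp[sp] = log_A(s, sp) + log_emit(t + 1, sp) + lb(t + 1, sp);
      lb(t, s) = lse(tmp.data(), S);
    }
  }
  for (int s = 0; s < S; ++s) tmp[s] = log_pi[s] + log_emit(0, s) + lb(0, s);
  const double ll_b = lse(tmp.data(), S);

  NumericMatrix gamma(n, S);
  for (int t = 0; t < n; ++t)
    for (int s = 0; s < S; ++s) {
      double g = la(t, s) + lb(t, s) - ll;
      gamma(t, s) = (g == R_NegInf) ? 0.0 : std::exp(g);
    }

  NumericMatrix xi(S, S);
  for (int t = 0; t + 1 < n; ++t)
    for (int s = 0; s < S; ++s) {
      if (la(t, s) == R_NegInf) continue;
      for (int sp = 0; sp < S; ++sp) {
        double v = la(t, s) + log_A(s, sp) + log_emit(t + 1, sp) +
                   lb(t + 1, sp) - ll;
        if (v > R_NegInf) xi(s, sp) += std::exp(v);
      }
    }

  return List::create(_["loglik"] = ll, _["loglik_backward"] = ll_b,
                      _["gamma"] = gamma, _["xi"] = xi);
}

// Forward recursion only: the chunk log-likelihood.
// [[Rcpp::export]]
double forward_loglik_core(NumericMatrix log_emit, NumericVector log_pi,
                           NumericMatrix log_A) {
  const int n = log_emit.nrow(), S = log_emit.ncol();
  if (n < 1) stop("empty chunk");
  std::vector<double> prev(S), cur(S), tmp(S);
  for (int s = 0; s < S; ++s) prev[s] = log_pi[s] + log_emit(0, s);
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < S; ++s) {
      for (int sp = 0; sp < S; ++sp) tmp[sp] = prev[sp] + log_A(sp, s);
      cur[s] = log_emit(t, s) + lse(tmp.data(), S);
    }
    prev = cur;
  }
  double ll = lse(prev.data(), S);
  if (!R_finite(ll)) stop("non-finite chunk log-likelihood");
  return ll;
}

// Max-probability state path. Ties are broken towards the lowest state
// index (strict > while scanning states in ascending order).
// [[Rcpp::export]]
List viterbi_core(NumericMatrix log_emit, NumericVector log_pi,
                  NumericMatrix log_A) {
  const int n = log_emit.nrow(), S = log_emit.ncol();
  if (n < 1) stop("empty chunk");
  NumericMatrix delta(n, S);
  IntegerMatrix psi(n, S);
  for (int s = 0; s < S; ++s) delta(0, s) = log_pi[s] + log_emit(0, s);
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf;
      int arg = 0;
      for (int sp = 0; sp < S; ++sp) {
        double v = delta(t - 1, sp) + log_A(sp, s);
        if (v > best) { best = v; arg = sp; }
      }
      delta(t, s) = log_emit(t, s) + best;
      psi(t, s) = arg;
    }
  }
  double best = R_NegInf;
  int arg = 0;
  for (int s = 0; s < S; ++s)
    if (delta(n - 1, s) > best) { best = delta(n - 1, s); arg = s; }
  if (!R_finite(best)) stop("non-finite Viterbi path score");
  IntegerVector path(n);
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  return List::create(_["path"] = path, _["score"] = best);
}
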