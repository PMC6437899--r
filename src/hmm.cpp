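#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over one observation sequence.
// logemit: n x k matrix of per-bin, per-state emission log-densities.
// trans:   k x k row-stochastic transition matrix.
// init:    length-k initial distribution.
// Returns gamma (n x k posteriors), xi (k x k expected transition counts,
// summed over t) and the sequence log-likelihood. Per-step scaling plus a
// per-bin emission shift keeps everything finite for n >= 1e6.
// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix logemit, NumericMatrix trans,
                          NumericVector init) {
  const int n = logemit.nrow(), k = logemit.ncol();
  NumericMatrix e(n, k), alpha(n, k), gamma(n, k);
  NumericVector c(n), m(n);
  double logshift = 0.0;

  for (int t = 0; t < n; ++t) {
    double mx = logemit(t, 0);
    for (int j = 1; j < k; ++j) if (logemit(t, j) > mx) mx = logemit(t, j);
    m[t] = mx;
    for (int j = 0; j < k; ++j) e(t, j) = std::exp(logemit(t, j) - mx);
    logshift += mx;
  }

  // forward
  double ct = 0.0;
  for (int j = 0; j < k; ++j) { alpha(0, j) = init[j] * e(0, j); ct += alpha(0, j); }
  if (ct <= 0.0) stop("zero forward probability at position 1");
  for (int j = 0; j < k; ++j) alpha(0, j) /= ct;
  c[0] = ct;
  for (int t = 1; t < n; ++t) {
    ct = 0.0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int i = 0; i < k; ++i) s += alpha(t - 1, i) * trans(i, j);
      s *= e(t, j);
      alpha(t, j) = s;
      ct += s;
    }
    if (ct <= 0.0) stop("zero forward probability at position %d", t + 1);
    for (int j = 0; j < k; ++j) alpha(t, j) /= ct;
    c[t] = ct;
  }

  // backward + gamma + xi
  NumericMatrix xi(k, k);
  std::vector<double> beta(k, 1.0), betn(k);
  for (int j = 0; j < k; ++j) gamma(n - 1, j) = alpha(n - 1, j);
  for (int t = n - 2; t >= 0; --t) {
    for (int j = 0; j < k; ++j) betn[j] = e(t + 1, j) * beta[j];
    double gsum = 0.0;
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        double x = alpha(t, i) * trans(i, j) * betn[j] / c[t + 1];
        xi(i, j) += x;
        s += trans(i, j) * betn[j];
      }
      s /= c[t + 1];
      gamma(t, i) = alpha(t, i) * s;
      gsum += gamma(t, i);
      beta[i] = s; // overwritten after loop? no: beta[i] must not be used for other i this step
    }
    // note: beta[i] assignment above uses only trans row i and betn (old beta),
    // so in-place update is safe.
    if (gsum > 0) for (int i = 0; i < k; ++i) gamma(t, i) /= gsum;
  }

  double loglik = logshift;
  for (int t = 0; t < n; ++t) loglik += std::log(c[t]);

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// Viterbi decoding with optional start/end state constraints.
// logtrans/loginit hold log-probabilities (-Inf where forbidden).
// Ties broken toward the lowest state index. Returns 1-based path.
// [[Rcpp::export]]
List cpp_viterbi(NumericMatrix logemit, NumericMatrix logtrans,
                 NumericVector loginit, LogicalVector allow_start,
                 LogicalVector allow_end) {
  const int n = logemit.nrow(), k = logemit.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  NumericVector delta(k), dnew(k);
  IntegerMatrix psi(n, k);

  for (int j = 0; j < k; ++j)
    delta[j] = allow_start[j] ? loginit[j] + logemit(0, j) : NEG;

  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < k; ++j) {
      double best = NEG; int arg = 0;
      for (int i = 0; i < k; ++i) {
        double v = delta[i] + logtrans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      dnew[j] = best + logemit(t, j);
      psi(t, j) = arg;
    }
    for (int j = 0; j < k; ++j) delta[j] = dnew[j];
  }

  double best = NEG; int arg = -1;
  for (int j = 0; j < k; ++j) {
    if (!allow_end[j]) continue;
    if (delta[j] > best) { best = delta[j]; arg = j; }
  }
  if (arg < 0 || best == NEG)
    return List::create(_["ok"] = false);

  IntegerVector path(n);
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < n; ++t) path[t] += 1;

  return List::create(_["ok"] = true, _["path"] = path, _["logprob"] = best);
}

// Sample a state path by inversion from pre-drawn uniforms (keeps the R RNG
// in charge so results are reproducible from set.seed()). 1-based output.
// [[Rcpp::export]]
IntegerVector cpp_sample_path(NumericMatrix trans, NumericVector init,
                              NumericVector u) {
  const int n = u.size(), k = init.size();
  IntegerVector path(n);
  int s = k - 1;
  double acc = 0.0;
  for (int j = 0; j < k; ++j) { acc += init[j]; if (u[0] <= acc) { s = j; break; } }
  path[0] = s + 1;
  for (int t = 1; t < n; ++t) {
    acc = 0.0;
    int nxt = k - 1;
    for (int j = 0; j < k; ++j) { acc += trans(s, j); if (u[t] <= acc) { nxt = j; break; } }
    s = nxt;
    path[t] = s + 1;
  }
  return path;
}
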