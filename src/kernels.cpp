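#include <Rcpp.h>
using namespace Rcpp;

// Edge-level primitives for attention message passing.  Feature matrices are
// passed transposed (one COLUMN per node) so every gather/scatter touches
// contiguous memory.  All index vectors are 0-based; callers guarantee that
// every aggregation group (receiver node) occurs at least once (self-loops).

// colSums(X[, ix] * Y[, iy]) over edges: the Q_i . K_j attention logits and
// the dZ_i . M_j terms of the backward pass.
// [[Rcpp::export(name = ".edge_dot_cols")]]
NumericVector edge_dot_cols(const NumericMatrix& X, const NumericMatrix& Y,
                            const IntegerVector& ix, const IntegerVector& iy) {
  const int m = ix.size(), d = X.nrow();
  NumericVector out(m);
  const double* xp = X.begin();
  const double* yp = Y.begin();
  for (int e = 0; e < m; ++e) {
    const double* xa = xp + (size_t)ix[e] * d;
    const double* yb = yp + (size_t)iy[e] * d;
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xa[j] * yb[j];
    out[e] = s;
  }
  return out;
}

// Numerically stable softmax of edge logits within receiver groups g (0-based
// node ids, n nodes).  With all-zero logits this reduces exactly to 1/|N(i)|
// (exp(0) = 1 and integer-valued sums are exact in doubles), which is what
// makes the uniform-weight GCN variant bit-identical to zero-logit attention.
// [[Rcpp::export(name = ".group_softmax")]]
NumericVector group_softmax(const NumericVector& logit, const IntegerVector& g,
                            const int n) {
  const int m = logit.size();
  NumericVector mx(n, R_NegInf), denom(n), out(m);
  for (int e = 0; e < m; ++e)
    if (logit[e] > mx[g[e]]) mx[g[e]] = logit[e];
  for (int e = 0; e < m; ++e) {
    out[e] = std::exp(logit[e] - mx[g[e]]);
    denom[g[e]] += out[e];
  }
  for (int e = 0; e < m; ++e) out[e] /= denom[g[e]];
  return out;
}

// d logit = a * (d a - sum_{group} a * d a): softmax Jacobian within groups.
// [[Rcpp::export(name = ".group_softmax_backward")]]
NumericVector group_softmax_backward(const NumericVector& a,
                                     const NumericVector& da,
                                     const IntegerVector& g, const int n) {
  const int m = a.size();
  NumericVector s(n), out(m);
  for (int e = 0; e < m; ++e) s[g[e]] += a[e] * da[e];
  for (int e = 0; e < m; ++e) out[e] = a[e] * (da[e] - s[g[e]]);
  return out;
}

// out[, to[e]] += w[e] * X[, from[e]]: the weighted scatter used for the
// forward aggregation and for every row-gradient accumulation.
// [[Rcpp::export(name = ".scatter_scale_cols")]]
NumericMatrix scatter_scale_cols(const NumericVector& w,
                                 const NumericMatrix& X,
                                 const IntegerVector& from,
                                 const IntegerVector& to, const int nout) {
  const int m = w.size(), d = X.nrow();
  NumericMatrix out(d, nout);
  const double* xp = X.begin();
  double* op = out.begin();
  for (int e = 0; e < m; ++e) {
    const double* xa = xp + (size_t)from[e] * d;
    double* ob = op + (size_t)to[e] * d;
    const double we = w[e];
    for (int j = 0; j < d; ++j) ob[j] += we * xa[j];
  }
  return out;
}
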