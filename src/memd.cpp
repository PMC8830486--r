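#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline through strictly increasing knots x with one value
// column per variate; evaluated at integer sample times 0..T-1 into `out`
// (overwritten).  Second derivatives from the natural boundary condition,
// solved by the Thomas algorithm with a multi-column RHS.
static void spline_eval(const std::vector<double> &x,
                        const std::vector<std::vector<double> > &y,
                        int T, int nvar, std::vector<double> &out) {
  const int M = (int)x.size();
  if (M == 2) { // degenerate: linear interpolation
    for (int v = 0; v < nvar; ++v) {
      double slope = (y[1][v] - y[0][v]) / (x[1] - x[0]);
      for (int t = 0; t < T; ++t)
        out[(size_t)v * T + t] = y[0][v] + slope * (t - x[0]);
    }
    return;
  }
  std::vector<double> h(M - 1);
  for (int i = 0; i < M - 1; ++i) h[i] = x[i + 1] - x[i];
  const int n = M - 2;
  std::vector<double> a(n), b(n), c(n);
  std::vector<std::vector<double> > d(n, std::vector<double>(nvar));
  for (int i = 0; i < n; ++i) {
    a[i] = h[i];
    b[i] = 2.0 * (h[i] + h[i + 1]);
    c[i] = h[i + 1];
    for (int v = 0; v < nvar; ++v)
      d[i][v] = 6.0 * ((y[i + 2][v] - y[i + 1][v]) / h[i + 1] -
                       (y[i + 1][v] - y[i][v]) / h[i]);
  }
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    for (int v = 0; v < nvar; ++v) d[i][v] -= w * d[i - 1][v];
  }
  std::vector<std::vector<double> > M2(M, std::vector<double>(nvar, 0.0));
  for (int v = 0; v < nvar; ++v) M2[n][v] = d[n - 1][v] / b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    for (int v = 0; v < nvar; ++v)
      M2[i + 1][v] = (d[i][v] - c[i] * M2[i + 2][v]) / b[i];
  int seg = 0;
  for (int t = 0; t < T; ++t) {
    double tt = (double)t;
    while (seg < M - 2 && tt > x[seg + 1]) ++seg;
    double hi = h[seg];
    double A = (x[seg + 1] - tt) / hi;
    double B = (tt - x[seg]) / hi;
    double A3 = (A * A * A - A) * hi * hi / 6.0;
    double B3 = (B * B * B - B) * hi * hi / 6.0;
    for (int v = 0; v < nvar; ++v)
      out[(size_t)v * T + t] = A * y[seg][v] + B * y[seg + 1][v] +
        A3 * M2[seg][v] + B3 * M2[seg + 1][v];
  }
}

// Envelope of the multivariate signal through the interior strict maxima
// of sign * projection (sign = -1 gives the minima envelope), with up to
// two extrema mirrored about each boundary.  Writes into `out`; returns
// the extrema count, or -1 when fewer than two exist.
static int one_envelope(const NumericMatrix &v, const std::vector<double> &proj,
                        double sign, int T, int nvar,
                        std::vector<double> &out) {
  std::vector<int> tm;
  for (int t = 1; t < T - 1; ++t)
    if (sign * proj[t] > sign * proj[t - 1] &&
        sign * proj[t] > sign * proj[t + 1]) tm.push_back(t);
  const int J = (int)tm.size();
  if (J < 2) return -1;
  // sub-sample refinement: parabola through the three samples around each
  // extremum gives the knot instant; each variate's value there from its
  // own local quadratic.  Removes the O(dt^2) jitter that otherwise makes
  // tone envelopes wobble.
  std::vector<double> tx(J);
  std::vector<std::vector<double> > tv(J, std::vector<double>(nvar));
  for (int j = 0; j < J; ++j) {
    int t = tm[j];
    double pm = proj[t - 1], p0 = proj[t], pp = proj[t + 1];
    double denom = pm - 2.0 * p0 + pp;
    double del = (denom != 0.0) ? 0.5 * (pm - pp) / denom : 0.0;
    if (del > 0.5) del = 0.5;
    if (del < -0.5) del = -0.5;
    tx[j] = t + del;
    for (int vv = 0; vv < nvar; ++vv) {
      double vm = v(vv, t - 1), v0 = v(vv, t), vp = v(vv, t + 1);
      tv[j][vv] = v0 + 0.5 * del * (vp - vm) +
        0.5 * del * del * (vp - 2.0 * v0 + vm);
    }
  }
  std::vector<double> x;
  std::vector<std::vector<double> > y;
  int nmir = std::min(2, J);
  for (int j = nmir - 1; j >= 0; --j) { // reflect about t = 0
    x.push_back(-tx[j]);
    y.push_back(tv[j]);
  }
  for (int j = 0; j < J; ++j) {
    x.push_back(tx[j]);
    y.push_back(tv[j]);
  }
  for (int j = 0; j < nmir; ++j) { // reflect about t = T-1
    x.push_back(2.0 * (T - 1) - tx[J - 1 - j]);
    y.push_back(tv[J - 1 - j]);
  }
  spline_eval(x, y, T, nvar, out);
  return J;
}

// Mean envelope m(t) and local envelope amplitude a(t) of a multivariate
// signal.  Per direction: the projection's maxima and minima each define a
// cubic-spline multivariate envelope (so the direction set acts as if
// closed under negation); m averages all 2K envelopes, and a(t) averages
// over directions the variate-space norm of half the upper-lower envelope
// difference (the local oscillation amplitude used by the sifting
// stoppage rule).  A projection with fewer than two maxima or minima
// marks the signal as a residue.  v: nvar x T, dirs: K x nvar.
// [[Rcpp::export]]
List memd_envelope_mean_cpp(NumericMatrix v, NumericMatrix dirs) {
  const int nvar = v.nrow(), T = v.ncol(), K = dirs.nrow();
  if (dirs.ncol() != nvar) stop("direction dimensionality mismatch");
  std::vector<double> acc((size_t)nvar * T, 0.0);
  std::vector<double> eup((size_t)nvar * T), edn((size_t)nvar * T);
  std::vector<double> amp(T, 0.0);
  IntegerVector nmax(K);
  bool ok = true;

  std::vector<double> proj(T);
  for (int k = 0; k < K && ok; ++k) {
    for (int t = 0; t < T; ++t) {
      double s = 0.0;
      for (int vv = 0; vv < nvar; ++vv) s += dirs(k, vv) * v(vv, t);
      proj[t] = s;
    }
    int jmax = one_envelope(v, proj, +1.0, T, nvar, eup);
    int jmin = one_envelope(v, proj, -1.0, T, nvar, edn);
    nmax[k] = jmax;
    if (jmax < 0 || jmin < 0) { ok = false; break; }
    for (size_t i = 0; i < acc.size(); ++i) acc[i] += eup[i] + edn[i];
    for (int t = 0; t < T; ++t) {
      double s = 0.0;
      for (int vv = 0; vv < nvar; ++vv) {
        double dd = (eup[(size_t)vv * T + t] - edn[(size_t)vv * T + t]) / 2.0;
        s += dd * dd;
      }
      amp[t] += std::sqrt(s);
    }
  }

  NumericMatrix m(nvar, T);
  NumericVector amp_out(T);
  if (ok) {
    for (int vv = 0; vv < nvar; ++vv)
      for (int t = 0; t < T; ++t)
        m(vv, t) = acc[(size_t)vv * T + t] / (2 * K);
    for (int t = 0; t < T; ++t) amp_out[t] = amp[t] / K;
  }
  return List::create(_["ok"] = ok, _["m"] = m, _["amp"] = amp_out,
                      _["n_maxima"] = nmax);
}
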