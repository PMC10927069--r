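#include <Rcpp.h>
using namespace Rcpp;

// Product-integral propagation of state-occupation probabilities.
//
// inc:  m x K matrix of off-diagonal cumulative-hazard increments
//       dA_{h->j}(t_m), one column per permitted transition, already scaled
//       by exp(beta' z) for the exposure level of interest.
// from, to: 1-based state indices per transition column.
// pi:   initial distribution over the n_state states.
// grid: ordered event times t_1 < ... < t_m (days).
// horizon: integration end T.
//
// At each event time the increment matrix dA has off-diagonals inc[m, k]
// and diagonal -row sum; if an off-diagonal row sum exceeds 1 the row is
// rescaled to 1 (counted in `clipped`). Occupation probabilities are
// propagated as p <- p (I + dA); expected durations are the exact integral
// of the piecewise-constant occupation path over [0, horizon].
//
// Returns: occupation path ((m+1) x n_state, row 0 at time 0), durations
// (n_state), number of clipped rows, and optionally the full transition
// matrix path P(0, t) ((m+1) x n_state x n_state, row-major per slice).
// [[Rcpp::export]]
List aj_path_cpp(NumericMatrix inc, IntegerVector from, IntegerVector to,
                 NumericVector pi, NumericVector grid, double horizon,
                 bool return_P = false) {
  const int m = inc.nrow(), K = inc.ncol(), S = pi.size();
  if (from.size() != K || to.size() != K)
    stop("from/to must match the number of increment columns");
  if (grid.size() != m) stop("grid length must match increment rows");

  std::vector<double> p(pi.begin(), pi.end());
  std::vector<double> pnew(S), rowsum(S), scale(S);
  NumericMatrix occ(m + 1, S);
  for (int s = 0; s < S; ++s) occ(0, s) = p[s];
  NumericVector E(S);
  int clipped = 0;

  NumericVector Parr;
  std::vector<double> P, Pnew;
  if (return_P) {
    Parr = NumericVector(Dimension(S, S, m + 1));
    P.assign(S * S, 0.0);
    Pnew.assign(S * S, 0.0);
    for (int s = 0; s < S; ++s) { P[s * S + s] = 1.0; Parr[s * S + s] = 1.0; }
  }

  double tprev = 0.0;
  for (int i = 0; i < m; ++i) {
    double t = grid[i];
    if (t < tprev) stop("grid must be nondecreasing");
    for (int s = 0; s < S; ++s) E[s] += p[s] * (t - tprev);
    tprev = t;

    std::fill(rowsum.begin(), rowsum.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      double v = inc(i, k);
      if (v < 0) stop("negative cumulative-hazard increment");
      rowsum[from[k] - 1] += v;
    }
    for (int s = 0; s < S; ++s) {
      if (rowsum[s] > 1.0) { scale[s] = 1.0 / rowsum[s]; ++clipped; }
      else scale[s] = 1.0;
    }

    std::copy(p.begin(), p.end(), pnew.begin());
    if (return_P) std::copy(P.begin(), P.end(), Pnew.begin());
    for (int k = 0; k < K; ++k) {
      double v = inc(i, k);
      if (v == 0.0) continue;
      int h = from[k] - 1, j = to[k] - 1;
      v *= scale[h];
      double flow = p[h] * v;
      pnew[j] += flow;
      pnew[h] -= flow;
      if (return_P) {
        for (int r = 0; r < S; ++r) {
          double f = P[h * S + r] * v; // column-major: P[r, h]
          Pnew[j * S + r] += f;
          Pnew[h * S + r] -= f;
        }
      }
    }
    for (int s = 0; s < S; ++s) {
      if (pnew[s] < -1e-9) stop("occupation probability went negative");
      if (pnew[s] < 0) pnew[s] = 0;
    }
    std::swap(p, pnew);
    for (int s = 0; s < S; ++s) occ(i + 1, s) = p[s];
    if (return_P) {
      std::swap(P, Pnew);
      std::copy(P.begin(), P.end(), Parr.begin() + (R_xlen_t)(i + 1) * S * S);
    }
  }
  if (horizon < tprev) stop("horizon precedes the last event time");
  for (int s = 0; s < S; ++s) E[s] += p[s] * (horizon - tprev);

  List out = List::create(_["occupation"] = occ, _["durations"] = E,
                          _["clipped"] = clipped);
  if (return_P) out["P"] = Parr;
  return out;
}
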