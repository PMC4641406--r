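#include <Rcpp.h>
using namespace Rcpp;

// Brownian pruning (Felsenstein contrasts) for arbitrary per-branch variances.
// Edges must be in postorder (children before parents). stem_var[node] is the
// total process variance accumulated on the edge above `node`; tip_var adds
// observation variance at the leaves. Returns the root-marginal (flat prior on
// the root state, i.e. REML/contrast) log-likelihood together with the
// GLS root estimate and its variance, from which the ML and fixed-root
// likelihoods follow in R.
// [[Rcpp::export]]
NumericVector cpp_bm_pruning(int n_nodes, int n_tip,
                             IntegerVector edge_parent, IntegerVector edge_child,
                             NumericVector stem_var, NumericVector tip_var,
                             NumericVector x) {
  std::vector<double> xh(n_nodes + 1), vh(n_nodes + 1);
  std::vector<int> has(n_nodes + 1, 0);
  for (int i = 1; i <= n_tip; ++i) {
    xh[i] = x[i - 1];
    vh[i] = tip_var[i - 1];
    has[i] = 1;
  }
  const double LOG2PI = 1.837877066409345483560659472811;
  double lnl = 0.0;
  int ne = edge_parent.size();
  for (int e = 0; e < ne; ++e) {
    int c = edge_child[e], p = edge_parent[e];
    double xc = xh[c];
    double vc = vh[c] + stem_var[c - 1];
    if (!has[p]) {
      xh[p] = xc; vh[p] = vc; has[p] = 1;
    } else {
      double vs = vh[p] + vc;
      if (vs <= 0) return NumericVector::create(R_NegInf, NA_REAL, NA_REAL);
      double d = xh[p] - xc;
      lnl += -0.5 * (LOG2PI + std::log(vs) + d * d / vs);
      xh[p] = (xh[p] * vc + xc * vh[p]) / vs;
      vh[p] = vh[p] * vc / vs;
    }
  }
  int root = edge_parent[ne - 1];
  return NumericVector::create(lnl, xh[root], vh[root]);
}

// One root-to-tip pass over a painted tree. Edges are given in preorder
// (parents before children); each edge carries >= 1 painting segments,
// ordered from the parent end, flattened into the seg_* arrays with CSR-style
// offsets (edge_off, edge_nseg; 0-based into the seg arrays).
// Per segment: duration dt, OU parameters (alpha > 0) or a precomputed
// variance increment vincr (alpha == 0 covers BM and time-varying-rate
// segments), and the 0-based index of the mean parameter (theta or root
// state) it pulls toward.
// Outputs, per node: accumulated variance Vacc, accumulated log decay
// (-sum alpha*dt from the root), and the row of the mean design matrix M so
// that E[x_node] = M %*% c(mean parameters).
// [[Rcpp::export]]
List cpp_paint_pass(int n_nodes, int root,
                    IntegerVector edge_parent, IntegerVector edge_child,
                    IntegerVector edge_off, IntegerVector edge_nseg,
                    NumericVector seg_dt, NumericVector seg_alpha,
                    NumericVector seg_sigma2, NumericVector seg_vincr,
                    IntegerVector seg_par, int n_par, int root_par) {
  NumericVector vacc(n_nodes), ldec(n_nodes);
  NumericMatrix M(n_nodes, n_par);
  M(root - 1, root_par) = 1.0;
  int ne = edge_parent.size();
  std::vector<double> row(n_par);
  for (int e = 0; e < ne; ++e) {
    int p = edge_parent[e] - 1, c = edge_child[e] - 1;
    double v = vacc[p], l = ldec[p];
    for (int j = 0; j < n_par; ++j) row[j] = M(p, j);
    int off = edge_off[e], ns = edge_nseg[e];
    for (int s = off; s < off + ns; ++s) {
      double a = seg_alpha[s], dt = seg_dt[s];
      if (a > 0) {
        double E = std::exp(-a * dt);
        double one_m_E2 = -std::expm1(-2.0 * a * dt);
        v = v * E * E + seg_sigma2[s] * one_m_E2 / (2.0 * a);
        l -= a * dt;
        for (int j = 0; j < n_par; ++j) row[j] *= E;
        row[seg_par[s]] += 1.0 - E;
      } else {
        v += seg_vincr[s];
      }
    }
    vacc[c] = v; ldec[c] = l;
    for (int j = 0; j < n_par; ++j) M(c, j) = row[j];
  }
  return List::create(_["vacc"] = vacc, _["logdecay"] = ldec, _["M"] = M);
}

// Era-style rate classes: each shift (identified by the child node of its
// edge) opens a new class inherited by the whole descendant clade until
// overridden by a nested shift. Edges in preorder. Returns the 0-based class
// of every edge; class k+1 belongs to shift_child[k], class 0 to the root.
// [[Rcpp::export]]
IntegerVector cpp_era_classes(int n_nodes, int root,
                              IntegerVector edge_parent, IntegerVector edge_child,
                              IntegerVector shift_child) {
  std::vector<int> shift_of(n_nodes + 1, 0);
  for (int k = 0; k < shift_child.size(); ++k) shift_of[shift_child[k]] = k + 1;
  std::vector<int> cls(n_nodes + 1, 0);
  cls[root] = 0;
  int ne = edge_parent.size();
  IntegerVector out(ne);
  for (int e = 0; e < ne; ++e) {
    int p = edge_parent[e], c = edge_child[e];
    int k = shift_of[c] ? shift_of[c] : cls[p];
    cls[c] = k;
    out[e] = k;
  }
  return out;
}
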