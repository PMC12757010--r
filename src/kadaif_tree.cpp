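// Tree engine for subspace-ordination isolation forests.
//
// Each internal node draws a random feature subset, renormalizes it to
// relative abundances (Bray-Curtis mode), ordinates the node's samples
// (PCoA on Bray-Curtis, or PCA), picks one ordination axis at random
// (probability proportional to variance explained by default), and splits
// at a threshold drawn uniformly over the projection range.  The baseline
// single-feature isolation forest shares the same recursion and scoring.
//
// All randomness comes from R's global RNG (unif_rand), so a set.seed()
// before each tree build makes the whole forest bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

enum Reduction { RED_PCOA = 0, RED_PCA = 1, RED_SINGLE = 2 };
enum PcSel { SEL_VARW = 0, SEL_UNIF = 1, SEL_FIRST = 2 };

struct Params {
  int psi;
  bool with_replacement;
  int r;
  int max_depth;
  int n_components;
  int pc_sel;
  int reduction;
  bool renormalize;
  int retry_limit;
};

// c(m) = 2(H(m-1) - (m-1)/m) for m >= 2, else 0; exact summation.
double c_norm(int m) {
  if (m < 2) return 0.0;
  double h = 0.0;
  for (int i = 1; i <= m - 1; ++i) h += 1.0 / i;
  return 2.0 * (h - (double)(m - 1) / m);
}

int draw_int(int n) {  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

arma::uvec sample_features(int F, const Params& P) {
  int psi = P.psi;
  if (!P.with_replacement && psi > F) psi = F;
  arma::uvec out(psi);
  if (P.with_replacement) {
    for (int j = 0; j < psi; ++j) out(j) = draw_int(F);
  } else {
    // partial Fisher-Yates
    std::vector<int> pool(F);
    for (int i = 0; i < F; ++i) pool[i] = i;
    for (int j = 0; j < psi; ++j) {
      int k = j + draw_int(F - j);
      std::swap(pool[j], pool[k]);
      out(j) = pool[j];
    }
  }
  return out;
}

// Bray-Curtis with the zero-row convention: d = 0 between two all-zero
// rows, d = 1 between an all-zero and a non-zero row.
arma::mat bray_curtis(const arma::mat& sub) {
  int m = sub.n_rows;
  arma::vec rs = arma::sum(sub, 1);
  arma::mat D(m, m, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double denom = rs(i) + rs(j);
      double d;
      if (denom <= 0.0) {
        d = 0.0;
      } else {
        double s = arma::accu(arma::min(sub.row(i), sub.row(j)));
        d = 1.0 - 2.0 * s / denom;
      }
      D(i, j) = D(j, i) = d;
    }
  }
  return D;
}

// Flip so the largest-magnitude entry is positive (reproducible signs).
void fix_sign(arma::vec& v) {
  arma::uword idx = arma::index_max(arma::abs(v));
  if (v(idx) < 0) v = -v;
}

int pick_axis(const arma::vec& w, int k, int mode) {
  if (mode == SEL_FIRST || k == 1) return 0;
  if (mode == SEL_UNIF) return draw_int(k);
  double tot = 0.0;
  for (int i = 0; i < k; ++i) tot += w(i);
  double u = unif_rand() * tot, cum = 0.0;
  for (int i = 0; i < k; ++i) {
    cum += w(i);
    if (u <= cum) return i;
  }
  return k - 1;
}

struct SplitResult {
  arma::uvec feats;       // column indices into X (0-based)
  int comp;               // chosen axis (0-based)
  double threshold;
  arma::uvec left, right; // positions within the node (0-based)
  arma::vec means;        // pca only: per-feature means of the node subset
  arma::vec loading;      // pca only: loading vector of the chosen axis
};

// One split attempt; false signals a degenerate split (caller retries).
bool try_split(const arma::mat& X, const arma::uvec& rows, const Params& P,
               SplitResult& out) {
  int m = rows.n_elem;
  int F = X.n_cols;
  arma::vec proj;

  if (P.reduction == RED_SINGLE) {
    out.feats.set_size(1);
    out.feats(0) = draw_int(F);
    proj = X.submat(rows, out.feats);
    out.comp = 0;
  } else {
    out.feats = sample_features(F, P);
    arma::mat sub = X.submat(rows, out.feats);
    if (P.renormalize) {
      for (int i = 0; i < m; ++i) {
        double s = arma::accu(sub.row(i));
        if (s > 0) sub.row(i) /= s;
      }
    }
    if (P.reduction == RED_PCOA) {
      arma::mat D = bray_curtis(sub);
      // Gower centering: B = -0.5 * (A - rm 1' - 1 rm' + gm), A = D^2
      arma::mat A = arma::square(D);
      arma::vec rm = arma::mean(A, 1);
      double gm = arma::mean(rm);
      arma::mat B = -0.5 * A;
      B.each_col() += 0.5 * rm;
      B.each_row() += 0.5 * rm.t();  // A symmetric: column means == row means
      B -= 0.5 * gm;
      arma::vec eval;
      arma::mat evec;
      if (!arma::eig_sym(eval, evec, B)) return false;
      double evmax = eval.max();
      double tol = std::max(1e-12, evmax * 1e-9);
      // positive eigenvalues, descending (eig_sym returns ascending)
      std::vector<int> pos;
      for (int i = (int)eval.n_elem - 1; i >= 0; --i)
        if (eval(i) > tol) pos.push_back(i);
      if (pos.empty()) return false;
      double sum_pos = 0.0;
      for (size_t i = 0; i < pos.size(); ++i) sum_pos += eval(pos[i]);
      int k = std::min<int>(P.n_components, pos.size());
      arma::vec w(k);
      for (int i = 0; i < k; ++i) w(i) = eval(pos[i]) / sum_pos;
      out.comp = pick_axis(w, k, P.pc_sel);
      int e = pos[out.comp];
      arma::vec axis = evec.col(e);
      fix_sign(axis);
      proj = axis * std::sqrt(eval(e));
    } else {  // RED_PCA
      out.means = arma::mean(sub, 0).t();
      arma::mat C = sub.each_row() - out.means.t();
      arma::mat U, V;
      arma::vec s;
      if (!arma::svd_econ(U, s, V, C)) return false;
      double smax = s.max();
      double tol = std::max(1e-12, smax * 1e-9);
      int npos = 0;
      for (arma::uword i = 0; i < s.n_elem; ++i)
        if (s(i) > tol) ++npos;
      if (npos == 0) return false;
      double sum_var = 0.0;
      for (int i = 0; i < npos; ++i) sum_var += s(i) * s(i);
      int k = std::min(P.n_components, npos);
      arma::vec w(k);
      for (int i = 0; i < k; ++i) w(i) = s(i) * s(i) / sum_var;
      out.comp = pick_axis(w, k, P.pc_sel);
      arma::vec load = V.col(out.comp);
      fix_sign(load);
      out.loading = load;
      proj = C * load;
    }
  }

  double mn = proj.min(), mx = proj.max();
  if (!(mx > mn)) return false;
  out.threshold = mn + unif_rand() * (mx - mn);
  out.left = arma::find(proj <= out.threshold);
  out.right = arma::find(proj > out.threshold);
  if (out.left.n_elem == 0 || out.right.n_elem == 0) return false;
  return true;
}

List make_leaf(const arma::uvec& rows, int depth, arma::vec& depth_acc) {
  int m = rows.n_elem;
  double d = depth + c_norm(m);
  for (int i = 0; i < m; ++i) depth_acc(rows(i)) += d;
  return List::create(_["kind"] = "leaf",
                      _["members"] = IntegerVector(rows.begin(), rows.end()) + 1,
                      _["depth"] = depth,
                      _["size"] = m);
}

List build_node(const arma::mat& X, const arma::uvec& rows, int depth,
                const Params& P, arma::vec& depth_acc) {
  int m = rows.n_elem;
  if (depth >= P.max_depth || m <= P.r)
    return make_leaf(rows, depth, depth_acc);

  SplitResult sp;
  bool ok = false;
  for (int attempt = 0; attempt <= P.retry_limit && !ok; ++attempt)
    ok = try_split(X, rows, P, sp);
  if (!ok) return make_leaf(rows, depth, depth_acc);

  List left = build_node(X, rows(sp.left), depth + 1, P, depth_acc);
  List right = build_node(X, rows(sp.right), depth + 1, P, depth_acc);
  List node = List::create(
      _["kind"] = "split",
      _["features"] = IntegerVector(sp.feats.begin(), sp.feats.end()) + 1,
      _["component"] = sp.comp + 1,
      _["threshold"] = sp.threshold,
      _["left"] = left,
      _["right"] = right);
  if (P.reduction == RED_PCA) {
    node["means"] = NumericVector(sp.means.begin(), sp.means.end());
    node["loading"] = NumericVector(sp.loading.begin(), sp.loading.end());
  }
  return node;
}

Params read_params(List params) {
  Params P;
  P.psi = as<int>(params["psi"]);
  P.with_replacement = as<bool>(params["with_replacement"]);
  P.r = as<int>(params["r"]);
  P.max_depth = as<int>(params["max_depth"]);
  P.n_components = as<int>(params["n_components"]);
  P.pc_sel = as<int>(params["pc_sel"]);
  P.reduction = as<int>(params["reduction"]);
  P.renormalize = as<bool>(params["renormalize"]);
  P.retry_limit = as<int>(params["retry_limit"]);
  return P;
}

}  // namespace

// Build one isolation tree on all rows of X; returns the tree structure and
// the per-sample adjusted path length (edge count to leaf + c(leaf size)).
// [[Rcpp::export(name = ".build_tree_cpp")]]
List build_tree_cpp(const arma::mat& X, List params) {
  Params P = read_params(params);
  int n = X.n_rows;
  arma::vec depth_acc(n, arma::fill::zeros);
  arma::uvec rows = arma::regspace<arma::uvec>(0, n - 1);
  List tree = build_node(X, rows, 0, P, depth_acc);
  return List::create(_["depths"] = NumericVector(depth_acc.begin(), depth_acc.end()),
                      _["tree"] = tree);
}

// Test hook: the engine's Bray-Curtis matrix (zero-row conventions included).
// [[Rcpp::export(name = ".bray_curtis_cpp")]]
arma::mat bray_curtis_cpp(const arma::mat& x) {
  return bray_curtis(x);
}

// Test hook: the engine's normalization constant.
// [[Rcpp::export(name = ".c_norm_cpp")]]
double c_norm_cpp(int n) { return c_norm(n); }
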