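#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Least-absolute-deviations (median) regression via a dense primal simplex
// on the residual-splitting linear program
//
//   min sum_i w_i (u_i^+ + u_i^-)   s.t.  X beta + u^+ - u^- = y,
//
// beta free (split beta = beta^+ - beta^-), u^+, u^- >= 0.  Row weights w
// carry the smoothing penalty when the design is augmented with penalty
// rows.  The basis inverse is kept dense and updated by elementary row
// operations; Dantzig pricing with a Bland fallback guards against cycling
// on degenerate instances.  The optimum is a vertex, so the attained
// objective is exact up to round-off; coefficient non-uniqueness (possible
// for L1 fits) only affects beta, never the objective.

namespace {

class L1Simplex {
public:
  L1Simplex(const mat& X, const vec& y, const vec& w)
    : X_(X), y_(y), w_(w),
      n_(static_cast<int>(X.n_rows)), p_(static_cast<int>(X.n_cols)),
      Binv_(n_, n_, fill::zeros), basis_(n_), xB_(n_), cB_(n_) {}

  bool solve(int maxit) {
    const double tol = 1e-9;
    for (int i = 0; i < n_; ++i) {
      if (y_[i] >= 0.0) {
        basis_[i] = 2 * p_ + i; Binv_(i, i) = 1.0; xB_[i] = y_[i];
      } else {
        basis_[i] = 2 * p_ + n_ + i; Binv_(i, i) = -1.0; xB_[i] = -y_[i];
      }
      cB_[i] = w_[i];
    }
    const int blandAfter = 20 * (n_ + p_);
    for (iters_ = 0; iters_ < maxit; ++iters_) {
      const vec pi = Binv_.t() * cB_;
      const vec s = X_.t() * pi;
      int enter = -1;
      double best = -tol;
      const bool bland = iters_ >= blandAfter;
      const int ncol = 2 * p_ + 2 * n_;
      for (int j = 0; j < ncol; ++j) {
        double d;
        if (j < p_)               d = -s[j];
        else if (j < 2 * p_)      d =  s[j - p_];
        else if (j < 2 * p_ + n_) d = w_[j - 2 * p_] - pi[j - 2 * p_];
        else                      d = w_[j - 2 * p_ - n_] + pi[j - 2 * p_ - n_];
        if (d < -tol) {
          if (bland) { enter = j; break; }
          if (d < best) { best = d; enter = j; }
        }
      }
      if (enter < 0) return true;  // optimal

      vec dir;
      if (enter < p_)               dir =  Binv_ * X_.col(enter);
      else if (enter < 2 * p_)      dir = -(Binv_ * X_.col(enter - p_));
      else if (enter < 2 * p_ + n_) dir =  Binv_.col(enter - 2 * p_);
      else                          dir = -Binv_.col(enter - 2 * p_ - n_);

      // ratio test; ties broken toward the smallest basic column id
      int leave = -1;
      double theta = 0.0;
      for (int t = 0; t < n_; ++t) {
        if (dir[t] > tol) {
          const double r = xB_[t] / dir[t];
          if (leave < 0 || r < theta - tol ||
              (r < theta + tol && basis_[t] < basis_[leave])) {
            leave = t; theta = r;
          }
        }
      }
      if (leave < 0) return false;  // unbounded: impossible for LAD, bail out

      const double piv = dir[leave];
      Binv_.row(leave) /= piv;
      const double th = xB_[leave] / piv;
      for (int t = 0; t < n_; ++t) {
        if (t == leave) continue;
        const double f = dir[t];
        if (f != 0.0) {
          Binv_.row(t) -= f * Binv_.row(leave);
          xB_[t] -= f * th;
          if (xB_[t] < 0.0) xB_[t] = (xB_[t] > -1e-11) ? 0.0 : xB_[t];
        }
      }
      xB_[leave] = th;
      basis_[leave] = enter;
      cB_[leave] = (enter < 2 * p_) ? 0.0 : w_[(enter - 2 * p_) % n_];
    }
    return false;  // iteration cap hit
  }

  vec beta() const {
    vec b(p_, fill::zeros);
    for (int t = 0; t < n_; ++t) {
      if (basis_[t] < p_)           b[basis_[t]] += xB_[t];
      else if (basis_[t] < 2 * p_)  b[basis_[t] - p_] -= xB_[t];
    }
    return b;
  }

  int iterations() const { return iters_; }

private:
  const mat& X_;
  const vec& y_;
  const vec& w_;
  int n_, p_;
  mat Binv_;
  ivec basis_;
  vec xB_, cB_;
  int iters_ = 0;
};

// Fast path for the unweighted batch: an interpolation-set exchange
// algorithm. An optimal LAD fit interpolates p affinely independent
// observations; starting from any nonsingular p-subset, repeatedly move
// the fitted hyperplane along the edge that keeps p-1 interpolated points
// fixed, sliding past residual sign changes until the one-dimensional
// objective turns upward (a weighted-median step), and exchange the freed
// point for the one reached. The objective strictly decreases every
// exchange, so the method terminates at a vertex satisfying the L1
// optimality condition; on (numerically) pathological instances it signals
// failure and the caller falls back to the dense simplex.
static bool l1_exchange(const mat& X, const vec& y, const uvec& S0,
                        vec& beta_out, double& obj_out) {
  const int n = static_cast<int>(X.n_rows);
  const int p = static_cast<int>(X.n_cols);
  const double tolz = 1e-10;
  uvec S = S0;
  std::vector<char> inS(n, 0);
  for (int j = 0; j < p; ++j) inS[S[j]] = 1;
  mat XsInv;
  vec beta, r(n);
  std::vector<std::pair<double, int>> bp;
  const int maxit = 100 + 10 * n;
  for (int iter = 0; iter < maxit; ++iter) {
    const mat Xs = X.rows(S);
    if (!inv(XsInv, Xs)) return false;
    beta = XsInv * y(S);
    r = y - X * beta;
    const mat W = X * XsInv;  // column j: effect of freeing S[j]
    vec h(p, fill::zeros), z(p, fill::zeros);
    for (int i = 0; i < n; ++i) {
      if (inS[i]) continue;
      if (std::abs(r[i]) <= tolz) {
        for (int j = 0; j < p; ++j) z[j] += std::abs(W(i, j));
      } else {
        const double s = r[i] > 0 ? 1.0 : -1.0;
        for (int j = 0; j < p; ++j) h[j] += s * W(i, j);
      }
    }
    int jb = -1;
    double viol = 1e-9;
    for (int j = 0; j < p; ++j) {
      const double v = std::abs(h[j]) - 1.0 - z[j];
      if (v > viol) { viol = v; jb = j; }
    }
    if (jb < 0) {  // optimality: |h_j| <= 1 + z_j for all j
      beta_out = beta;
      obj_out = accu(abs(r));
      return true;
    }
    const double sigma = h[jb] > 0 ? 1.0 : -1.0;
    bp.clear();
    for (int i = 0; i < n; ++i) {
      if (inS[i] || std::abs(r[i]) <= tolz) continue;
      const double wi = sigma * W(i, jb);
      const double t = r[i] / wi;
      if (t > 0) bp.emplace_back(t, i);
    }
    if (bp.empty()) return false;  // unbounded edge: cannot happen for LAD
    std::sort(bp.begin(), bp.end());
    double slope = 1.0 + z[jb] - std::abs(h[jb]);
    int enter = -1;
    for (const auto& b : bp) {
      slope += 2.0 * std::abs(W(b.second, jb));
      enter = b.second;
      if (slope >= 0) break;
    }
    if (slope < 0) return false;
    inS[S[jb]] = 0;
    inS[enter] = 1;
    S[jb] = enter;
  }
  return false;
}

// greedy nonsingular p-subset of rows (shared across a batch: the design
// is common to all responses)
static bool init_subset(const mat& X, uvec& S) {
  const int n = static_cast<int>(X.n_rows);
  const int p = static_cast<int>(X.n_cols);
  S.set_size(p);
  mat acc(p, p);
  int got = 0;
  for (int i = 0; i < n && got < p; ++i) {
    acc.row(got) = X.row(i);
    if (arma::rank(acc.rows(0, got)) == got + 1) S[got++] = i;
  }
  return got == p;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".l1_fit_cpp")]]
Rcpp::List l1_fit_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::vec& w) {
  if (X.n_rows != y.n_elem || X.n_rows != w.n_elem)
    Rcpp::stop("l1 fit: X, y and w must have matching row counts");
  // uniform weights: the exchange algorithm is exact and much faster
  if (w.max() - w.min() < 1e-14 && w.min() > 0) {
    uvec S0;
    vec beta;
    double obj;
    if (init_subset(X, S0) && l1_exchange(X, y, S0, beta, obj))
      return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                                Rcpp::Named("objective") = w[0] * obj,
                                Rcpp::Named("iterations") = NA_INTEGER);
  }
  L1Simplex s(X, y, w);
  const int maxit = 400 * std::max<int>(static_cast<int>(X.n_rows), 10);
  if (!s.solve(maxit))
    Rcpp::stop("L1 simplex did not converge (n = %d, p = %d, iterations = %d)",
               static_cast<int>(X.n_rows), static_cast<int>(X.n_cols),
               s.iterations());
  const vec b = s.beta();
  const double obj = dot(w, abs(y - X * b));
  return Rcpp::List::create(Rcpp::Named("coefficients") = b,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = s.iterations());
}

// Batched unweighted LAD objectives for many response columns sharing one
// design; the workhorse of the permutation loop.
//' @noRd
// [[Rcpp::export(name = ".l1_obj_batch_cpp")]]
arma::vec l1_obj_batch_cpp(const arma::mat& X, const arma::mat& Y) {
  if (X.n_rows != Y.n_rows)
    Rcpp::stop("l1 batch: X and Y must have the same number of rows");
  const int m = static_cast<int>(Y.n_cols);
  const vec w(X.n_rows, fill::ones);
  const int maxit = 400 * std::max<int>(static_cast<int>(X.n_rows), 10);
  vec out(m);
  uvec S0;
  const bool haveInit = init_subset(X, S0);
  vec beta;
  double obj;
  for (int j = 0; j < m; ++j) {
    const vec yj = Y.col(j);
    if (haveInit && l1_exchange(X, yj, S0, beta, obj)) {
      out[j] = obj;
      continue;
    }
    L1Simplex s(X, yj, w);  // rigorous fallback
    if (!s.solve(maxit))
      Rcpp::stop("L1 simplex did not converge for response column %d", j + 1);
    out[j] = accu(abs(yj - X * s.beta()));
  }
  return out;
}
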