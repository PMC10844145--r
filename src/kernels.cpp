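// Computational kernels for the conditional-independence tests.
// Everything here is O(n^2) or worse and sits inside permutation loops,
// hence C++. All randomness goes through R's RNG so set.seed() in R
// governs reproducibility.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Distance correlation (V-statistic, double-centering form)
// ---------------------------------------------------------------------------

static arma::mat dist_centered(const arma::vec& x) {
  const int n = x.n_elem;
  arma::mat d(n, n);
  for (int i = 0; i < n; ++i) {
    d(i, i) = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double v = std::abs(x[i] - x[j]);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  arma::vec rm = arma::mean(d, 1);
  double gm = arma::mean(rm);
  d.each_col() -= rm;
  d.each_row() -= rm.t();
  d += gm;
  return d;
}

static double dcor_from_centered(const arma::mat& A, const arma::mat& B) {
  double dcov2 = arma::accu(A % B);
  double dvx = arma::accu(A % A);
  double dvy = arma::accu(B % B);
  if (dvx <= 0.0 || dvy <= 0.0) return 0.0;
  double r2 = dcov2 / std::sqrt(dvx * dvy);
  return r2 > 0.0 ? std::sqrt(r2) : 0.0;
}

// [[Rcpp::export]]
double dcor_stat_cpp(const arma::vec& x, const arma::vec& y) {
  return dcor_from_centered(dist_centered(x), dist_centered(y));
}

// Fill xp with x in block-shuffled order. starts: 1-based block start
// indices; block r spans starts[r]..(starts[r+1]-1). Block order drawn
// from R's RNG.
static void block_shuffle_fill(const arma::vec& x, const arma::ivec& starts,
                               arma::vec& xp) {
  const int nb = starts.n_elem;
  const int n = x.n_elem;
  IntegerVector ord(nb);
  for (int b = 0; b < nb; ++b) ord[b] = b;
  ord = sample(ord, nb, false);
  int pos = 0;
  for (int q = 0; q < nb; ++q) {
    int b = ord[q];
    int s = starts[b] - 1;
    int e = (b + 1 < nb) ? starts[b + 1] - 1 : n;
    for (int i = s; i < e; ++i) xp[pos++] = x[i];
  }
}

// Permutation distribution of dcor(x_shuffled, y) under block shuffling.
// [[Rcpp::export]]
arma::vec dcor_blockperm_cpp(const arma::vec& x, const arma::vec& y,
                             const arma::ivec& starts, const int n_perm) {
  arma::mat B = dist_centered(y);
  arma::vec out(n_perm), xp(x.n_elem);
  for (int r = 0; r < n_perm; ++r) {
    block_shuffle_fill(x, starts, xp);
    out[r] = dcor_from_centered(dist_centered(xp), B);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pearson correlation under block shuffling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::vec pearson_blockperm_cpp(const arma::vec& x, const arma::vec& y,
                                const arma::ivec& starts, const int n_perm) {
  const int n = x.n_elem;
  double my = arma::mean(y), sy = arma::stddev(y, 1);
  double mx = arma::mean(x), sx = arma::stddev(x, 1);
  arma::vec yc = (y - my);
  arma::vec out(n_perm), xp(n);
  for (int r = 0; r < n_perm; ++r) {
    block_shuffle_fill(x, starts, xp);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (xp[i] - mx) * yc[i];
    out[r] = s / (n * sx * sy);
  }
  return out;
}

// ---------------------------------------------------------------------------
// kNN conditional mutual information (Frenzel-Pompe / KSG, maximum norm)
// ---------------------------------------------------------------------------

// Max-norm distance between rows i and j over columns of M restricted by
// the helper's caller; M holds the coordinates of one subspace.
static inline double maxnorm(const arma::mat& M, int i, int j) {
  double m = 0.0;
  for (arma::uword c = 0; c < M.n_cols; ++c) {
    double v = std::abs(M(i, c) - M(j, c));
    if (v > m) m = v;
  }
  return m;
}

// x, y: n-vectors; z: n x dz matrix (dz may be 0). k: neighbour count.
// Returns the CMI estimate in nats.
// [[Rcpp::export]]
double cmi_knn_stat_cpp(const arma::vec& x, const arma::vec& y,
                        const arma::mat& z, const int k) {
  const int n = x.n_elem;
  const int dz = z.n_cols;
  arma::mat xz(n, 1 + dz), yz(n, 1 + dz);
  xz.col(0) = x;
  yz.col(0) = y;
  if (dz > 0) {
    xz.cols(1, dz) = z;
    yz.cols(1, dz) = z;
  }
  std::vector<double> d(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    // k-th smallest joint-space distance (self excluded)
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dj = maxnorm(xz, i, j);
      double vy = std::abs(y[i] - y[j]);
      if (vy > dj) dj = vy;
      d[m++] = dj;
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.begin() + m);
    double eps = d[k - 1];
    int nxz = 0, nyz = 0, nz = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dz_ij = 0.0;
      if (dz > 0) {
        for (int c = 0; c < dz; ++c) {
          double v = std::abs(z(i, c) - z(j, c));
          if (v > dz_ij) dz_ij = v;
        }
      }
      if (dz_ij < eps) {
        ++nz;
        double dx = std::abs(x[i] - x[j]);
        if (std::max(dx, dz_ij) < eps) ++nxz;
        double dy = std::abs(y[i] - y[j]);
        if (std::max(dy, dz_ij) < eps) ++nyz;
      }
    }
    acc += R::digamma(nxz + 1.0) + R::digamma(nyz + 1.0) - R::digamma(nz + 1.0);
  }
  return R::digamma((double)k) - acc / n;
}

// Nearest-neighbour lists in Z-space used by the local permutation scheme.
static arma::imat z_neighbours(const arma::mat& z, const int k_perm) {
  const int n = z.n_rows;
  arma::imat nb(n, k_perm);
  std::vector<std::pair<double, int> > d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) d[j] = std::make_pair(maxnorm(z, i, j), j);
    d[i].first = R_PosInf;  // exclude self
    std::partial_sort(d.begin(), d.begin() + k_perm, d.end());
    for (int q = 0; q < k_perm; ++q) nb(i, q) = d[q].second;
  }
  return nb;
}

// Local permutation null for the CMI statistic: X values are shuffled only
// among samples with nearby Z, preserving the X-Z dependence. With empty Z
// the null instead block-shuffles X (starts gives the block starts), so the
// serial dependence of the series is preserved under the null.
// [[Rcpp::export]]
arma::vec cmi_local_perm_cpp(const arma::vec& x, const arma::vec& y,
                             const arma::mat& z, const int k,
                             const int k_perm, const int n_perm,
                             const arma::ivec& starts) {
  const int n = x.n_elem;
  const int dz = z.n_cols;
  arma::vec out(n_perm);
  arma::imat nb;
  if (dz > 0) nb = z_neighbours(z, std::min(k_perm, n - 1));
  IntegerVector ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int r = 0; r < n_perm; ++r) {
    arma::vec xp(n);
    if (dz == 0) {
      block_shuffle_fill(x, starts, xp);
    } else {
      IntegerVector p = sample(ord, n, false);  // random visiting order
      std::vector<bool> used(n, false);
      const int kp = nb.n_cols;
      for (int q = 0; q < n; ++q) {
        int i = p[q];
        int start = (int)std::floor(unif_rand() * kp);
        int chosen = -1;
        for (int s = 0; s < kp; ++s) {
          int j = nb(i, (start + s) % kp);
          if (!used[j]) { chosen = j; break; }
        }
        if (chosen < 0) chosen = nb(i, start);  // all taken: reuse a neighbour
        else used[chosen] = true;
        xp[i] = x[chosen];
      }
    }
    out[r] = cmi_knn_stat_cpp(xp, y, z, k);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Gaussian-process regression, RBF + white-noise kernel
// ---------------------------------------------------------------------------

static arma::mat rbf_kernel(const arma::mat& Z, const double ls) {
  const int n = Z.n_rows;
  arma::mat K(n, n);
  const double inv2 = 1.0 / (2.0 * ls * ls);
  for (int i = 0; i < n; ++i) {
    K(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (arma::uword c = 0; c < Z.n_cols; ++c) {
        double v = Z(i, c) - Z(j, c);
        s += v * v;
      }
      double val = std::exp(-s * inv2);
      K(i, j) = val;
      K(j, i) = val;
    }
  }
  return K;
}

// Negative log marginal likelihood of y ~ GP(0, rbf(ls) + noise*I).
// theta = c(log(ls), log(noise_variance)); y standardized by the caller.
// [[Rcpp::export]]
double gp_nlml_cpp(const arma::vec& theta, const arma::mat& Z,
                   const arma::vec& y) {
  const int n = y.n_elem;
  const double ls = std::exp(theta[0]);
  const double nv = std::exp(theta[1]);
  arma::mat K = rbf_kernel(Z, ls);
  K.diag() += nv;
  arma::mat L;
  if (!arma::chol(L, K, "lower")) return 1e10;
  arma::vec a = arma::solve(arma::trimatl(L), y);
  double quad = arma::dot(a, a);
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  return 0.5 * (quad + logdet + n * std::log(2.0 * M_PI));
}

// Posterior-mean residuals y - K_f (K_f + nv I)^{-1} ... evaluated at the
// training points: residual = nv * (K + nv I)^{-1} y.
// [[Rcpp::export]]
arma::vec gp_residuals_cpp(const arma::vec& theta, const arma::mat& Z,
                           const arma::vec& y) {
  const double ls = std::exp(theta[0]);
  const double nv = std::exp(theta[1]);
  arma::mat K = rbf_kernel(Z, ls);
  K.diag() += nv;
  arma::vec alpha = arma::solve(K, y, arma::solve_opts::likely_sympd);
  return nv * alpha;
}
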