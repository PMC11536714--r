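// Gibbs sampler core for the multiple-trait animal model with
// data augmentation of missing records.
//
// Scan order per iteration (fixed, for reproducibility):
//   1. missing records y_i^M | y_i^O, b, u, R
//   2. fixed-effect columns b_k (one multivariate block per design column)
//   3. breeding values u_i, i = 1..s in pedigree order
//   4. G ~ IW(U'A^-1 U + S0g, s + nu0g)
//   5. R ~ IW(E'E + S0r, n + nu0r)
// All draws use R's RNG so a set.seed() on the R side makes the whole
// chain bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uvec;
using arma::uword;

static mat chol_jitter(const mat& P, const char* what, int iter) {
  mat U;
  if (arma::chol(U, P)) return U;
  double j = 1e-8 * arma::trace(P) / P.n_rows;
  mat Pj = P + j * arma::eye(P.n_rows, P.n_cols);
  if (arma::chol(U, Pj)) return U;
  stop("non-positive-definite %s update at iteration %d", what, iter);
  return U; // unreached
}

static vec rnorm_vec(uword m) {
  vec z(m);
  for (uword i = 0; i < m; ++i) z(i) = R::rnorm(0.0, 1.0);
  return z;
}

// Draw from N(P^-1 rhs, P^-1)
static vec mvn_prec(const mat& P, const vec& rhs, const char* what, int iter) {
  mat U = chol_jitter(P, what, iter);
  vec mu = arma::solve(arma::trimatu(U),
                       arma::solve(arma::trimatl(U.t()), rhs));
  return mu + arma::solve(arma::trimatu(U), rnorm_vec(P.n_rows));
}

// Inverse-Wishart draw via Bartlett decomposition of the Wishart on S^-1.
static mat riwish_cpp(double df, const mat& S, int iter) {
  uword m = S.n_rows;
  mat Sinv = arma::inv_sympd(arma::symmatu(S));
  mat L = arma::chol(Sinv, "lower");
  mat A(m, m, arma::fill::zeros);
  for (uword i = 0; i < m; ++i) {
    for (uword j = 0; j < i; ++j) A(i, j) = R::rnorm(0.0, 1.0);
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
  }
  mat LA = L * A;
  mat W = LA * LA.t();
  mat out;
  if (!arma::inv_sympd(out, W)) {
    W += 1e-10 * arma::trace(W) / m * arma::eye(m, m);
    if (!arma::inv_sympd(out, W))
      stop("singular inverse-Wishart draw at iteration %d", iter);
  }
  return arma::symmatu(out);
}

// Conditional N(mean, cov) of y[mis] given y[obs] under y ~ N(mu, R).
static void cond_moments(const mat& R, const rowvec& y, const rowvec& mu,
                         const uvec& obs, const uvec& mis,
                         vec& cmean, mat& ccov) {
  mat Roo = R.submat(obs, obs);
  mat Rqo = R.submat(mis, obs);
  mat Rqq = R.submat(mis, mis);
  vec dev = y.elem(obs) - mu.elem(obs);
  mat K = arma::solve(Roo, Rqo.t());      // Roo^-1 Roq
  cmean = mu.elem(mis) + K.t() * dev;
  ccov = arma::symmatu(Rqq - Rqo * K);
}

// [[Rcpp::export]]
List cpp_cond_moments(const arma::mat& R, const arma::rowvec& mu,
                      const arma::rowvec& y, const arma::uvec& observed) {
  uvec obs = arma::find(observed == 1);
  uvec mis = arma::find(observed == 0);
  if (obs.n_elem == 0) stop("record has no observed trait");
  vec cmean; mat ccov;
  cond_moments(R, y, mu, obs, mis, cmean, ccov);
  return List::create(_["mean"] = cmean, _["cov"] = ccov);
}

// [[Rcpp::export]]
List cpp_mtm_gibbs(arma::mat Y, const arma::umat& OBS, const arma::mat& X,
                   const List& coef_traits, const arma::ivec& rec_of,
                   const arma::sp_mat& Ainv,
                   arma::mat G, arma::mat R,
                   double nu_g, const arma::mat& Sg,
                   double nu_r, const arma::mat& Sr,
                   int n_iter, int burn_in, int thin,
                   bool update_miss, bool update_b, bool update_g, bool update_r,
                   arma::mat b, arma::mat U,
                   int verbose) {
  const uword n = Y.n_rows, m = Y.n_cols, p = X.n_cols, s = Ainv.n_rows;
  if (U.n_rows != s || U.n_cols != m) stop("bad u dimensions");
  if (b.n_rows != p || b.n_cols != m) stop("bad b dimensions");

  // per-column trait index sets (0-based) and sums of squares
  std::vector<uvec> tk(p);
  vec sxx(p);
  for (uword k = 0; k < p; ++k) {
    tk[k] = as<uvec>(coef_traits[k]) - 1;
    sxx(k) = arma::dot(X.col(k), X.col(k));
  }

  // individual -> record row (-1 = no record)
  arma::ivec ind_rec(s); ind_rec.fill(-1);
  for (uword r = 0; r < n; ++r) {
    int i = rec_of(r) - 1;
    if (i < 0 || i >= (int)s) stop("record individual out of range");
    ind_rec(i) = r;
  }

  // missing-trait index cache per record
  std::vector<uvec> obs_idx(n), mis_idx(n);
  for (uword r = 0; r < n; ++r) {
    obs_idx[r] = arma::find(OBS.row(r).t() == 1);
    mis_idx[r] = arma::find(OBS.row(r).t() == 0);
    if (obs_idx[r].n_elem == 0) stop("record %d has no observed trait", (int)r + 1);
  }

  mat Ginv = arma::inv_sympd(arma::symmatu(G));
  mat Rinv = arma::inv_sympd(arma::symmatu(R));

  // complete-data residuals E = Y - Xb - u
  mat E(n, m);
  {
    mat Xb(n, m, arma::fill::zeros);
    for (uword k = 0; k < p; ++k)
      Xb.cols(tk[k]) += X.col(k) * b.submat(uvec{k}, tk[k]);
    for (uword r = 0; r < n; ++r)
      E.row(r) = Y.row(r) - Xb.row(r) - U.row(rec_of(r) - 1);
  }

  const int n_keep = (thin > 0) ? (n_iter - burn_in) / thin : 0;
  const uword ntri = m * (m + 1) / 2;
  mat G_samp(std::max(n_keep, 0), ntri), R_samp(std::max(n_keep, 0), ntri);
  mat b_mean(p, m, arma::fill::zeros), u_mean(s, m, arma::fill::zeros);
  int kept = 0, mean_n = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // -- 1. augment missing records ------------------------------------
    if (update_miss) {
      for (uword r = 0; r < n; ++r) {
        const uvec& q = mis_idx[r];
        if (q.n_elem == 0) continue;
        rowvec mu = Y.row(r) - E.row(r);
        vec cmean; mat ccov;
        cond_moments(R, Y.row(r), mu, obs_idx[r], q, cmean, ccov);
        mat Uc = chol_jitter(ccov, "augmentation", it);
        vec draw = cmean + Uc.t() * rnorm_vec(q.n_elem);
        for (uword l = 0; l < q.n_elem; ++l) {
          Y(r, q(l)) = draw(l);
          E(r, q(l)) = draw(l) - mu(q(l));
        }
      }
    }

    // -- 2. fixed effects, one block per design column ------------------
    if (update_b) for (uword k = 0; k < p; ++k) {
      const uvec& T = tk[k];
      vec bold = b.submat(uvec{k}, T).t();
      vec full = Rinv * (E.t() * X.col(k));      // m-vector
      mat P = sxx(k) * Rinv.submat(T, T);
      vec rhs = full.elem(T) + P * bold;
      vec bnew = mvn_prec(P, rhs, "fixed-effect", it);
      b.submat(uvec{k}, T) = bnew.t();
      E.cols(T) -= X.col(k) * (bnew - bold).t();
    }

    // -- 3. breeding values --------------------------------------------
    vec v(m);
    for (uword i = 0; i < s; ++i) {
      v.zeros();
      double aii = 0.0;
      for (arma::sp_mat::const_col_iterator ci = Ainv.begin_col(i);
           ci != Ainv.end_col(i); ++ci) {
        const uword j = ci.row();
        const double a = *ci;
        if (j == i) aii = a;
        else for (uword t = 0; t < m; ++t) v(t) += a * U(j, t);
      }
      mat P = aii * Ginv;
      vec rhs = -(Ginv * v);
      int r = ind_rec(i);
      vec etil;
      if (r >= 0) {
        etil = E.row(r).t() + U.row(i).t();
        P += Rinv;
        rhs += Rinv * etil;
      }
      vec unew = mvn_prec(P, rhs, "breeding-value", it);
      U.row(i) = unew.t();
      if (r >= 0) E.row(r) = (etil - unew).t();
    }

    // -- 4. genetic covariances ----------------------------------------
    if (update_g) {
      mat S = Sg;
      for (uword j = 0; j < s; ++j) {
        for (arma::sp_mat::const_col_iterator ci = Ainv.begin_col(j);
             ci != Ainv.end_col(j); ++ci) {
          const uword i2 = ci.row();
          const double a = *ci;
          for (uword t2 = 0; t2 < m; ++t2) {
            const double aj = a * U(j, t2);
            for (uword t1 = 0; t1 < m; ++t1) S(t1, t2) += aj * U(i2, t1);
          }
        }
      }
      G = riwish_cpp((double)s + nu_g, arma::symmatu(S), it);
      Ginv = arma::inv_sympd(G);
    }

    // -- 5. residual covariances ---------------------------------------
    if (update_r) {
      mat S = Sr + E.t() * E;
      R = riwish_cpp((double)n + nu_r, arma::symmatu(S), it);
      Rinv = arma::inv_sympd(R);
    }

    if (it > burn_in) {
      b_mean += b; u_mean += U; ++mean_n;
      if (thin > 0 && (it - burn_in) % thin == 0 && kept < n_keep) {
        uword c = 0;
        for (uword j2 = 0; j2 < m; ++j2)
          for (uword i2 = 0; i2 <= j2; ++i2, ++c) {
            G_samp(kept, c) = G(i2, j2);
            R_samp(kept, c) = R(i2, j2);
          }
        ++kept;
      }
    }
    if (verbose > 0 && it % verbose == 0) {
      Rcout << "iter " << it << "  diag(G): " << G.diag().t()
            << "        diag(R): " << R.diag().t();
    }
    if (it % 256 == 0) checkUserInterrupt();
  }
  if (mean_n > 0) { b_mean /= mean_n; u_mean /= mean_n; }

  return List::create(
    _["G"] = G_samp.head_rows(kept),
    _["R"] = R_samp.head_rows(kept),
    _["n_kept"] = kept,
    _["b_mean"] = b_mean,
    _["u_mean"] = u_mean,
    _["state"] = List::create(_["b"] = b, _["u"] = U, _["G"] = G,
                              _["R"] = R, _["Y"] = Y));
}

// [[Rcpp::export]]
arma::mat cpp_riwish(double df, const arma::mat& S) {
  return riwish_cpp(df, S, 0);
}
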