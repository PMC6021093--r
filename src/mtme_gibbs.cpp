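// Gibbs sampler core for the multi-trait multi-environment mixed model
//
//   y = X beta + Z1 r + Z2 b + Z3 u + e
//
// with u ~ N(0, I (x) Sigma_u) over trait-by-environment combinations and
// r, b, e carrying per-environment trait covariance matrices (replicates,
// blocks and plots are nested in environment, so cross-environment cells of
// those structures do not exist).  All location effects are updated in one
// Gaussian block by solving the mixed-model equations; covariance matrices
// are updated from their inverse-Wishart full conditionals; missing trait
// observations are handled by data augmentation.  Uses R's RNG throughout so
// set.seed() on the R side makes a chain reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat symm(const arma::mat& A) { return 0.5 * (A + A.t()); }

// Upper Cholesky with escalating diagonal jitter; counts repairs.
static arma::mat chol_upper_safe(const arma::mat& C, int& n_repair) {
  arma::mat U;
  double base = 1e-10 * arma::trace(C) / C.n_rows;
  if (!(base > 0)) base = 1e-12;
  for (int attempt = 0; attempt < 8; ++attempt) {
    arma::mat Cj = symm(C);
    if (attempt > 0) {
      Cj.diag() += base * std::pow(10.0, attempt - 1);
    }
    if (arma::chol(U, Cj)) {
      if (attempt > 0) ++n_repair;
      return U;
    }
  }
  stop("Cholesky of the location-effect coefficient matrix failed even after jitter repair; the system is numerically singular");
}

// One draw Sigma ~ InvWishart(nu, S)  (i.e. Sigma^{-1} ~ Wishart(nu, S^{-1})),
// by the Bartlett decomposition, using R's RNG.
static arma::mat rinvwishart(double nu, const arma::mat& S, int& n_repair) {
  const int p = S.n_rows;
  arma::mat Sj = symm(S);
  arma::mat Sinv;
  if (!arma::inv_sympd(Sinv, Sj)) {
    Sj.diag() += 1e-10 * arma::trace(Sj) / p;
    Sinv = arma::inv(Sj);
    ++n_repair;
  }
  arma::mat L = arma::chol(symm(Sinv), "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat W = symm(LA * LA.t());
  arma::mat Sig;
  if (!arma::inv_sympd(Sig, W)) {
    W.diag() += 1e-10 * arma::trace(W) / p;
    Sig = arma::inv(W);
    ++n_repair;
  }
  return symm(Sig);
}

// Observed-data conditional Gaussian deviance:
//   D = sum_plots [ m log(2 pi) + log|S_oo| + e_o' S_oo^{-1} e_o ]
// where o indexes the observed traits of a plot and S is that environment's
// residual covariance.
static double cond_deviance(const arma::mat& Y, const arma::imat& obs,
                            const arma::ivec& env, const arma::mat& Fit,
                            const std::vector<arma::mat>& Sig_e) {
  const int n = Y.n_rows, K = Y.n_cols;
  const int E = (int)Sig_e.size();
  const double l2pi = std::log(2.0 * M_PI);
  // cache logdet/inverse per (environment, missingness pattern)
  std::vector<std::vector<arma::mat>> inv_cache(E, std::vector<arma::mat>(1 << K));
  std::vector<std::vector<double>> ld_cache(E, std::vector<double>(1 << K));
  std::vector<std::vector<bool>> ready(E, std::vector<bool>(1 << K, false));
  double D = 0.0;
  for (int p = 0; p < n; ++p) {
    int mask = 0, m = 0;
    for (int t = 0; t < K; ++t) if (obs(p, t)) { mask |= (1 << t); ++m; }
    if (m == 0) continue;
    const int e = env(p) - 1;
    if (!ready[e][mask]) {
      arma::uvec o(m);
      int j = 0;
      for (int t = 0; t < K; ++t) if (mask & (1 << t)) o(j++) = t;
      arma::mat Soo = Sig_e[e](o, o);
      double ld, sign;
      arma::log_det(ld, sign, Soo);
      inv_cache[e][mask] = arma::inv_sympd(symm(Soo));
      ld_cache[e][mask] = ld;
      ready[e][mask] = true;
    }
    arma::vec eo(m);
    int j = 0;
    for (int t = 0; t < K; ++t)
      if (mask & (1 << t)) eo(j++) = Y(p, t) - Fit(p, t);
    D += m * l2pi + ld_cache[e][mask] +
         arma::as_scalar(eo.t() * inv_cache[e][mask] * eo);
  }
  return D;
}

// [[Rcpp::export]]
List mtme_gibbs_cpp(const arma::mat& Y, const arma::imat& obs,
                    const arma::ivec& env, const arma::ivec& rep,
                    const arma::ivec& blk, const arma::ivec& gen,
                    const arma::ivec& env_of_rep, const arma::ivec& env_of_blk,
                    bool full_model, int n_env,
                    List prior, List init,
                    int n_iter, int burn_in, int thin,
                    bool keep_u, bool has_rep, bool has_blk, bool has_gen) {
  const int n = Y.n_rows;
  const int K = Y.n_cols;
  const int E = n_env;
  const int G = has_gen ? (int)gen.max() : 0;
  const int nrep = has_rep ? (int)env_of_rep.n_elem : 0;
  const int nblk = has_blk ? (int)env_of_blk.n_elem : 0;
  const int d_u = full_model ? K * E : K;
  const int off_r = K * E;
  const int off_b = off_r + nrep * K;
  const int off_u = off_b + nblk * K;
  const int q = off_u + (has_gen ? G * d_u : 0);
  int n_repair = 0;

  // priors
  const double beta_var = as<double>(prior["beta_var"]);
  double nu_u = 0; arma::mat S_u;
  if (has_gen) { nu_u = as<double>(prior["nu_u"]); S_u = as<arma::mat>(prior["S_u"]); }
  double nu_r = 0, nu_b = 0;
  const double nu_e = as<double>(prior["nu_e"]);
  std::vector<arma::mat> S_r(E), S_b(E), S_e(E);
  {
    List Se = prior["S_e"];
    for (int e = 0; e < E; ++e) S_e[e] = as<arma::mat>(Se[e]);
    if (has_rep) {
      nu_r = as<double>(prior["nu_r"]);
      List Sr = prior["S_r"];
      for (int e = 0; e < E; ++e) S_r[e] = as<arma::mat>(Sr[e]);
    }
    if (has_blk) {
      nu_b = as<double>(prior["nu_b"]);
      List Sb = prior["S_b"];
      for (int e = 0; e < E; ++e) S_b[e] = as<arma::mat>(Sb[e]);
    }
  }

  // state initialisation
  arma::mat Sig_u;
  if (has_gen) Sig_u = as<arma::mat>(init["Sigma_u"]);
  std::vector<arma::mat> Sig_r(E), Sig_b(E), Sig_e(E);
  {
    List Se = init["Sigma_e"];
    for (int e = 0; e < E; ++e) Sig_e[e] = as<arma::mat>(Se[e]);
    if (has_rep) { List Sr = init["Sigma_r"]; for (int e = 0; e < E; ++e) Sig_r[e] = as<arma::mat>(Sr[e]); }
    if (has_blk) { List Sb = init["Sigma_b"]; for (int e = 0; e < E; ++e) Sig_b[e] = as<arma::mat>(Sb[e]); }
  }
  arma::vec beta0 = as<arma::vec>(init["beta"]); // length K*E, combo order t*E+e
  arma::vec theta(q, arma::fill::zeros);
  theta.subvec(0, K * E - 1) = beta0;
  arma::mat Ystar = Y;
  for (int p = 0; p < n; ++p)
    for (int t = 0; t < K; ++t)
      if (!obs(p, t)) Ystar(p, t) = beta0(t * E + (env(p) - 1));

  // per-environment level counts
  arma::ivec n_rep_e(E, arma::fill::zeros), n_blk_e(E, arma::fill::zeros),
      n_plot_e(E, arma::fill::zeros);
  for (int l = 0; l < nrep; ++l) n_rep_e(env_of_rep(l) - 1)++;
  for (int l = 0; l < nblk; ++l) n_blk_e(env_of_blk(l) - 1)++;
  for (int p = 0; p < n; ++p) n_plot_e(env(p) - 1)++;

  // column index cache: cols(p, 4*t + slot), slot 0..3 = beta, rep, blk, gen
  arma::imat cols(n, 4 * K);
  for (int p = 0; p < n; ++p) {
    const int e = env(p) - 1;
    for (int t = 0; t < K; ++t) {
      cols(p, 4 * t + 0) = t * E + e;
      cols(p, 4 * t + 1) = has_rep ? off_r + (rep(p) - 1) * K + t : -1;
      cols(p, 4 * t + 2) = has_blk ? off_b + (blk(p) - 1) * K + t : -1;
      cols(p, 4 * t + 3) = has_gen
        ? off_u + (gen(p) - 1) * d_u + (full_model ? t * E + e : t) : -1;
    }
  }

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  arma::mat beta_draws(n_keep, K * E);
  arma::mat su_draws(n_keep, has_gen ? d_u * d_u : 1);
  std::vector<arma::mat> sr_draws, sb_draws, se_draws;
  for (int e = 0; e < E; ++e) {
    se_draws.push_back(arma::mat(n_keep, K * K));
    if (has_rep) sr_draws.push_back(arma::mat(n_keep, K * K));
    if (has_blk) sb_draws.push_back(arma::mat(n_keep, K * K));
  }
  arma::mat u_draws((keep_u && has_gen) ? n_keep : 0, has_gen ? G * d_u : 1);
  arma::vec dev_draws(n_keep);
  arma::vec theta_mean(q, arma::fill::zeros);
  std::vector<arma::mat> se_mean(E, arma::mat(K, K, arma::fill::zeros));

  arma::mat C(q, q);
  arma::vec rhs(q), z(q);
  arma::mat Fit(n, K);

  for (int it = 1; it <= n_iter; ++it) {
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();

    // --- location block: theta | covariances, ystar -------------------
    std::vector<arma::mat> Rinv(E);
    for (int e = 0; e < E; ++e) Rinv[e] = arma::inv_sympd(symm(Sig_e[e]));

    C.zeros();
    rhs.zeros();
    for (int j = 0; j < K * E; ++j) C(j, j) = 1.0 / beta_var;
    if (has_rep) {
      std::vector<arma::mat> Srinv(E);
      for (int e = 0; e < E; ++e) Srinv[e] = arma::inv_sympd(symm(Sig_r[e]));
      for (int l = 0; l < nrep; ++l)
        C.submat(off_r + l * K, off_r + l * K, off_r + l * K + K - 1,
                 off_r + l * K + K - 1) += Srinv[env_of_rep(l) - 1];
    }
    if (has_blk) {
      std::vector<arma::mat> Sbinv(E);
      for (int e = 0; e < E; ++e) Sbinv[e] = arma::inv_sympd(symm(Sig_b[e]));
      for (int l = 0; l < nblk; ++l)
        C.submat(off_b + l * K, off_b + l * K, off_b + l * K + K - 1,
                 off_b + l * K + K - 1) += Sbinv[env_of_blk(l) - 1];
    }
    if (has_gen) {
      arma::mat Su_inv = arma::inv_sympd(symm(Sig_u));
      for (int g = 0; g < G; ++g)
        C.submat(off_u + g * d_u, off_u + g * d_u, off_u + g * d_u + d_u - 1,
                 off_u + g * d_u + d_u - 1) += Su_inv;
    }
    for (int p = 0; p < n; ++p) {
      const arma::mat& Ri = Rinv[env(p) - 1];
      for (int t1 = 0; t1 < K; ++t1) {
        for (int s1 = 0; s1 < 4; ++s1) {
          const int c1 = cols(p, 4 * t1 + s1);
          if (c1 < 0) continue;
          for (int t2 = 0; t2 < K; ++t2) {
            const double rv = Ri(t1, t2);
            rhs(c1) += rv * Ystar(p, t2);
            for (int s2 = 0; s2 < 4; ++s2) {
              const int c2 = cols(p, 4 * t2 + s2);
              if (c2 >= 0) C(c1, c2) += rv;
            }
          }
        }
      }
    }
    arma::mat U = chol_upper_safe(C, n_repair);
    for (int j = 0; j < q; ++j) z(j) = R::norm_rand();
    arma::vec w = arma::solve(arma::trimatl(U.t()), rhs);
    theta = arma::solve(arma::trimatu(U), w + z);

    // fitted values
    for (int p = 0; p < n; ++p)
      for (int t = 0; t < K; ++t) {
        double f = 0.0;
        for (int s = 0; s < 4; ++s) {
          const int c = cols(p, 4 * t + s);
          if (c >= 0) f += theta(c);
        }
        Fit(p, t) = f;
      }

    // --- data augmentation of missing trait observations --------------
    for (int p = 0; p < n; ++p) {
      int nmiss = 0;
      for (int t = 0; t < K; ++t) if (!obs(p, t)) ++nmiss;
      if (nmiss == 0) continue;
      const int e = env(p) - 1;
      arma::uvec om(K - nmiss), mm(nmiss);
      int jo = 0, jm = 0;
      for (int t = 0; t < K; ++t) {
        if (obs(p, t)) om(jo++) = t; else mm(jm++) = t;
      }
      arma::vec draw;
      if (jo == 0) {
        arma::mat L = arma::chol(symm(Sig_e[e]), "lower");
        arma::vec zz(K);
        for (int t = 0; t < K; ++t) zz(t) = R::norm_rand();
        draw = L * zz;
      } else {
        arma::mat Soo = Sig_e[e](om, om);
        arma::mat Smo = Sig_e[e](mm, om);
        arma::mat Smm = Sig_e[e](mm, mm);
        arma::vec eo(jo);
        for (int j = 0; j < jo; ++j) eo(j) = Y(p, om(j)) - Fit(p, om(j));
        arma::mat SooInv = arma::inv_sympd(symm(Soo));
        arma::vec cmean = Smo * SooInv * eo;
        arma::mat ccov = symm(Smm - Smo * SooInv * Smo.t());
        arma::mat L;
        if (!arma::chol(L, ccov, "lower")) {
          ccov.diag() += 1e-12 + 1e-10 * arma::trace(ccov) / ccov.n_rows;
          L = arma::chol(ccov, "lower");
          ++n_repair;
        }
        arma::vec zz(jm);
        for (int j = 0; j < jm; ++j) zz(j) = R::norm_rand();
        draw = cmean + L * zz;
      }
      for (int j = 0; j < jm; ++j) Ystar(p, mm(j)) = Fit(p, mm(j)) + draw(j);
    }

    // --- covariance blocks --------------------------------------------
    if (has_gen) {
      arma::mat Ueff(G, d_u);
      for (int g = 0; g < G; ++g)
        for (int c = 0; c < d_u; ++c) Ueff(g, c) = theta(off_u + g * d_u + c);
      Sig_u = rinvwishart(nu_u + G, symm(S_u + Ueff.t() * Ueff), n_repair);
    }
    if (has_rep) {
      for (int e = 0; e < E; ++e) {
        arma::mat sc(K, K, arma::fill::zeros);
        for (int l = 0; l < nrep; ++l) {
          if (env_of_rep(l) - 1 != e) continue;
          arma::vec v(K);
          for (int t = 0; t < K; ++t) v(t) = theta(off_r + l * K + t);
          sc += v * v.t();
        }
        Sig_r[e] = rinvwishart(nu_r + n_rep_e(e), symm(S_r[e] + sc), n_repair);
      }
    }
    if (has_blk) {
      for (int e = 0; e < E; ++e) {
        arma::mat sc(K, K, arma::fill::zeros);
        for (int l = 0; l < nblk; ++l) {
          if (env_of_blk(l) - 1 != e) continue;
          arma::vec v(K);
          for (int t = 0; t < K; ++t) v(t) = theta(off_b + l * K + t);
          sc += v * v.t();
        }
        Sig_b[e] = rinvwishart(nu_b + n_blk_e(e), symm(S_b[e] + sc), n_repair);
      }
    }
    for (int e = 0; e < E; ++e) {
      arma::mat sc(K, K, arma::fill::zeros);
      for (int p = 0; p < n; ++p) {
        if (env(p) - 1 != e) continue;
        arma::vec v(K);
        for (int t = 0; t < K; ++t) v(t) = Ystar(p, t) - Fit(p, t);
        sc += v * v.t();
      }
      Sig_e[e] = rinvwishart(nu_e + n_plot_e(e), symm(S_e[e] + sc), n_repair);
    }

    // --- retention -----------------------------------------------------
    if (it > burn_in && (it - burn_in) % thin == 0) {
      const int k = (it - burn_in) / thin - 1;
      if (k < n_keep) {
        beta_draws.row(k) = theta.subvec(0, K * E - 1).t();
        if (has_gen) su_draws.row(k) = arma::vectorise(Sig_u).t();
        for (int e = 0; e < E; ++e) {
          se_draws[e].row(k) = arma::vectorise(Sig_e[e]).t();
          if (has_rep) sr_draws[e].row(k) = arma::vectorise(Sig_r[e]).t();
          if (has_blk) sb_draws[e].row(k) = arma::vectorise(Sig_b[e]).t();
        }
        if (keep_u && has_gen)
          u_draws.row(k) = theta.subvec(off_u, q - 1).t();
        dev_draws(k) = cond_deviance(Y, obs, env, Fit, Sig_e);
        theta_mean += theta;
        for (int e = 0; e < E; ++e) se_mean[e] += Sig_e[e];
      }
    }
  }

  double dev_at_mean = NA_REAL;
  if (n_keep > 0) {
    theta_mean /= n_keep;
    for (int e = 0; e < E; ++e) se_mean[e] /= n_keep;
    arma::mat FitM(n, K);
    for (int p = 0; p < n; ++p)
      for (int t = 0; t < K; ++t) {
        double f = 0.0;
        for (int s = 0; s < 4; ++s) {
          const int c = cols(p, 4 * t + s);
          if (c >= 0) f += theta_mean(c);
        }
        FitM(p, t) = f;
      }
    dev_at_mean = cond_deviance(Y, obs, env, FitM, se_mean);
  }

  List sr_out(E), sb_out(E), se_out(E), se_mean_out(E);
  for (int e = 0; e < E; ++e) {
    se_out[e] = se_draws[e];
    se_mean_out[e] = se_mean[e];
    if (has_rep) sr_out[e] = sr_draws[e];
    if (has_blk) sb_out[e] = sb_draws[e];
  }

  return List::create(
      _["beta"] = beta_draws, _["Sigma_u"] = su_draws, _["Sigma_r"] = sr_out,
      _["Sigma_b"] = sb_out, _["Sigma_e"] = se_out, _["u"] = u_draws,
      _["deviance"] = dev_draws, _["dev_at_mean"] = dev_at_mean,
      _["theta_mean"] = theta_mean, _["Sigma_e_mean"] = se_mean_out,
      _["n_keep"] = n_keep, _["n_psd_repair"] = n_repair,
      _["offsets"] = IntegerVector::create(_["off_r"] = off_r,
                                           _["off_b"] = off_b,
                                           _["off_u"] = off_u, _["q"] = q,
                                           _["d_u"] = d_u));
}
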