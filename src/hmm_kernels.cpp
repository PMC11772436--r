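// Core hidden-Markov computations: state-conditional Gaussian log densities
// with missing data, scaled forward filtering, forward-filtering
// backward-sampling (FFBS), Viterbi decoding, and the per-patient Gibbs
// sweep of the multilevel sampler. All random draws use R's RNG so runs
// are replayable bit-exactly from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727;

// Stationary distribution of a row-stochastic matrix; falls back to power
// iteration when the linear system is near-singular.
static arma::vec stationary_dist(const arma::mat& G) {
  const int m = G.n_rows;
  if (m == 1) return arma::ones(1);
  arma::mat A = arma::eye(m, m) - G.t();
  A.row(m - 1) = arma::ones<arma::rowvec>(m);
  arma::vec b = arma::zeros(m);
  b(m - 1) = 1.0;
  arma::vec pi;
  bool ok = arma::solve(pi, A, b, arma::solve_opts::no_approx);
  if (!ok || !pi.is_finite() || pi.min() < -1e-8) {
    pi = arma::ones(m) / m;
    for (int it = 0; it < 500; ++it) pi = G.t() * pi;
  }
  pi = arma::clamp(pi, 1e-12, 1.0);
  return pi / arma::accu(pi);
}

// Row softmax over (0, alpha_row): reference category is column 1.
static arma::mat gamma_from_alpha(const arma::mat& alpha, const int m) {
  arma::mat G(m, m);
  if (m == 1) { G(0, 0) = 1.0; return G; }
  for (int s = 0; s < m; ++s) {
    arma::rowvec z(m);
    z(0) = 0.0;
    for (int j = 1; j < m; ++j) z(j) = alpha(s, j - 1);
    const double mx = z.max();
    arma::rowvec e = arma::exp(z - mx);
    G.row(s) = e / arma::accu(e);
  }
  return G;
}

// T x m matrix of log emission densities; NaN (R NA) entries are skipped,
// so a fully missing occasion contributes 0 to every state.
static arma::mat emission_logdens(const arma::mat& y, const arma::mat& mu,
                                  const arma::mat& sig) {
  const int T = y.n_rows, K = y.n_cols, m = mu.n_rows;
  arma::mat ld(T, m, arma::fill::zeros);
  arma::mat lsig = arma::log(sig);
  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      const double v = y(t, k);
      if (std::isnan(v)) continue;
      for (int s = 0; s < m; ++s) {
        const double z = (v - mu(s, k)) / sig(s, k);
        ld(t, s) += -LOG_SQRT_2PI - lsig(s, k) - 0.5 * z * z;
      }
    }
  }
  return ld;
}

// Scaled forward recursion. Fills filt (T x m, normalized filtered state
// probabilities) and returns the exact marginal log-likelihood.
static double forward_filter(const arma::mat& ld, const arma::mat& G,
                             const arma::vec& pi, arma::mat& filt) {
  const int T = ld.n_rows, m = ld.n_cols;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    const double mx = ld.row(t).max();
    arma::rowvec e = arma::exp(ld.row(t) - mx);
    arma::rowvec pred = (t == 0) ? pi.t() : arma::rowvec(filt.row(t - 1) * G);
    arma::rowvec a = pred % e;
    const double c = arma::accu(a);
    if (!(c > 0.0) || !std::isfinite(c))
      stop("forward filtering underflow at occasion %d", t + 1);
    filt.row(t) = a / c;
    ll += std::log(c) + mx;
  }
  return ll;
}

static int sample_cat(const arma::rowvec& p) {
  const double u = unif_rand() * arma::accu(p);
  double cs = 0.0;
  for (int s = 0; s < (int)p.n_elem; ++s) {
    cs += p(s);
    if (u <= cs) return s;
  }
  return p.n_elem - 1;
}

// One exact draw from P(S_1..T | y, params). 0-based states.
static arma::ivec ffbs_draw(const arma::mat& ld, const arma::mat& G,
                            const arma::vec& pi) {
  const int T = ld.n_rows;
  arma::mat filt(T, ld.n_cols);
  forward_filter(ld, G, pi, filt);
  arma::ivec S(T);
  S(T - 1) = sample_cat(filt.row(T - 1));
  for (int t = T - 2; t >= 0; --t) {
    arma::rowvec w = filt.row(t) % G.col(S(t + 1)).t();
    S(t) = sample_cat(w);
  }
  return S;
}

// Joint-MAP path; ties broken toward the lower state index (strict >).
static arma::ivec viterbi_path(const arma::mat& ld, const arma::mat& G,
                               const arma::vec& pi) {
  const int T = ld.n_rows, m = ld.n_cols;
  arma::mat lG = arma::log(G + 1e-300);
  arma::mat delta(T, m);
  arma::imat psi(T, m, arma::fill::zeros);
  for (int s = 0; s < m; ++s)
    delta(0, s) = std::log(pi(s) + 1e-300) + ld(0, s);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < m; ++s) {
      int best = 0;
      double bv = delta(t - 1, 0) + lG(0, s);
      for (int r = 1; r < m; ++r) {
        const double v = delta(t - 1, r) + lG(r, s);
        if (v > bv) { bv = v; best = r; }
      }
      delta(t, s) = bv + ld(t, s);
      psi(t, s) = best;
    }
  }
  arma::ivec S(T);
  int best = 0;
  double bv = delta(T - 1, 0);
  for (int s = 1; s < m; ++s)
    if (delta(T - 1, s) > bv) { bv = delta(T - 1, s); best = s; }
  S(T - 1) = best;
  for (int t = T - 2; t >= 0; --t) S(t) = psi(t + 1, S(t + 1));
  return S;
}

// [[Rcpp::export]]
NumericMatrix emission_logdens_cpp(const arma::mat& y, const arma::mat& mu,
                                   const arma::mat& sig) {
  return wrap(emission_logdens(y, mu, sig));
}

// [[Rcpp::export]]
double forward_loglik_cpp(const arma::mat& y, const arma::mat& mu,
                          const arma::mat& sig, const arma::mat& G,
                          const arma::vec& pi) {
  arma::mat ld = emission_logdens(y, mu, sig);
  arma::mat filt(ld.n_rows, ld.n_cols);
  return forward_filter(ld, G, pi, filt);
}

// [[Rcpp::export]]
IntegerVector ffbs_cpp(const arma::mat& y, const arma::mat& mu,
                       const arma::mat& sig, const arma::mat& G,
                       const arma::vec& pi) {
  arma::ivec S = ffbs_draw(emission_logdens(y, mu, sig), G, pi) + 1;
  return IntegerVector(S.begin(), S.end());
}

// [[Rcpp::export]]
IntegerVector viterbi_cpp(const arma::mat& y, const arma::mat& mu,
                          const arma::mat& sig, const arma::mat& G,
                          const arma::vec& pi) {
  arma::ivec S = viterbi_path(emission_logdens(y, mu, sig), G, pi) + 1;
  return IntegerVector(S.begin(), S.end());
}

// [[Rcpp::export]]
NumericVector stationary_cpp(const arma::mat& G) {
  return wrap(stationary_dist(G));
}

// [[Rcpp::export]]
NumericMatrix gamma_from_alpha_cpp(const arma::mat& alpha, const int m) {
  return wrap(gamma_from_alpha(alpha, m));
}

// Ancillarity-sufficiency (non-centered) translation update for one row
// of the group transition logits: proposes a shift applied to the group
// row AND to every patient's corresponding row (random-effect residuals
// held fixed), so the group parameter can move even when each patient
// carries little transition information. Target: transition counts +
// stationary term for each patient's first state + the Gaussian prior on
// the group logits. Returns updated alpha_bar, alpha_i and acceptances.
// [[Rcpp::export]]
List asis_alpha_bar_cpp(arma::mat alpha_bar, arma::cube alpha_i,
                        const arma::cube& trans, const arma::ivec& s1,
                        const arma::mat& prop_sd, const double prior_loc,
                        const double prior_sd) {
  const int m = alpha_bar.n_rows;
  const int n = alpha_i.n_slices;
  arma::imat accept(m, std::max(m - 1, 1), arma::fill::zeros);
  if (m < 2) return List::create(_["alpha_bar"] = alpha_bar,
                                 _["alpha_i"] = alpha_i,
                                 _["accept"] = accept);
  for (int s = 0; s < m; ++s) {
    for (int c = 0; c < m - 1; ++c) {
      const double delta = norm_rand() * prop_sd(s, c);
      double lp_cur = 0.0, lp_prop = 0.0;
      for (int i = 0; i < n; ++i) {
        arma::mat alph = alpha_i.slice(i);
        arma::mat G = gamma_from_alpha(alph, m);
        arma::mat alph2 = alph;
        alph2(s, c) += delta;
        arma::mat G2 = gamma_from_alpha(alph2, m);
        arma::vec pi = stationary_dist(G);
        arma::vec pi2 = stationary_dist(G2);
        lp_cur += std::log(pi(s1(i)));
        lp_prop += std::log(pi2(s1(i)));
        for (int j = 0; j < m; ++j) {
          const double nct = trans(s, j, i);
          if (nct > 0.0) {
            lp_cur += nct * std::log(G(s, j));
            lp_prop += nct * std::log(G2(s, j));
          }
        }
      }
      const double zc = (alpha_bar(s, c) - prior_loc) / prior_sd;
      const double zp = (alpha_bar(s, c) + delta - prior_loc) / prior_sd;
      lp_cur += -0.5 * zc * zc;
      lp_prop += -0.5 * zp * zp;
      if (std::isfinite(lp_prop) && std::log(unif_rand()) < lp_prop - lp_cur) {
        alpha_bar(s, c) += delta;
        for (int i = 0; i < n; ++i) alpha_i.slice(i)(s, c) += delta;
        accept(s, c) = 1;
      }
    }
  }
  return List::create(_["alpha_bar"] = alpha_bar, _["alpha_i"] = alpha_i,
                      _["accept"] = accept);
}

// Companion non-centered rescaling update for the transition
// random-effect SDs: for one cell (s, j), proposes a log-scale change of
// omega with the standardized residuals held fixed, i.e. every patient's
// logit cell moves as alpha_i' = alpha_bar + r * (alpha_i - alpha_bar)
// with r = omega'/omega. Prior on omega is the conditional implied by
// the half-Cauchy scale-mixture auxiliary a (omega^2 ~ IG(1/2, 1/a)),
// with the log-walk Jacobian included.
// [[Rcpp::export]]
List asis_omega_cpp(arma::mat omega, const arma::mat& alpha_bar,
                    arma::cube alpha_i, const arma::cube& trans,
                    const arma::ivec& s1, const arma::mat& a_om,
                    const arma::mat& prop_sd) {
  const int m = alpha_bar.n_rows;
  const int n = alpha_i.n_slices;
  arma::imat accept(m, std::max(m - 1, 1), arma::fill::zeros);
  if (m < 2) return List::create(_["omega"] = omega, _["alpha_i"] = alpha_i,
                                 _["accept"] = accept);
  for (int s = 0; s < m; ++s) {
    for (int j = 0; j < m - 1; ++j) {
      const double w = omega(s, j);
      const double w2 = w * std::exp(norm_rand() * prop_sd(s, j));
      const double r = w2 / w;
      double lp_cur = -std::log(w) - 1.0 / (a_om(s, j) * w * w);
      double lp_prop = -std::log(w2) - 1.0 / (a_om(s, j) * w2 * w2);
      for (int i = 0; i < n; ++i) {
        arma::mat alph = alpha_i.slice(i);
        arma::mat G = gamma_from_alpha(alph, m);
        arma::mat alph2 = alph;
        alph2(s, j) = alpha_bar(s, j) + r * (alph(s, j) - alpha_bar(s, j));
        arma::mat G2 = gamma_from_alpha(alph2, m);
        arma::vec pi = stationary_dist(G);
        arma::vec pi2 = stationary_dist(G2);
        lp_cur += std::log(pi(s1(i)));
        lp_prop += std::log(pi2(s1(i)));
        for (int jj = 0; jj < m; ++jj) {
          const double nct = trans(s, jj, i);
          if (nct > 0.0) {
            lp_cur += nct * std::log(G(s, jj));
            lp_prop += nct * std::log(G2(s, jj));
          }
        }
      }
      if (std::isfinite(lp_prop) && std::log(unif_rand()) < lp_prop - lp_cur) {
        for (int i = 0; i < n; ++i) {
          alpha_i.slice(i)(s, j) = alpha_bar(s, j) +
            r * (alpha_i.slice(i)(s, j) - alpha_bar(s, j));
        }
        omega(s, j) = w2;
        accept(s, j) = 1;
      }
    }
  }
  return List::create(_["omega"] = omega, _["alpha_i"] = alpha_i,
                      _["accept"] = accept);
}

// One Gibbs sweep over all patients:
//  (1) draw the latent path by FFBS given current subject parameters
//      (initial distribution = subject-level stationary distribution);
//  (2) row-wise Gaussian random-walk Metropolis on the subject transition
//      logits, target = path transition counts + stationary term for the
//      first occasion + Normal(alpha_bar, omega) random-effect prior;
//  (3) accumulate per-state sufficient statistics (count/sum/sum-of-
//      squares per state x channel, transition counts) for the conjugate
//      updates done in R.
// mu_i: m x K x n cube, alpha_i: m x (m-1) x n cube, prop_sd: n x m.
// [[Rcpp::export]]
List sweep_all_cpp(const List& ylist, const arma::cube& mu_i,
                   const arma::mat& sigma, arma::cube alpha_i,
                   const arma::mat& alpha_bar, const arma::mat& omega,
                   const arma::mat& prop_sd, const int n_scans) {
  const int n = ylist.size();
  const int m = mu_i.n_rows, K = mu_i.n_cols;
  arma::cube ncube(m, K, n, arma::fill::zeros);
  arma::cube sumc(m, K, n, arma::fill::zeros);
  arma::cube sumsq(m, K, n, arma::fill::zeros);
  arma::cube trans(m, m, n, arma::fill::zeros);
  arma::imat accept(n, m, arma::fill::zeros);
  List paths(n);

  for (int i = 0; i < n; ++i) {
    arma::mat y = as<arma::mat>(ylist[i]);
    const int T = y.n_rows;
    arma::mat alph = (m > 1) ? arma::mat(alpha_i.slice(i)) : arma::mat(m, 0);
    arma::mat G = gamma_from_alpha(alph, m);
    arma::vec pi = stationary_dist(G);
    arma::mat ld = emission_logdens(y, mu_i.slice(i), sigma);
    arma::ivec S = ffbs_draw(ld, G, pi);

    for (int t = 0; t + 1 < T; ++t) trans(S(t), S(t + 1), i) += 1.0;
    const int s1 = S(0);

    if (m > 1) {
      for (int scan = 0; scan < n_scans; ++scan)
      for (int s = 0; s < m; ++s) {
        arma::rowvec cur = alph.row(s);
        arma::rowvec prop = cur;
        for (int j = 0; j < m - 1; ++j) prop(j) += norm_rand() * prop_sd(i, s);
        arma::mat alph2 = alph;
        alph2.row(s) = prop;
        arma::mat G2 = gamma_from_alpha(alph2, m);
        arma::vec pi2 = stationary_dist(G2);
        double lp_cur = std::log(pi(s1));
        double lp_prop = std::log(pi2(s1));
        for (int j = 0; j < m; ++j) {
          const double nct = trans(s, j, i);
          if (nct > 0.0) {
            lp_cur += nct * std::log(G(s, j));
            lp_prop += nct * std::log(G2(s, j));
          }
        }
        for (int j = 0; j < m - 1; ++j) {
          const double zc = (cur(j) - alpha_bar(s, j)) / omega(s, j);
          const double zp = (prop(j) - alpha_bar(s, j)) / omega(s, j);
          lp_cur += -0.5 * zc * zc;
          lp_prop += -0.5 * zp * zp;
        }
        if (std::isfinite(lp_prop) &&
            std::log(unif_rand()) < lp_prop - lp_cur) {
          alph = alph2;
          G = G2;
          pi = pi2;
          accept(i, s) += 1; // acceptance count over scans
        }
      }
      alpha_i.slice(i) = alph;
    }

    for (int t = 0; t < T; ++t) {
      const int s = S(t);
      for (int k = 0; k < K; ++k) {
        const double v = y(t, k);
        if (std::isnan(v)) continue;
        ncube(s, k, i) += 1.0;
        sumc(s, k, i) += v;
        sumsq(s, k, i) += v * v;
      }
    }
    arma::ivec S1 = S + 1;
    paths[i] = IntegerVector(S1.begin(), S1.end());
  }

  return List::create(_["states"] = paths, _["alpha_i"] = alpha_i,
                      _["accept"] = accept, _["n"] = ncube, _["sum"] = sumc,
                      _["sumsq"] = sumsq, _["trans"] = trans);
}
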