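// Gibbs sampler for the Dirichlet-process mixture of multivariate linear
// trajectories with a latent-factor prior on the stacked regression
// coefficients theta_i = (alpha_i1..alpha_iG, beta_i1..beta_iG):
//
//   y_igk  = alpha_ig + beta_ig * u_ik + e_igk,   e ~ N(0, sigma_g^2)
//   theta_i = mu_{z_i} + Lambda eta_i + d_i,      d ~ N(0, diag(psi))
//   eta_i  ~ N(0, I_q),  mu_c ~ N(m0, s0^2 I) coordinatewise,  z ~ CRP(a)
//
// Label updates act on the factor residual r_i = theta_i - Lambda eta_i,
// for which psi is the relevant diagonal covariance. Because the base
// measure is coordinatewise normal and conjugate to that kernel, the
// default update is the marginal conjugate scheme (Neal 2000, Alg. 2):
// existing clusters are weighted by n_c N(r_i; mu_c, Psi) and a new
// cluster by a N(r_i; m0, Psi + s0^2 I), drawing the new cluster's mean
// from its posterior on acceptance. The auxiliary-component scheme
// (Neal's Alg. 8, n_aux fresh draws from G0) is retained as an option;
// it is exact too but seeds new clusters far more slowly as the
// coefficient dimension grows. The concentration parameter a gets the
// usual Beta-augmentation update under a Gamma prior.
//
// Only per-subject sufficient statistics enter: Sxx (n_i, sum u, sum u^2),
// Sxy per outcome (sum y, sum u y), Syy per outcome. All randomness comes
// from R's RNG so set.seed() in R controls the whole chain.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// index into an unnormalized-log-weight categorical
static int sample_logweights(const std::vector<double>& lw) {
  double m = R_NegInf;
  for (double v : lw) if (v > m) m = v;
  double tot = 0.0;
  std::vector<double> w(lw.size());
  for (size_t t = 0; t < lw.size(); ++t) { w[t] = std::exp(lw[t] - m); tot += w[t]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t t = 0; t < lw.size(); ++t) { acc += w[t]; if (u <= acc) return (int)t; }
  return (int)lw.size() - 1;
}

// [[Rcpp::export]]
List dp_gibbs_cpp(const arma::mat& sxx,        // n x 3: n_i, sum u, sum u^2
                  const arma::mat& sxy,        // n x 2G: (sum y_g, sum u y_g) per g
                  const arma::mat& syy,        // n x G: sum y_g^2
                  int G, int q,
                  double m0, double s02,
                  double a_sig, double b_sig,
                  double a_psi, double b_psi,
                  double a_alpha, double b_alpha,
                  int n_iter, int n_burn, int thin, int n_aux,
                  bool aux_labels,                  // Alg. 8 instead of marginal scheme
                  const arma::ivec& init_labels,    // length 0 (one cluster) or n (1-based)
                  bool fix_lambda,
                  const arma::ivec& fixed_labels,   // length 0, or n (1-based)
                  const arma::vec& fixed_sigma2,    // length 0 or G
                  const arma::vec& fixed_psi,       // length 0 or 2G
                  double fixed_alpha,               // <= 0 means sample
                  bool store_traces) {
  const int n = sxx.n_rows;
  const int d = 2 * G;
  const bool labels_free = (fixed_labels.n_elem == 0);
  const bool use_factors = !fix_lambda && q > 0;

  // ---- state ----
  arma::mat theta(n, d, arma::fill::zeros);
  arma::mat eta(n, std::max(q, 1), arma::fill::zeros);
  arma::mat Lambda(d, std::max(q, 1), arma::fill::zeros);
  arma::vec psi(d, arma::fill::ones);
  arma::vec sigma2(G, arma::fill::ones);
  double alpha = (fixed_alpha > 0.0) ? fixed_alpha : 1.0;
  if (fixed_sigma2.n_elem == (unsigned)G) sigma2 = fixed_sigma2;
  if (fixed_psi.n_elem == (unsigned)d) psi = fixed_psi;

  // theta init: per-subject OLS, falling back to mean + zero slope
  for (int i = 0; i < n; ++i) {
    double ni = sxx(i, 0), su = sxx(i, 1), su2 = sxx(i, 2);
    double det = ni * su2 - su * su;
    for (int g = 0; g < G; ++g) {
      double sy = sxy(i, 2 * g), suy = sxy(i, 2 * g + 1);
      if (det > 1e-10) {
        theta(i, g)     = (su2 * sy - su * suy) / det;
        theta(i, G + g) = (ni * suy - su * sy) / det;
      } else {
        theta(i, g)     = sy / ni;
        theta(i, G + g) = 0.0;
      }
    }
  }

  std::vector<int> z(n, 0);
  std::vector<double> counts;
  arma::mat mu;                         // K x d
  {
    const arma::ivec& zl = labels_free ? init_labels : fixed_labels;
    if (zl.n_elem == 0) {
      counts.assign(1, (double)n);
      mu = arma::mean(theta, 0);        // 1 x d
    } else {
      int K = zl.max();
      mu.set_size(K, d);
      counts.assign(K, 0.0);
      for (int i = 0; i < n; ++i) { z[i] = zl(i) - 1; counts[z[i]] += 1.0; }
      for (int c = 0; c < K; ++c) {
        arma::rowvec s(d, arma::fill::zeros);
        for (int i = 0; i < n; ++i) if (z[i] == c) s += theta.row(i);
        mu.row(c) = s / std::max(counts[c], 1.0);
      }
    }
  }
  // variance inits consistent with the initial theta/partition so the
  // first label sweeps start from a non-degenerate state
  if (fixed_sigma2.n_elem == 0) {
    for (int g = 0; g < G; ++g) {
      double ssr = 0.0, ntot = 0.0;
      for (int i = 0; i < n; ++i) {
        double a = theta(i, g), b = theta(i, G + g);
        double quad = a * a * sxx(i, 0) + 2.0 * a * b * sxx(i, 1) + b * b * sxx(i, 2);
        ssr += syy(i, g) - 2.0 * (a * sxy(i, 2 * g) + b * sxy(i, 2 * g + 1)) + quad;
        ntot += sxx(i, 0);
      }
      sigma2(g) = std::max(ssr / std::max(ntot, 1.0), 1e-4);
    }
  }
  if (fixed_psi.n_elem == 0) {
    for (int j = 0; j < d; ++j) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = theta(i, j) - mu(z[i], j);
        ss += e * e;
      }
      psi(j) = std::max(ss / n, 0.05);
    }
  }

  const int n_keep = (n_iter - n_burn) / thin;
  IntegerMatrix labels_out(n_keep, n);
  IntegerVector k_out(n_keep);
  NumericVector alpha_out(store_traces ? n_keep : 0);
  NumericMatrix sigma2_out(store_traces ? n_keep : 0, store_traces ? G : 0);
  NumericMatrix mu_mean_acc(n, d);      // running sum of mu_{z_i} (original scale of panel)
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // ---- (i) theta_i | data, mu, Lambda, eta, psi, sigma2 (2x2 blocks per outcome)
    for (int i = 0; i < n; ++i) {
      arma::rowvec pm = mu.row(z[i]);
      if (use_factors) pm += eta.row(i) * Lambda.t();
      double ni = sxx(i, 0), su = sxx(i, 1), su2 = sxx(i, 2);
      for (int g = 0; g < G; ++g) {
        int j1 = g, j2 = G + g;
        double isg = 1.0 / sigma2(g);
        double P11 = ni * isg + 1.0 / psi(j1);
        double P12 = su * isg;
        double P22 = su2 * isg + 1.0 / psi(j2);
        double b1 = sxy(i, 2 * g) * isg + pm(j1) / psi(j1);
        double b2 = sxy(i, 2 * g + 1) * isg + pm(j2) / psi(j2);
        double det = P11 * P22 - P12 * P12;
        double V11 = P22 / det, V12 = -P12 / det, V22 = P11 / det;
        double m1 = V11 * b1 + V12 * b2;
        double m2 = V12 * b1 + V22 * b2;
        double L11 = std::sqrt(V11);
        double L21 = V12 / L11;
        double L22 = std::sqrt(std::max(V22 - L21 * L21, 1e-12));
        double z1 = norm_rand(), z2 = norm_rand();
        theta(i, j1) = m1 + L11 * z1;
        theta(i, j2) = m2 + L21 * z1 + L22 * z2;
      }
    }

    // ---- (ii) eta_i | theta, Lambda, psi
    if (use_factors) {
      arma::mat LtPsiInv = Lambda.t();
      for (int j = 0; j < d; ++j) LtPsiInv.col(j) /= psi(j);
      arma::mat A = arma::eye(q, q) + LtPsiInv * Lambda;
      arma::mat V = arma::inv_sympd(arma::symmatu(A));
      arma::mat Lch = arma::chol(V, "lower");
      for (int i = 0; i < n; ++i) {
        arma::vec resid = (theta.row(i) - mu.row(z[i])).t();
        arma::vec mvec = V * (LtPsiInv * resid);
        arma::vec zdraw(q);
        for (int l = 0; l < q; ++l) zdraw(l) = norm_rand();
        eta.row(i) = (mvec + Lch * zdraw).t();
      }
    }

    // ---- (iii) Lambda rows and psi
    arma::mat resid = theta;
    for (int i = 0; i < n; ++i) resid.row(i) -= mu.row(z[i]);
    if (use_factors) {
      arma::mat E = eta.t() * eta;      // q x q
      for (int j = 0; j < d; ++j) {
        arma::mat M = arma::eye(q, q) + E / psi(j);
        arma::mat V = arma::inv_sympd(arma::symmatu(M));
        arma::vec b = (eta.t() * resid.col(j)) / psi(j);
        arma::vec mvec = V * b;
        arma::mat Lch = arma::chol(V, "lower");
        arma::vec zdraw(q);
        for (int l = 0; l < q; ++l) zdraw(l) = norm_rand();
        Lambda.row(j) = (mvec + Lch * zdraw).t();
      }
      resid -= eta * Lambda.t();
    }
    if (fixed_psi.n_elem == 0) {
      for (int j = 0; j < d; ++j) {
        double ss = arma::dot(resid.col(j), resid.col(j));
        psi(j) = rinvgamma(a_psi + 0.5 * n, b_psi + 0.5 * ss);
      }
    }

    // ---- (iv) sigma_g^2 | theta
    if (fixed_sigma2.n_elem == 0) {
      for (int g = 0; g < G; ++g) {
        double ssr = 0.0, ntot = 0.0;
        for (int i = 0; i < n; ++i) {
          double a = theta(i, g), b = theta(i, G + g);
          double quad = a * a * sxx(i, 0) + 2.0 * a * b * sxx(i, 1) + b * b * sxx(i, 2);
          ssr += syy(i, g) - 2.0 * (a * sxy(i, 2 * g) + b * sxy(i, 2 * g + 1)) + quad;
          ntot += sxx(i, 0);
        }
        sigma2(g) = rinvgamma(a_sig + 0.5 * ntot, b_sig + 0.5 * std::max(ssr, 0.0));
      }
    }

    // ---- (v) cluster labels
    if (labels_free) {
      arma::mat r = theta;
      if (use_factors) r -= eta * Lambda.t();
      // per-coordinate log-normalizing terms (psi changes once per sweep)
      double ldet_within = 0.0, ldet_marg = 0.0;
      for (int j = 0; j < d; ++j) {
        ldet_within += std::log(psi(j));
        ldet_marg += std::log(psi(j) + s02);
      }
      for (int i = 0; i < n; ++i) {
        int c = z[i];
        counts[c] -= 1.0;
        bool was_single = (counts[c] <= 0.0);
        arma::mat auxmu;
        int first_fresh = 0;
        if (aux_labels) {
          auxmu.set_size(n_aux, d);
          if (was_single) { auxmu.row(0) = mu.row(c); first_fresh = 1; }
        }
        if (was_single) {
          mu.shed_row(c);
          counts.erase(counts.begin() + c);
          for (int j2 = 0; j2 < n; ++j2) if (z[j2] > c) z[j2]--;
        }
        int K = (int)counts.size();

        if (aux_labels) {
          // Neal's algorithm 8: n_aux fresh components drawn from G0
          double s0 = std::sqrt(s02);
          for (int t = first_fresh; t < n_aux; ++t)
            for (int j = 0; j < d; ++j)
              auxmu(t, j) = m0 + s0 * norm_rand();
          std::vector<double> lw(K + n_aux);
          for (int c2 = 0; c2 < K; ++c2) {
            double quad = 0.0;
            for (int j = 0; j < d; ++j) {
              double e = r(i, j) - mu(c2, j);
              quad += e * e / psi(j);
            }
            lw[c2] = std::log(counts[c2]) - 0.5 * quad;
          }
          double lnew = std::log(alpha / n_aux);
          for (int t = 0; t < n_aux; ++t) {
            double quad = 0.0;
            for (int j = 0; j < d; ++j) {
              double e = r(i, j) - auxmu(t, j);
              quad += e * e / psi(j);
            }
            lw[K + t] = lnew - 0.5 * quad;
          }
          int pick = sample_logweights(lw);
          if (pick < K) {
            z[i] = pick;
            counts[pick] += 1.0;
          } else {
            mu.insert_rows(mu.n_rows, auxmu.row(pick - K));
            counts.push_back(1.0);
            z[i] = K;
          }
        } else {
          // marginal conjugate scheme (Neal's algorithm 2): the new-cluster
          // weight integrates mu over G0
          std::vector<double> lw(K + 1);
          for (int c2 = 0; c2 < K; ++c2) {
            double quad = 0.0;
            for (int j = 0; j < d; ++j) {
              double e = r(i, j) - mu(c2, j);
              quad += e * e / psi(j);
            }
            lw[c2] = std::log(counts[c2]) - 0.5 * (quad + ldet_within);
          }
          double quad = 0.0;
          for (int j = 0; j < d; ++j) {
            double e = r(i, j) - m0;
            quad += e * e / (psi(j) + s02);
          }
          lw[K] = std::log(alpha) - 0.5 * (quad + ldet_marg);
          int pick = sample_logweights(lw);
          if (pick < K) {
            z[i] = pick;
            counts[pick] += 1.0;
          } else {
            // seed the new cluster's mean from its posterior given r_i
            arma::rowvec mnew(d);
            for (int j = 0; j < d; ++j) {
              double prec = 1.0 / s02 + 1.0 / psi(j);
              double mean = (m0 / s02 + r(i, j) / psi(j)) / prec;
              mnew(j) = mean + norm_rand() / std::sqrt(prec);
            }
            mu.insert_rows(mu.n_rows, mnew);
            counts.push_back(1.0);
            z[i] = K;
          }
        }
      }
    }

    // ---- (vi) mu_c | members (conjugate normal; r_i = theta - Lambda eta)
    {
      arma::mat r = theta;
      if (use_factors) r -= eta * Lambda.t();
      int K = (int)counts.size();
      arma::mat rsum(K, d, arma::fill::zeros);
      for (int i = 0; i < n; ++i) rsum.row(z[i]) += r.row(i);
      for (int c = 0; c < K; ++c) {
        for (int j = 0; j < d; ++j) {
          double prec = 1.0 / s02 + counts[c] / psi(j);
          double mean = (m0 / s02 + rsum(c, j) / psi(j)) / prec;
          mu(c, j) = mean + norm_rand() / std::sqrt(prec);
        }
      }
    }

    // ---- (vii) concentration parameter
    if (labels_free && fixed_alpha <= 0.0) {
      int K = (int)counts.size();
      double e = R::rbeta(alpha + 1.0, (double)n);
      double rate = b_alpha - std::log(e);
      double odds = (a_alpha + K - 1.0) / ((double)n * rate);
      double w = odds / (1.0 + odds);
      if (unif_rand() < w)
        alpha = R::rgamma(a_alpha + K, 1.0 / rate);
      else
        alpha = R::rgamma(a_alpha + K - 1.0, 1.0 / rate);
    }

    // ---- record
    if (it >= n_burn && ((it - n_burn) % thin == 0)) {
      for (int i = 0; i < n; ++i) {
        labels_out(kept, i) = z[i] + 1;
        for (int j = 0; j < d; ++j) mu_mean_acc(i, j) += mu(z[i], j);
      }
      k_out[kept] = (int)counts.size();
      if (store_traces) {
        alpha_out[kept] = alpha;
        for (int g = 0; g < G; ++g) sigma2_out(kept, g) = sigma2(g);
      }
      kept++;
    }
  }

  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j)
      mu_mean_acc(i, j) /= std::max(kept, 1);

  List out = List::create(
    _["labels"] = labels_out,
    _["n_clusters"] = k_out,
    _["coef_mean"] = mu_mean_acc);
  if (store_traces) {
    out["alpha"] = alpha_out;
    out["sigma2"] = sigma2_out;
  }
  return out;
}

// Posterior similarity matrix: S_ij = fraction of draws with z_i == z_j.
// [[Rcpp::export]]
arma::mat psm_cpp(const IntegerMatrix& labels) {
  const int m = labels.nrow(), n = labels.ncol();
  arma::mat S(n, n, arma::fill::zeros);
  for (int t = 0; t < m; ++t) {
    for (int i = 0; i < n; ++i) {
      int zi = labels(t, i);
      for (int j = i + 1; j < n; ++j) {
        if (zi == labels(t, j)) S(i, j) += 1.0;
      }
    }
  }
  S /= (double)m;
  S = S + S.t();
  S.diag().ones();
  return S;
}
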