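// Adaptive Metropolis-within-Gibbs sampler for the latent space item
// response model (and the Rasch sub-model when the distance term is off).
//
// Blocks: theta_p | b_i | log sigma^2 | log lambda | xi_p rows | zeta_i rows.
// Proposal scales adapt per coordinate during burn-in (Robbins-Monro on the
// log scale, frozen afterwards so the retained chain is a valid MH chain).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double stable_log1pexp(double x) {
  // stable log(1 + e^x)
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double cell_ll(double y, double eta) {
  // Bernoulli log-probability, never via log(sigmoid)
  return y * eta - stable_log1pexp(eta);
}

struct Priors {
  double sigma_b;       // SD of item intercept prior
  double cauchy_scale;  // half-Cauchy scale
  bool cauchy_on_sd;    // half-Cauchy on sigma (true) or sigma^2 (false)
  double mu_spike, mu_slab, sd_spike, sd_slab, w_slab;
};

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

static double log_mix_prior(double loglam, const Priors& pr) {
  double a_sp = std::log(1.0 - pr.w_slab) + dnorm_log(loglam, pr.mu_spike, pr.sd_spike);
  double a_sl = std::log(pr.w_slab) + dnorm_log(loglam, pr.mu_slab, pr.sd_slab);
  double m = std::max(a_sp, a_sl);
  return m + std::log(std::exp(a_sp - m) + std::exp(a_sl - m));
}

static double log_sigma2_prior(double s2, const Priors& pr) {
  // density with respect to sigma^2
  if (pr.cauchy_on_sd) {
    double s = std::sqrt(s2);
    double lp = std::log(2.0) - std::log(M_PI * pr.cauchy_scale *
                (1.0 + (s / pr.cauchy_scale) * (s / pr.cauchy_scale)));
    return lp - std::log(2.0 * s);  // Jacobian d(sigma)/d(sigma^2)
  }
  return std::log(2.0) - std::log(M_PI * pr.cauchy_scale *
         (1.0 + (s2 / pr.cauchy_scale) * (s2 / pr.cauchy_scale)));
}

class Sampler {
public:
  const arma::mat& Y;    // P x I, unobserved cells hold 0 (masked out)
  const arma::mat& M;    // P x I observation mask in {0,1}
  int P, I, K;
  bool use_distance;
  Priors pr;

  arma::vec theta, b;
  double sigma2, loglam;
  arma::mat xi, zeta;    // P x K, I x K
  arma::mat D;           // P x I person-item distances

  Sampler(const arma::mat& Y_, const arma::mat& M_, int K_, bool use_distance_,
          const Priors& pr_)
    : Y(Y_), M(M_), P(Y_.n_rows), I(Y_.n_cols), K(K_),
      use_distance(use_distance_), pr(pr_) {}

  void refresh_distances() {
    if (!use_distance) { D.zeros(P, I); return; }
    D.set_size(P, I);
    for (int p = 0; p < P; ++p)
      for (int i = 0; i < I; ++i) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          double d = xi(p, k) - zeta(i, k);
          s += d * d;
        }
        D(p, i) = std::sqrt(s);
      }
  }

  double row_ll(int p, double th, const double* drow) const {
    double lam = use_distance ? std::exp(loglam) : 0.0;
    double s = 0.0;
    for (int i = 0; i < I; ++i) {
      if (M(p, i) == 0.0) continue;
      s += cell_ll(Y(p, i), th + b(i) - lam * drow[i]);
    }
    return s;
  }

  double col_ll(int i, double bi, const arma::vec& dcol) const {
    double lam = use_distance ? std::exp(loglam) : 0.0;
    double s = 0.0;
    for (int p = 0; p < P; ++p) {
      if (M(p, i) == 0.0) continue;
      s += cell_ll(Y(p, i), theta(p) + bi - lam * dcol(p));
    }
    return s;
  }

  double full_ll(double lam) const {
    double s = 0.0;
    for (int i = 0; i < I; ++i)
      for (int p = 0; p < P; ++p) {
        if (M(p, i) == 0.0) continue;
        s += cell_ll(Y(p, i), theta(p) + b(i) - lam * D(p, i));
      }
    return s;
  }

  double full_log_prior() const {
    double lp = 0.0;
    double sd_th = std::sqrt(sigma2);
    for (int p = 0; p < P; ++p) lp += dnorm_log(theta(p), 0.0, sd_th);
    for (int i = 0; i < I; ++i) lp += dnorm_log(b(i), 0.0, pr.sigma_b);
    lp += log_sigma2_prior(sigma2, pr);
    if (use_distance) {
      lp += log_mix_prior(loglam, pr);
      for (int p = 0; p < P; ++p)
        for (int k = 0; k < K; ++k) lp += dnorm_log(xi(p, k), 0.0, 1.0);
      for (int i = 0; i < I; ++i)
        for (int k = 0; k < K; ++k) lp += dnorm_log(zeta(i, k), 0.0, 1.0);
    }
    return lp;
  }
};

struct Adapt {
  arma::vec ls;      // log proposal SDs
  arma::vec acc;     // acceptances in current batch
  arma::vec tries;
  double target;
  Adapt(int n, double init_sd, double target_) :
    ls(n, arma::fill::value(std::log(init_sd))),
    acc(n, arma::fill::zeros), tries(n, arma::fill::zeros), target(target_) {}
  void update(int batch) {
    double delta = std::min(0.25, 1.0 / std::sqrt((double)batch));
    for (arma::uword j = 0; j < ls.n_elem; ++j) {
      if (tries(j) > 0) {
        double rate = acc(j) / tries(j);
        ls(j) += (rate > target) ? delta : -delta;
      }
      acc(j) = 0.0; tries(j) = 0.0;
    }
  }
};

// [[Rcpp::export]]
List lsirm_mcmc_cpp(const arma::mat& Y, const arma::mat& M, int K,
                    arma::vec theta0, arma::vec b0, double sigma2_0,
                    double loglam0, arma::mat xi0, arma::mat zeta0,
                    int n_iter, int n_burnin, bool use_distance,
                    List prior, List ctrl) {
  Priors pr;
  pr.sigma_b      = as<double>(prior["sigma_b"]);
  pr.cauchy_scale = as<double>(prior["sigma_cauchy_scale"]);
  pr.cauchy_on_sd = as<bool>(prior["cauchy_on_sd"]);
  pr.mu_spike = as<double>(prior["mu_spike"]);
  pr.mu_slab  = as<double>(prior["mu_slab"]);
  pr.sd_spike = as<double>(prior["sd_spike"]);
  pr.sd_slab  = as<double>(prior["sd_slab"]);
  pr.w_slab   = as<double>(prior["slab_prior_weight"]);

  bool up_theta  = as<bool>(ctrl["update_theta"]);
  bool up_b      = as<bool>(ctrl["update_b"]);
  bool up_sigma2 = as<bool>(ctrl["update_sigma2"]);
  bool up_lambda = as<bool>(ctrl["update_lambda"]) && use_distance;
  bool up_xi     = as<bool>(ctrl["update_xi"]) && use_distance;
  bool up_zeta   = as<bool>(ctrl["update_zeta"]) && use_distance;
  int batch_size = as<int>(ctrl["adapt_batch"]);
  double temper_floor = as<double>(ctrl["temper_floor"]);

  Sampler s(Y, M, K, use_distance, pr);
  s.theta = theta0; s.b = b0; s.sigma2 = sigma2_0; s.loglam = loglam0;
  s.xi = xi0; s.zeta = zeta0;
  s.refresh_distances();

  int P = s.P, I = s.I;
  Adapt a_theta(P, 1.0, 0.44), a_b(I, 0.5, 0.44), a_s2(1, 0.5, 0.44),
        a_lam(1, 0.5, 0.44), a_xi(P, 0.5, 0.35), a_zeta(I, 0.5, 0.35);

  int n_keep = n_iter - n_burnin;
  arma::mat theta_dr(n_keep, P), b_dr(n_keep, I);
  arma::vec s2_dr(n_keep), lam_dr(n_keep), ll_dr(n_keep), lp_dr(n_keep);
  arma::cube xi_dr(P, K, use_distance ? n_keep : 0);
  arma::cube zeta_dr(I, K, use_distance ? n_keep : 0);

  RNGScope scope;
  std::vector<double> dnew(I);
  int batch = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < n_burnin;
    // Likelihood-tempered burn-in: ramp the inverse temperature from a
    // small value to 1 over the first half of burn-in.  At low beta the
    // untempered prior dissolves noise-fitting latent configurations,
    // while genuinely supported structure (whose likelihood payoff is much
    // larger) survives the ramp, so chains settle into the dominant
    // spike/slab basin by posterior mass rather than by initialization.
    // All retained draws use beta = 1, leaving the sampled kernel exact.
    double beta = 1.0;
    if (use_distance && n_burnin > 0 && temper_floor < 1.0) {
      double ramp = 0.5 * (double)n_burnin;
      if ((double)it < ramp)
        beta = temper_floor + (1.0 - temper_floor) * (double)it / ramp;
    }
    double lam = use_distance ? std::exp(s.loglam) : 0.0;

    if (up_theta) {
      double sd_th = std::sqrt(s.sigma2);
      for (int p = 0; p < P; ++p) {
        double step = std::exp(a_theta.ls(p));
        double prop = s.theta(p) + step * R::norm_rand();
        const double* drow_p = s.D.colptr(0); (void)drow_p;
        // gather row p of D
        for (int i = 0; i < I; ++i) dnew[i] = s.D(p, i);
        double d = beta * (s.row_ll(p, prop, dnew.data()) -
                           s.row_ll(p, s.theta(p), dnew.data()))
                 + dnorm_log(prop, 0.0, sd_th) - dnorm_log(s.theta(p), 0.0, sd_th);
        a_theta.tries(p) += 1;
        if (std::log(R::unif_rand()) < d) { s.theta(p) = prop; a_theta.acc(p) += 1; }
      }
    }

    if (up_b) {
      for (int i = 0; i < I; ++i) {
        double step = std::exp(a_b.ls(i));
        double prop = s.b(i) + step * R::norm_rand();
        arma::vec dcol = s.D.col(i);
        double d = beta * (s.col_ll(i, prop, dcol) - s.col_ll(i, s.b(i), dcol))
                 + dnorm_log(prop, 0.0, pr.sigma_b) - dnorm_log(s.b(i), 0.0, pr.sigma_b);
        a_b.tries(i) += 1;
        if (std::log(R::unif_rand()) < d) { s.b(i) = prop; a_b.acc(i) += 1; }
      }
    }

    if (up_sigma2) {
      double step = std::exp(a_s2.ls(0));
      double prop_log = std::log(s.sigma2) + step * R::norm_rand();
      double prop = std::exp(prop_log);
      double d = log_sigma2_prior(prop, pr) - log_sigma2_prior(s.sigma2, pr)
               + prop_log - std::log(s.sigma2);  // Jacobian of log transform
      double sd_new = std::sqrt(prop), sd_old = std::sqrt(s.sigma2);
      for (int p = 0; p < P; ++p)
        d += dnorm_log(s.theta(p), 0.0, sd_new) - dnorm_log(s.theta(p), 0.0, sd_old);
      a_s2.tries(0) += 1;
      if (std::log(R::unif_rand()) < d) { s.sigma2 = prop; a_s2.acc(0) += 1; }
    }

    if (up_lambda) {
      // three sub-updates per sweep: random walk, prior independence,
      // random walk.  The independence draw from the mixture prior lets the
      // chain hop between the spike and slab basins.  Every proposal shifts
      // each item intercept by (lambda' - lambda) * mean observed distance
      // of that item, a deterministic invertible companion move (unit
      // Jacobian) that preserves the average column fit, so a lambda jump
      // does not have to wait for b to re-equilibrate.
      arma::vec dbar(I, arma::fill::zeros);
      for (int i = 0; i < I; ++i) {
        double sum = 0.0, n = 0.0;
        for (int p = 0; p < P; ++p)
          if (M(p, i) == 1.0) { sum += s.D(p, i); n += 1.0; }
        if (n > 0) dbar(i) = sum / n;
      }
      for (int rep = 0; rep < 3; ++rep) {
        bool is_rw = (rep != 1);
        double prop;
        if (is_rw) {
          prop = s.loglam + std::exp(a_lam.ls(0)) * R::norm_rand();
        } else if (R::unif_rand() < pr.w_slab) {
          prop = pr.mu_slab + pr.sd_slab * R::norm_rand();
        } else {
          prop = pr.mu_spike + pr.sd_spike * R::norm_rand();
        }
        double lam_cur = std::exp(s.loglam), lam_new = std::exp(prop);
        arma::vec b_new = s.b;
        if (up_b) b_new += (lam_new - lam_cur) * dbar;
        double dll = 0.0, d = 0.0;
        for (int i = 0; i < I; ++i) {
          for (int p = 0; p < P; ++p) {
            if (M(p, i) == 0.0) continue;
            double base = s.theta(p);
            dll += cell_ll(Y(p, i), base + b_new(i) - lam_new * s.D(p, i))
                 - cell_ll(Y(p, i), base + s.b(i) - lam_cur * s.D(p, i));
          }
          d += dnorm_log(b_new(i), 0.0, pr.sigma_b)
             - dnorm_log(s.b(i), 0.0, pr.sigma_b);
        }
        d += beta * dll;
        if (is_rw) {
          // independence proposal density cancels the mixture prior
          d += log_mix_prior(prop, pr) - log_mix_prior(s.loglam, pr);
          a_lam.tries(0) += 1;
        }
        if (std::log(R::unif_rand()) < d) {
          s.loglam = prop; s.b = b_new;
          if (is_rw) a_lam.acc(0) += 1;
        }
      }
      lam = std::exp(s.loglam);
    }

    if (up_lambda && up_xi && up_zeta) {
      // likelihood-invariant scale move: positions *= c, lambda /= c keeps
      // every lambda*d product fixed; only the priors and the Jacobian
      // (one factor c per scaled coordinate) enter the ratio.  Lets the
      // chain slide along the lambda-vs-configuration-scale ridge.
      double dlt = 0.3 * R::norm_rand();
      double c = std::exp(dlt);
      double ss = arma::accu(arma::square(s.xi)) + arma::accu(arma::square(s.zeta));
      double npos = (double)(P + I) * K;
      double d = -0.5 * (c * c - 1.0) * ss
               + log_mix_prior(s.loglam - dlt, pr) - log_mix_prior(s.loglam, pr)
               + npos * dlt;
      if (std::log(R::unif_rand()) < d) {
        s.xi *= c; s.zeta *= c; s.D *= c;
        s.loglam -= dlt;
        lam = std::exp(s.loglam);
      }
    }

    if (up_xi) {
      for (int p = 0; p < P; ++p) {
        // mostly random-walk steps; occasionally an independence draw from
        // the standard-normal prior (prior and proposal cancel), which
        // dissolves spurious configurations that the likelihood barely
        // supports while leaving well-supported ones alone
        bool rw = R::unif_rand() >= 0.2;
        arma::rowvec prop(K);
        double dpr = 0.0;
        if (rw) {
          double step = std::exp(a_xi.ls(p));
          prop = s.xi.row(p);
          for (int k = 0; k < K; ++k) prop(k) += step * R::norm_rand();
          for (int k = 0; k < K; ++k)
            dpr += dnorm_log(prop(k), 0.0, 1.0) - dnorm_log(s.xi(p, k), 0.0, 1.0);
        } else {
          for (int k = 0; k < K; ++k) prop(k) = R::norm_rand();
        }
        // companion move: shift theta_p so the person's mean fit is kept
        // when the row's mean distance changes (unit Jacobian, invertible)
        double m_old = 0.0, m_new = 0.0, nobs = 0.0;
        for (int i = 0; i < I; ++i) {
          double ssq = 0.0;
          for (int k = 0; k < K; ++k) {
            double dd = prop(k) - s.zeta(i, k);
            ssq += dd * dd;
          }
          dnew[i] = std::sqrt(ssq);
          if (M(p, i) == 0.0) continue;
          m_old += s.D(p, i); m_new += dnew[i]; nobs += 1.0;
        }
        double th_new = s.theta(p);
        if (up_theta && nobs > 0) th_new += lam * (m_new - m_old) / nobs;
        double sd_th = std::sqrt(s.sigma2);
        double ll_old = 0.0, ll_new = 0.0;
        for (int i = 0; i < I; ++i) {
          if (M(p, i) == 0.0) continue;
          ll_old += cell_ll(Y(p, i), s.theta(p) + s.b(i) - lam * s.D(p, i));
          ll_new += cell_ll(Y(p, i), th_new + s.b(i) - lam * dnew[i]);
        }
        dpr += dnorm_log(th_new, 0.0, sd_th) - dnorm_log(s.theta(p), 0.0, sd_th);
        if (rw) a_xi.tries(p) += 1;
        if (std::log(R::unif_rand()) < beta * (ll_new - ll_old) + dpr) {
          s.xi.row(p) = prop;
          s.theta(p) = th_new;
          for (int i = 0; i < I; ++i) s.D(p, i) = dnew[i];
          if (rw) a_xi.acc(p) += 1;
        }
      }
    }

    if (up_zeta) {
      std::vector<double> dcol_new(P);
      for (int i = 0; i < I; ++i) {
        bool rw = R::unif_rand() >= 0.2;
        arma::rowvec prop(K);
        double dpr = 0.0;
        if (rw) {
          double step = std::exp(a_zeta.ls(i));
          prop = s.zeta.row(i);
          for (int k = 0; k < K; ++k) prop(k) += step * R::norm_rand();
          for (int k = 0; k < K; ++k)
            dpr += dnorm_log(prop(k), 0.0, 1.0) - dnorm_log(s.zeta(i, k), 0.0, 1.0);
        } else {
          for (int k = 0; k < K; ++k) prop(k) = R::norm_rand();
        }
        // companion move: shift b_i to keep the item's mean fit when the
        // column's mean distance changes (unit Jacobian, invertible)
        double m_old = 0.0, m_new = 0.0, nobs = 0.0;
        for (int p = 0; p < P; ++p) {
          double ssq = 0.0;
          for (int k = 0; k < K; ++k) {
            double dd = s.xi(p, k) - prop(k);
            ssq += dd * dd;
          }
          dcol_new[p] = std::sqrt(ssq);
          if (M(p, i) == 0.0) continue;
          m_old += s.D(p, i); m_new += dcol_new[p]; nobs += 1.0;
        }
        double b_new = s.b(i);
        if (up_b && nobs > 0) b_new += lam * (m_new - m_old) / nobs;
        double ll_old = 0.0, ll_new = 0.0;
        for (int p = 0; p < P; ++p) {
          if (M(p, i) == 0.0) continue;
          ll_old += cell_ll(Y(p, i), s.theta(p) + s.b(i) - lam * s.D(p, i));
          ll_new += cell_ll(Y(p, i), s.theta(p) + b_new - lam * dcol_new[p]);
        }
        dpr += dnorm_log(b_new, 0.0, pr.sigma_b) - dnorm_log(s.b(i), 0.0, pr.sigma_b);
        if (rw) a_zeta.tries(i) += 1;
        if (std::log(R::unif_rand()) < beta * (ll_new - ll_old) + dpr) {
          s.zeta.row(i) = prop;
          s.b(i) = b_new;
          for (int p = 0; p < P; ++p) s.D(p, i) = dcol_new[p];
          if (rw) a_zeta.acc(i) += 1;
        }
      }
    }

    if (adapting && (it + 1) % batch_size == 0) {
      ++batch;
      a_theta.update(batch); a_b.update(batch); a_s2.update(batch);
      a_lam.update(batch); a_xi.update(batch); a_zeta.update(batch);
    }

    if (it >= n_burnin) {
      int r = it - n_burnin;
      theta_dr.row(r) = s.theta.t();
      b_dr.row(r) = s.b.t();
      s2_dr(r) = s.sigma2;
      lam_dr(r) = use_distance ? s.loglam : R_NegInf;
      double ll = s.full_ll(use_distance ? std::exp(s.loglam) : 0.0);
      ll_dr(r) = ll;
      lp_dr(r) = ll + s.full_log_prior();
      if (use_distance) {
        xi_dr.slice(r) = s.xi;
        zeta_dr.slice(r) = s.zeta;
      }
    }
  }

  List acc = List::create(
    _["theta"] = arma::mean(a_theta.acc / arma::clamp(a_theta.tries, 1.0, arma::datum::inf)),
    _["b"] = arma::mean(a_b.acc / arma::clamp(a_b.tries, 1.0, arma::datum::inf)));

  return List::create(
    _["theta"] = theta_dr, _["b"] = b_dr, _["sigma2"] = s2_dr,
    _["log_lambda"] = lam_dr, _["xi"] = xi_dr, _["zeta"] = zeta_dr,
    _["log_lik"] = ll_dr, _["log_post"] = lp_dr);
}
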