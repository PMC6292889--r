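#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs samplers for the package's two Bayesian
// models. Both use R's RNG (seeded from R) so fits are reproducible with
// set.seed(). Proposal scales adapt by Robbins-Monro toward 0.44 acceptance
// during warmup only, leaving the post-warmup chain a valid Markov chain.

namespace {

struct Adapt {
  std::vector<double> ls;   // log step sizes
  explicit Adapt(int n, double init = -1.0) : ls(n, init) {}
  double scale(int j) const { return std::exp(ls[j]); }
  void tune(int j, double acc, int iter) {
    double gamma = std::pow(iter + 1.0, -0.6);
    ls[j] += gamma * (acc - 0.44);
    if (ls[j] < -10) ls[j] = -10;
    if (ls[j] > 5) ls[j] = 5;
  }
};

// NB log-likelihood change for a subset when eta -> eta + delta (constant
// shift): sum (theta+y) * (log(theta+mu) - log(theta+mu*e^delta)) + delta*sum y
double nb_shift_delta(const std::vector<int>& idx, const IntegerVector& y,
                      const std::vector<double>& mu, double theta,
                      double delta) {
  double ed = std::exp(delta), out = 0.0, sumy = 0.0;
  for (int i : idx) {
    out += (theta + y[i]) * (std::log(theta + mu[i]) -
                             std::log(theta + mu[i] * ed));
    sumy += y[i];
  }
  return out + delta * sumy;
}

void apply_shift(const std::vector<int>& idx, std::vector<double>& mu,
                 double delta) {
  double ed = std::exp(delta);
  for (int i : idx) mu[i] *= ed;
}

// full NB log-likelihood (theta-dependent parts only) over all observations
double nb_theta_part(const IntegerVector& y, const std::vector<double>& mu,
                     double theta) {
  double lgt = R::lgammafn(theta), lt = std::log(theta), out = 0.0;
  for (int i = 0; i < y.size(); ++i) {
    out += R::lgammafn(y[i] + theta) - lgt + theta * lt -
           (theta + y[i]) * std::log(theta + mu[i]);
  }
  return out;
}

double pc_logprior(double sigma, double u, double alpha) {
  double lambda = -std::log(alpha) / u;
  return std::log(lambda) - lambda * sigma;
}

// sum of squared second differences of f[offset..offset+T-1] touching index t
double local_ssd(const std::vector<double>& f, int offset, int T, int t) {
  double s = 0.0;
  int j0 = t - 2 < 0 ? 0 : t - 2;
  int j1 = t > T - 3 ? T - 3 : t;
  for (int j = j0; j <= j1; ++j) {
    double d = f[offset + j + 2] - 2.0 * f[offset + j + 1] + f[offset + j];
    s += d * d;
  }
  return s;
}

double total_ssd(const std::vector<double>& f, int offset, int T) {
  double s = 0.0;
  for (int j = 0; j + 2 < T; ++j) {
    double d = f[offset + j + 2] - 2.0 * f[offset + j + 1] + f[offset + j];
    s += d * d;
  }
  return s;
}

bool mh_accept(double log_ratio) {
  return std::log(R::unif_rand()) < log_ratio;
}

} // namespace

// [[Rcpp::export(name = ".nbrw2_mcmc")]]
List nbrw2_mcmc(IntegerVector y, NumericVector log_offset,
                IntegerVector region, IntegerVector site, IntegerVector gear,
                IntegerVector year, int n_region, int n_site, int n_year,
                IntegerVector site_region, bool regional, bool include_trend,
                int n_iter, int n_warmup, int thin, List prior) {
  const int n = y.size();
  const double beta_sd = as<double>(prior["beta_sd"]);
  const double pc_u_f = as<double>(prior["pc_u_f"]);
  const double pc_alpha_f = as<double>(prior["pc_alpha_f"]);
  const double pc_u_re = as<double>(prior["pc_u_re"]);
  const double pc_alpha_re = as<double>(prior["pc_alpha_re"]);
  const double ltheta_lo = as<double>(prior["ltheta_lo"]);
  const double ltheta_hi = as<double>(prior["ltheta_hi"]);

  const int n_traj = include_trend ? (regional ? n_region : 1) : 0;
  const int n_f = n_traj * n_year;
  const bool use_u = n_region > 1;
  const bool use_v = n_site > n_region;
  bool use_gear = false;
  for (int i = 0; i < n; ++i) if (gear[i] == 1) { use_gear = true; break; }

  // index lists
  std::vector<std::vector<int>> by_region(n_region), by_site(n_site),
      by_f(std::max(n_f, 1)), gear_idx(1);
  std::vector<int> all_idx(n);
  for (int i = 0; i < n; ++i) {
    all_idx[i] = i;
    by_region[region[i]].push_back(i);
    by_site[site[i]].push_back(i);
    if (include_trend) {
      int fi = regional ? region[i] * n_year + year[i] : year[i];
      by_f[fi].push_back(i);
    }
    if (gear[i] == 1) gear_idx[0].push_back(i);
  }

  // state
  double sum_y = 0.0, sum_off = 0.0;
  for (int i = 0; i < n; ++i) { sum_y += y[i]; sum_off += std::exp(log_offset[i]); }
  double beta0 = std::log((sum_y + 0.5) / sum_off);
  double beta_gear = 0.0;
  std::vector<double> u(n_region, 0.0), v(n_site, 0.0), f(std::max(n_f, 1), 0.0);
  double sigma_u = 0.3, sigma_v = 0.3, sigma_f = 0.05, ltheta = 0.0;

  std::vector<double> mu(n);
  for (int i = 0; i < n; ++i) mu[i] = std::exp(beta0 + log_offset[i]);

  // adaptation: beta0, beta_gear, u..., v..., f..., sig_u, sig_v, sig_f,
  // theta, tilts...
  // smooth block-move shapes: mode 0 is centred linear time, modes k >= 1
  // are DCT-II cosines of increasing frequency
  const int n_modes = include_trend ? std::min(n_year - 2, 8) : 0;
  std::vector<std::vector<double>> modes(n_modes + 1,
                                         std::vector<double>(n_year, 0.0));
  {
    double tbar = (n_year - 1.0) / 2.0;
    double norm = 0.0;
    for (int t = 0; t < n_year; ++t) norm += (t - tbar) * (t - tbar);
    norm = std::sqrt(norm / n_year);
    for (int t = 0; t < n_year; ++t) modes[0][t] = (t - tbar) / norm;
    for (int k = 1; k <= n_modes; ++k) {
      for (int t = 0; t < n_year; ++t) {
        modes[k][t] = std::sqrt(2.0) *
                      std::cos(M_PI * (k + 1) * (t + 0.5) / n_year);
      }
    }
  }

  const int A_B0 = 0, A_BG = 1, A_U = 2, A_V = A_U + n_region,
            A_F = A_V + n_site, A_SU = A_F + n_f, A_SV = A_SU + 1,
            A_SF = A_SV + 1, A_TH = A_SF + 1, A_SWAP = A_TH + 1,
            A_RS = A_SWAP + 1, A_SWAPV = A_RS + 1,
            A_TILT = A_SWAPV + n_region;
  Adapt ad(A_TILT + std::max(n_traj, 1) * (n_modes + 1), -1.0);
  for (int j = A_F; j < A_SU; ++j) ad.ls[j] = -2.0;

  const int n_keep = (n_iter - n_warmup) / thin;
  NumericMatrix draws(n_keep, 2 + n_region + n_site + n_f + 4);
  NumericMatrix loglik(n_keep, n);
  std::vector<double> lgam_y1(n);
  for (int i = 0; i < n; ++i) lgam_y1[i] = R::lgammafn(y[i] + 1.0);

  int kept = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    bool warm = iter < n_warmup;

    // fixed effects
    {
      double s = ad.scale(A_B0), d = R::norm_rand() * s;
      double lr = nb_shift_delta(all_idx, y, mu, std::exp(ltheta), d) +
                  (beta0 * beta0 - (beta0 + d) * (beta0 + d)) /
                      (2 * beta_sd * beta_sd);
      bool acc = mh_accept(lr);
      if (acc) { apply_shift(all_idx, mu, d); beta0 += d; }
      if (warm) ad.tune(A_B0, acc ? 1.0 : 0.0, iter);
    }
    if (use_gear) {
      double s = ad.scale(A_BG), d = R::norm_rand() * s;
      double lr = nb_shift_delta(gear_idx[0], y, mu, std::exp(ltheta), d) +
                  (beta_gear * beta_gear -
                   (beta_gear + d) * (beta_gear + d)) /
                      (2 * beta_sd * beta_sd);
      bool acc = mh_accept(lr);
      if (acc) { apply_shift(gear_idx[0], mu, d); beta_gear += d; }
      if (warm) ad.tune(A_BG, acc ? 1.0 : 0.0, iter);
    }

    // region effects
    if (use_u) {
      for (int r = 0; r < n_region; ++r) {
        double s = ad.scale(A_U + r), d = R::norm_rand() * s;
        double lr = nb_shift_delta(by_region[r], y, mu, std::exp(ltheta), d) +
                    (u[r] * u[r] - (u[r] + d) * (u[r] + d)) /
                        (2 * sigma_u * sigma_u);
        bool acc = mh_accept(lr);
        if (acc) { apply_shift(by_region[r], mu, d); u[r] += d; }
        if (warm) ad.tune(A_U + r, acc ? 1.0 : 0.0, iter);
      }
    }
    // site effects
    if (use_v) {
      for (int si = 0; si < n_site; ++si) {
        double s = ad.scale(A_V + si), d = R::norm_rand() * s;
        double lr = nb_shift_delta(by_site[si], y, mu, std::exp(ltheta), d) +
                    (v[si] * v[si] - (v[si] + d) * (v[si] + d)) /
                        (2 * sigma_v * sigma_v);
        bool acc = mh_accept(lr);
        if (acc) { apply_shift(by_site[si], mu, d); v[si] += d; }
        if (warm) ad.tune(A_V + si, acc ? 1.0 : 0.0, iter);
      }
    }

    if (include_trend) {
      double tau_f = 1.0 / (sigma_f * sigma_f);
      // latent trajectory, single-site updates
      for (int tr = 0; tr < n_traj; ++tr) {
        int off = tr * n_year;
        for (int t = 0; t < n_year; ++t) {
          int j = off + t;
          double s = ad.scale(A_F + j), d = R::norm_rand() * s;
          double ssd0 = local_ssd(f, off, n_year, t);
          f[j] += d;
          double ssd1 = local_ssd(f, off, n_year, t);
          f[j] -= d;
          double lr = -tau_f / 2.0 * (ssd1 - ssd0);
          if (!by_f[j].empty()) {
            lr += nb_shift_delta(by_f[j], y, mu, std::exp(ltheta), d);
          }
          bool acc = mh_accept(lr);
          if (acc) {
            f[j] += d;
            if (!by_f[j].empty()) apply_shift(by_f[j], mu, d);
          }
          if (warm) ad.tune(A_F + j, acc ? 1.0 : 0.0, iter);
        }
      }

      // block moves along smooth shapes: f_t += d * b_k(t). Shape 0 is the
      // linear tilt (RW2 null space, no prior term); shapes 1..K are cosine
      // modes capturing low-frequency curvature that single-site updates
      // reach only slowly. The RW2 prior change is computed exactly from
      // the second differences of the perturbed trajectory.
      for (int tr = 0; tr < n_traj; ++tr) {
        int off = tr * n_year;
        const std::vector<int>& scope = regional ? by_region[tr] : all_idx;
        double theta = std::exp(ltheta);
        for (int k = 0; k <= n_modes; ++k) {
          int aj = A_TILT + tr * (n_modes + 1) + k;
          double s = ad.scale(aj), d = R::norm_rand() * s;
          const std::vector<double>& b = modes[k];
          double lr = 0.0;
          if (k > 0) {
            double ssd0 = total_ssd(f, off, n_year);
            for (int t = 0; t < n_year; ++t) f[off + t] += d * b[t];
            double ssd1 = total_ssd(f, off, n_year);
            for (int t = 0; t < n_year; ++t) f[off + t] -= d * b[t];
            lr += -tau_f / 2.0 * (ssd1 - ssd0);
          }
          for (int i : scope) {
            double sh = d * b[year[i]];
            lr += (theta + y[i]) * (std::log(theta + mu[i]) -
                                    std::log(theta + mu[i] * std::exp(sh))) +
                  sh * y[i];
          }
          bool acc = mh_accept(lr);
          if (acc) {
            for (int t = 0; t < n_year; ++t) f[off + t] += d * b[t];
            for (int i : scope) mu[i] *= std::exp(d * b[year[i]]);
          }
          if (warm) ad.tune(aj, acc ? 1.0 : 0.0, iter);
        }
      }

      // translation moves keep the intrinsic trajectory identified:
      // (f - m, beta0 + m) for the global trend (flat-ish beta0 prior),
      // (f_r - m_r, u_r + m_r) per region (accounted against the u prior)
      if (!regional) {
        double m = 0.0;
        for (int t = 0; t < n_year; ++t) m += f[t];
        m /= n_year;
        double lr = (beta0 * beta0 - (beta0 + m) * (beta0 + m)) /
                    (2 * beta_sd * beta_sd);
        if (mh_accept(lr)) {
          for (int t = 0; t < n_year; ++t) f[t] -= m;
          beta0 += m;
        }
      } else {
        for (int r = 0; r < n_region; ++r) {
          int off = r * n_year;
          double m = 0.0;
          for (int t = 0; t < n_year; ++t) m += f[off + t];
          m /= n_year;
          double lr;
          if (use_u) {
            lr = (u[r] * u[r] - (u[r] + m) * (u[r] + m)) /
                 (2 * sigma_u * sigma_u);
          } else {
            lr = (beta0 * beta0 - (beta0 + m) * (beta0 + m)) /
                 (2 * beta_sd * beta_sd);
          }
          if (mh_accept(lr)) {
            for (int t = 0; t < n_year; ++t) f[off + t] -= m;
            if (use_u) u[r] += m; else beta0 += m;
          }
        }
      }
    }

    // joint level swap between the intercept and all region effects:
    // mu is unchanged, so only the priors enter
    if (use_u) {
      double s = ad.scale(A_SWAP), d = R::norm_rand() * s;
      double lr = (beta0 * beta0 - (beta0 + d) * (beta0 + d)) /
                  (2 * beta_sd * beta_sd);
      for (int r = 0; r < n_region; ++r) {
        lr += (u[r] * u[r] - (u[r] - d) * (u[r] - d)) /
              (2 * sigma_u * sigma_u);
      }
      bool acc = mh_accept(lr);
      if (acc) {
        beta0 += d;
        for (int r = 0; r < n_region; ++r) u[r] -= d;
      }
      if (warm) ad.tune(A_SWAP, acc ? 1.0 : 0.0, iter);
    }
    if (use_v) {
      // same swap between region effects and their sites' effects
      for (int r = 0; r < n_region; ++r) {
        double s = ad.scale(A_SWAPV + r), d = R::norm_rand() * s;
        double lr = (u[r] * u[r] - (u[r] + d) * (u[r] + d)) /
                    (2 * sigma_u * sigma_u);
        int n_sr = 0;
        for (int si = 0; si < n_site; ++si) {
          if (site_region[si] == r) {
            lr += (v[si] * v[si] - (v[si] - d) * (v[si] - d)) /
                  (2 * sigma_v * sigma_v);
            ++n_sr;
          }
        }
        if (n_sr == 0) continue;
        bool acc = mh_accept(lr);
        if (acc) {
          u[r] += d;
          for (int si = 0; si < n_site; ++si) {
            if (site_region[si] == r) v[si] -= d;
          }
        }
        if (warm) ad.tune(A_SWAPV + r, acc ? 1.0 : 0.0, iter);
      }
    }

    // curvature rescale: sigma_f and the non-linear part of f move
    // together (log sigma_f += e, f <- linear part + exp(e) * residual).
    // The RW2 prior terms cancel against the Jacobian, leaving the PC
    // prior and the likelihood under the rescaled trajectory.
    if (include_trend) {
      double s = ad.scale(A_RS), e = R::norm_rand() * s, c = std::exp(e);
      double x0 = std::log(sigma_f), x1 = x0 + e;
      double lr = pc_logprior(std::exp(x1), pc_u_f, pc_alpha_f) + x1 -
                  pc_logprior(std::exp(x0), pc_u_f, pc_alpha_f) - x0;
      std::vector<double> fnew(f);
      double theta = std::exp(ltheta);
      for (int tr = 0; tr < n_traj; ++tr) {
        int off = tr * n_year;
        // least-squares linear fit of the trajectory over t
        double tbar = (n_year - 1.0) / 2.0, sxy = 0.0, sxx = 0.0, fbar = 0.0;
        for (int t = 0; t < n_year; ++t) fbar += f[off + t];
        fbar /= n_year;
        for (int t = 0; t < n_year; ++t) {
          sxy += (t - tbar) * (f[off + t] - fbar);
          sxx += (t - tbar) * (t - tbar);
        }
        double slope = sxx > 0 ? sxy / sxx : 0.0;
        for (int t = 0; t < n_year; ++t) {
          double lin = fbar + slope * (t - tbar);
          fnew[off + t] = lin + c * (f[off + t] - lin);
        }
      }
      for (int i = 0; i < n; ++i) {
        int fi = regional ? region[i] * n_year + year[i] : year[i];
        double sh = fnew[fi] - f[fi];
        if (sh != 0.0) {
          lr += (theta + y[i]) * (std::log(theta + mu[i]) -
                                  std::log(theta + mu[i] * std::exp(sh))) +
                sh * y[i];
        }
      }
      bool acc = mh_accept(lr);
      if (acc) {
        for (int i = 0; i < n; ++i) {
          int fi = regional ? region[i] * n_year + year[i] : year[i];
          mu[i] *= std::exp(fnew[fi] - f[fi]);
        }
        f = fnew;
        sigma_f = std::exp(x1);
      }
      if (warm) ad.tune(A_RS, acc ? 1.0 : 0.0, iter);
    }

    // variance parameters (log-scale MH with PC priors + Jacobian)
    if (use_u) {
      double x = std::log(sigma_u), s = ad.scale(A_SU),
             x1 = x + R::norm_rand() * s;
      double ssq = 0.0;
      for (int r = 0; r < n_region; ++r) ssq += u[r] * u[r];
      double lp0 = -n_region * x - ssq / (2 * std::exp(2 * x)) +
                   pc_logprior(std::exp(x), pc_u_re, pc_alpha_re) + x;
      double lp1 = -n_region * x1 - ssq / (2 * std::exp(2 * x1)) +
                   pc_logprior(std::exp(x1), pc_u_re, pc_alpha_re) + x1;
      bool acc = mh_accept(lp1 - lp0);
      if (acc) sigma_u = std::exp(x1);
      if (warm) ad.tune(A_SU, acc ? 1.0 : 0.0, iter);
    }
    if (use_v) {
      double x = std::log(sigma_v), s = ad.scale(A_SV),
             x1 = x + R::norm_rand() * s;
      double ssq = 0.0;
      for (int si = 0; si < n_site; ++si) ssq += v[si] * v[si];
      double lp0 = -n_site * x - ssq / (2 * std::exp(2 * x)) +
                   pc_logprior(std::exp(x), pc_u_re, pc_alpha_re) + x;
      double lp1 = -n_site * x1 - ssq / (2 * std::exp(2 * x1)) +
                   pc_logprior(std::exp(x1), pc_u_re, pc_alpha_re) + x1;
      bool acc = mh_accept(lp1 - lp0);
      if (acc) sigma_v = std::exp(x1);
      if (warm) ad.tune(A_SV, acc ? 1.0 : 0.0, iter);
    }
    if (include_trend) {
      double ssd = 0.0;
      for (int tr = 0; tr < n_traj; ++tr) ssd += total_ssd(f, tr * n_year, n_year);
      double rank = n_traj * (n_year - 2.0);
      double x = std::log(sigma_f), s = ad.scale(A_SF),
             x1 = x + R::norm_rand() * s;
      // tau = exp(-2x); log tau = -2x
      double lp0 = rank / 2.0 * (-2 * x) - std::exp(-2 * x) / 2.0 * ssd +
                   pc_logprior(std::exp(x), pc_u_f, pc_alpha_f) + x;
      double lp1 = rank / 2.0 * (-2 * x1) - std::exp(-2 * x1) / 2.0 * ssd +
                   pc_logprior(std::exp(x1), pc_u_f, pc_alpha_f) + x1;
      bool acc = mh_accept(lp1 - lp0);
      if (acc) sigma_f = std::exp(x1);
      if (warm) ad.tune(A_SF, acc ? 1.0 : 0.0, iter);
    }

    // dispersion theta, log-uniform prior on [ltheta_lo, ltheta_hi]
    {
      double s = ad.scale(A_TH), x1 = ltheta + R::norm_rand() * s;
      bool acc = false;
      if (x1 >= ltheta_lo && x1 <= ltheta_hi) {
        double lr = nb_theta_part(y, mu, std::exp(x1)) -
                    nb_theta_part(y, mu, std::exp(ltheta));
        acc = mh_accept(lr);
        if (acc) ltheta = x1;
      }
      if (warm) ad.tune(A_TH, acc ? 1.0 : 0.0, iter);
    }

    // store
    if (!warm && ((iter - n_warmup) % thin == 0) && kept < n_keep) {
      int c = 0;
      draws(kept, c++) = beta0;
      draws(kept, c++) = beta_gear;
      for (int r = 0; r < n_region; ++r) draws(kept, c++) = u[r];
      for (int si = 0; si < n_site; ++si) draws(kept, c++) = v[si];
      for (int j = 0; j < n_f; ++j) draws(kept, c++) = f[j];
      draws(kept, c++) = sigma_u;
      draws(kept, c++) = sigma_v;
      draws(kept, c++) = sigma_f;
      draws(kept, c++) = std::exp(ltheta);
      double theta = std::exp(ltheta), lgt = R::lgammafn(theta),
             lt = std::log(theta);
      for (int i = 0; i < n; ++i) {
        loglik(kept, i) = R::lgammafn(y[i] + theta) - lgt - lgam_y1[i] +
                          theta * lt + y[i] * std::log(mu[i]) -
                          (theta + y[i]) * std::log(theta + mu[i]);
      }
      ++kept;
    }
  }

  return List::create(_["draws"] = draws, _["loglik"] = loglik,
                      _["n_f"] = n_f, _["n_traj"] = n_traj);
}

// [[Rcpp::export(name = ".pois_glmm_mcmc")]]
List pois_glmm_mcmc(IntegerVector y, NumericVector log_offset,
                    NumericVector x, IntegerVector region, int n_region,
                    int n_iter, int n_warmup, int thin, List prior) {
  const int n = y.size();
  const double beta_sd = as<double>(prior["beta_sd"]);
  const double pc_u_re = as<double>(prior["pc_u_re"]);
  const double pc_alpha_re = as<double>(prior["pc_alpha_re"]);
  const bool use_u = n_region > 1;

  std::vector<std::vector<int>> by_region(n_region);
  for (int i = 0; i < n; ++i) by_region[region[i]].push_back(i);

  double sum_y = 0.0, sum_off = 0.0;
  for (int i = 0; i < n; ++i) { sum_y += y[i]; sum_off += std::exp(log_offset[i]); }
  double beta0 = std::log((sum_y + 0.5) / sum_off), beta1 = 0.0;
  std::vector<double> u(n_region, 0.0);
  double sigma_u = 0.3;
  std::vector<double> mu(n);
  for (int i = 0; i < n; ++i) mu[i] = std::exp(beta0 + log_offset[i]);

  const int A_B0 = 0, A_B1 = 1, A_U = 2, A_SU = A_U + n_region,
            A_SW = A_SU + 1;
  Adapt ad(A_SW + 1, -1.0);

  // Poisson shift: delta applied as eta += d * w_i
  auto pois_delta = [&](const std::vector<int>& idx, double d,
                        const NumericVector* w) {
    double lr = 0.0;
    for (int i : idx) {
      double sh = w ? d * (*w)[i] : d;
      lr += y[i] * sh - mu[i] * (std::exp(sh) - 1.0);
    }
    return lr;
  };
  auto pois_apply = [&](const std::vector<int>& idx, double d,
                        const NumericVector* w) {
    for (int i : idx) mu[i] *= std::exp(w ? d * (*w)[i] : d);
  };
  std::vector<int> all_idx(n);
  for (int i = 0; i < n; ++i) all_idx[i] = i;

  const int n_keep = (n_iter - n_warmup) / thin;
  NumericMatrix draws(n_keep, 2 + n_region + 1);
  int kept = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    bool warm = iter < n_warmup;
    {
      double s = ad.scale(A_B0), d = R::norm_rand() * s;
      double lr = pois_delta(all_idx, d, nullptr) +
                  (beta0 * beta0 - (beta0 + d) * (beta0 + d)) /
                      (2 * beta_sd * beta_sd);
      bool acc = mh_accept(lr);
      if (acc) { pois_apply(all_idx, d, nullptr); beta0 += d; }
      if (warm) ad.tune(A_B0, acc ? 1.0 : 0.0, iter);
    }
    {
      double s = ad.scale(A_B1), d = R::norm_rand() * s;
      double lr = pois_delta(all_idx, d, &x) +
                  (beta1 * beta1 - (beta1 + d) * (beta1 + d)) /
                      (2 * beta_sd * beta_sd);
      bool acc = mh_accept(lr);
      if (acc) { pois_apply(all_idx, d, &x); beta1 += d; }
      if (warm) ad.tune(A_B1, acc ? 1.0 : 0.0, iter);
    }
    if (use_u) {
      for (int r = 0; r < n_region; ++r) {
        double s = ad.scale(A_U + r), d = R::norm_rand() * s;
        double lr = pois_delta(by_region[r], d, nullptr) +
                    (u[r] * u[r] - (u[r] + d) * (u[r] + d)) /
                        (2 * sigma_u * sigma_u);
        bool acc = mh_accept(lr);
        if (acc) { pois_apply(by_region[r], d, nullptr); u[r] += d; }
        if (warm) ad.tune(A_U + r, acc ? 1.0 : 0.0, iter);
      }
      // likelihood-free level swap between intercept and region effects
      {
        double s = ad.scale(A_SW), d = R::norm_rand() * s;
        double lr = (beta0 * beta0 - (beta0 + d) * (beta0 + d)) /
                    (2 * beta_sd * beta_sd);
        for (int r = 0; r < n_region; ++r) {
          lr += (u[r] * u[r] - (u[r] - d) * (u[r] - d)) /
                (2 * sigma_u * sigma_u);
        }
        bool acc = mh_accept(lr);
        if (acc) {
          beta0 += d;
          for (int r = 0; r < n_region; ++r) u[r] -= d;
        }
        if (warm) ad.tune(A_SW, acc ? 1.0 : 0.0, iter);
      }
      double xx = std::log(sigma_u), s = ad.scale(A_SU),
             x1 = xx + R::norm_rand() * s;
      double ssq = 0.0;
      for (int r = 0; r < n_region; ++r) ssq += u[r] * u[r];
      double lp0 = -n_region * xx - ssq / (2 * std::exp(2 * xx)) +
                   pc_logprior(std::exp(xx), pc_u_re, pc_alpha_re) + xx;
      double lp1 = -n_region * x1 - ssq / (2 * std::exp(2 * x1)) +
                   pc_logprior(std::exp(x1), pc_u_re, pc_alpha_re) + x1;
      bool acc = mh_accept(lp1 - lp0);
      if (acc) sigma_u = std::exp(x1);
      if (warm) ad.tune(A_SU, acc ? 1.0 : 0.0, iter);
    }
    if (!warm && ((iter - n_warmup) % thin == 0) && kept < n_keep) {
      int c = 0;
      draws(kept, c++) = beta0;
      draws(kept, c++) = beta1;
      for (int r = 0; r < n_region; ++r) draws(kept, c++) = u[r];
      draws(kept, c++) = sigma_u;
      ++kept;
    }
  }
  return List::create(_["draws"] = draws);
}
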