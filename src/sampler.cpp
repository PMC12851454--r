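// Componentwise adaptive random-walk Metropolis sampler for the logistic
// developmental-trajectory model.
//
// Unconstrained parameter layout (25 scalars):
//   0:             logit p_infant
//   1 + 6k + 0..5: log a, log b, logit p_adult, a_g, b_g, p_g  (curve k = 0..3)
//
// The positive-quadrant truncation of the (a, b) prior is absorbed by the
// log transform; its normalizing constant is parameter-independent and
// dropped. Jacobians of the log/logit transforms are part of the kernel.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NPAR = 25;
static const int NCELL = 4;

struct Prior {
  double pi_a, pi_b;           // Beta shapes, p_infant (on logit scale: a*log p + b*log(1-p))
  double pa_a, pa_b;           // Beta shapes, p_adult
  double mu_a, mu_b;           // (a, b) normal mean
  double i11, i12, i22;        // (a, b) inverse covariance
  double g_var;                // gender-offset variance
};

static inline double log_invlogit(double u) {
  // log plogis(u), stable for large |u|
  return (u > 0) ? -std::log1p(std::exp(-u)) : u - std::log1p(std::exp(u));
}

static inline double invlogit(double u) {
  return (u > 0) ? 1.0 / (1.0 + std::exp(-u)) : std::exp(u) / (1.0 + std::exp(u));
}

static double log_prior_theta(const std::vector<double>& th, const Prior& pr) {
  double lp = pr.pi_a * log_invlogit(th[0]) + pr.pi_b * log_invlogit(-th[0]);
  for (int k = 0; k < NCELL; ++k) {
    const int base = 1 + 6 * k;
    const double la = th[base], lb = th[base + 1];
    const double a = std::exp(la), b = std::exp(lb);
    const double da = a - pr.mu_a, db = b - pr.mu_b;
    lp += -0.5 * (da * da * pr.i11 + 2.0 * da * db * pr.i12 + db * db * pr.i22)
          + la + lb;  // Jacobian of exp
    const double u = th[base + 2];
    lp += pr.pa_a * log_invlogit(u) + pr.pa_b * log_invlogit(-u);
    for (int j = 3; j < 6; ++j) {
      const double x = th[base + j];
      lp += -0.5 * x * x / pr.g_var;
    }
  }
  return lp;
}

struct CellData {
  std::vector<double> age, z;
  std::vector<int> y;
};

static double cell_loglik(const CellData& cd, const std::vector<double>& th, int k) {
  const int base = 1 + 6 * k;
  const double a = std::exp(th[base]);
  const double b = std::exp(th[base + 1]);
  const double lpa = th[base + 2];
  const double ag = th[base + 3], bg = th[base + 4], pg = th[base + 5];
  const double p_inf = invlogit(th[0]);
  double ll = 0.0;
  const size_t n = cd.age.size();
  for (size_t i = 0; i < n; ++i) {
    const double z = cd.z[i];
    const double a_eff = a + z * ag;
    const double b_eff = b + z * bg;
    const double p_ad = invlogit(lpa + z * pg);
    double p = p_inf + (p_ad - p_inf) * invlogit(b_eff * (cd.age[i] - a_eff));
    // clip inside log terms only, guarding floating-point round-off
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    ll += cd.y[i] ? std::log(p) : std::log1p(-p);
  }
  return ll;
}

// [[Rcpp::export]]
List mh_sampler_cpp(NumericVector age, IntegerVector choice, NumericVector zcode,
                    IntegerVector cell, List prior, NumericVector theta0,
                    LogicalVector free_par, int n_iter, int n_warmup,
                    double scale0) {
  Prior pr;
  NumericVector pis = prior["p_infant_shape"], pas = prior["p_adult_shape"];
  NumericVector mu = prior["ab_mean"];
  NumericMatrix cv = prior["ab_cov"];
  pr.pi_a = pis[0]; pr.pi_b = pis[1];
  pr.pa_a = pas[0]; pr.pa_b = pas[1];
  pr.mu_a = mu[0]; pr.mu_b = mu[1];
  const double det = cv(0, 0) * cv(1, 1) - cv(0, 1) * cv(1, 0);
  pr.i11 = cv(1, 1) / det; pr.i22 = cv(0, 0) / det; pr.i12 = -cv(0, 1) / det;
  const double gsd = as<double>(prior["gender_sd"]);
  pr.g_var = gsd * gsd;

  std::vector<CellData> cells(NCELL);
  const int nrec = age.size();
  for (int i = 0; i < nrec; ++i) {
    const int k = cell[i];
    cells[k].age.push_back(age[i]);
    cells[k].z.push_back(zcode[i]);
    cells[k].y.push_back(choice[i]);
  }

  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> lscale(NPAR, std::log(scale0));
  std::vector<double> accept(NPAR, 0.0), proposals(NPAR, 0.0);

  double lp_prior = log_prior_theta(th, pr);
  std::vector<double> ll_cell(NCELL);
  for (int k = 0; k < NCELL; ++k) ll_cell[k] = cell_loglik(cells[k], th, k);

  const int n_keep = n_iter - n_warmup;
  NumericMatrix draws(n_keep, NPAR);

  for (int iter = 0; iter < n_iter; ++iter) {
    const bool warm = iter < n_warmup;
    const double gamma = warm ? std::pow((double)(iter + 1), -0.6) : 0.0;
    for (int j = 0; j < NPAR; ++j) {
      if (!free_par[j]) continue;
      const double old = th[j];
      th[j] = old + std::exp(lscale[j]) * norm_rand();
      const double lp_prior_new = log_prior_theta(th, pr);
      double delta = lp_prior_new - lp_prior;
      // which cells see this coordinate: p_infant touches all, curve
      // coordinates only their own cell
      double ll_new[NCELL];
      if (j == 0) {
        for (int k = 0; k < NCELL; ++k) {
          ll_new[k] = cell_loglik(cells[k], th, k);
          delta += ll_new[k] - ll_cell[k];
        }
      } else {
        const int k = (j - 1) / 6;
        ll_new[k] = cell_loglik(cells[k], th, k);
        delta += ll_new[k] - ll_cell[k];
      }
      const double alpha = (delta >= 0) ? 1.0 : std::exp(delta);
      proposals[j] += 1.0;
      if (unif_rand() < alpha) {
        accept[j] += 1.0;
        lp_prior = lp_prior_new;
        if (j == 0) {
          for (int k = 0; k < NCELL; ++k) ll_cell[k] = ll_new[k];
        } else {
          const int k = (j - 1) / 6;
          ll_cell[k] = ll_new[k];
        }
      } else {
        th[j] = old;
      }
      if (warm) {
        lscale[j] += gamma * (alpha - 0.44);
        if (lscale[j] < -10.0) lscale[j] = -10.0;
        if (lscale[j] > 5.0) lscale[j] = 5.0;
      }
    }
    if (!warm) {
      const int row = iter - n_warmup;
      for (int j = 0; j < NPAR; ++j) draws(row, j) = th[j];
    }
  }

  NumericVector acc(NPAR), scl(NPAR);
  for (int j = 0; j < NPAR; ++j) {
    acc[j] = proposals[j] > 0 ? accept[j] / proposals[j] : NA_REAL;
    scl[j] = std::exp(lscale[j]);
  }
  return List::create(_["draws"] = draws, _["accept_rate"] = acc,
                      _["scales"] = scl);
}
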