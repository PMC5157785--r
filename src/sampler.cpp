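#include <Rcpp.h>
using namespace Rcpp;

// FGM copula surface on the transformed-marginal scale.
// tanh(gamma/2) == (exp(gamma)-1)/(exp(gamma)+1), stable for large |gamma|.
static inline double fgm_pi(double p, double q, double gamma) {
  return 1.0 - (1.0 - p) * (1.0 - q) +
         p * (1.0 - p) * q * (1.0 - q) * std::tanh(gamma / 2.0);
}

static inline double sigmoid(double x) {
  if (x >= 0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Trinary (SA) or binary (NA) log-likelihood. Dose indices are 0-based.
// y in {0,1,2}; for NA any y != 0 counts as a DLT at the planned combination.
static double log_lik(const IntegerVector& a, const IntegerVector& b,
                      const IntegerVector& y, const NumericVector& skel_p,
                      const NumericVector& skel_q, double alpha, double beta,
                      double gamma, double lambda, bool sa) {
  double ll = 0.0;
  int n = a.size();
  for (int i = 0; i < n; ++i) {
    double p = std::pow(skel_p[a[i]], alpha);
    double q = std::pow(skel_q[b[i]], beta);
    double piT = fgm_pi(p, q, gamma);
    double pr;
    if (sa) {
      double pre = lambda * p;
      if (y[i] == 0)      pr = 1.0 - piT;
      else if (y[i] == 1) pr = pre;
      else                pr = piT - pre;
    } else {
      pr = (y[i] == 0) ? (1.0 - piT) : piT;
    }
    if (!(pr > 0.0)) return R_NegInf;
    ll += std::log(pr);
  }
  return ll;
}

struct Target {
  IntegerVector a, b, y;
  NumericVector skel_p, skel_q;
  bool sa;           // trinary likelihood
  bool lam_est;      // lambda is a sampled parameter
  double lam_fixed;  // used when !lam_est (SA only)
  double a_lo, a_rng, b_lo, b_rng;  // uniform supports for alpha, beta
  double g_mean, g_sd;              // normal prior on gamma
  double l_s1, l_s2;                // Beta prior shapes on lambda

  int n_par() const { return (sa && lam_est) ? 4 : 3; }

  // Unnormalised log posterior on the unconstrained scale u, with Jacobians
  // for the logit transforms of alpha, beta (range scale) and lambda.
  double operator()(const NumericVector& u) const {
    double s1 = sigmoid(u[0]);
    double s2 = sigmoid(u[1]);
    double alpha = a_lo + a_rng * s1;
    double beta = b_lo + b_rng * s2;
    double gamma = u[2];
    double lambda, jac_l = 0.0;
    if (sa && lam_est) {
      double s4 = sigmoid(u[3]);
      lambda = s4;
      if (s4 <= 0.0 || s4 >= 1.0) return R_NegInf;
      jac_l = (l_s1 - 1.0) * std::log(lambda) +
              (l_s2 - 1.0) * std::log(1.0 - lambda) +
              std::log(lambda * (1.0 - lambda));
    } else {
      lambda = sa ? lam_fixed : 0.0;
    }
    if (s1 <= 0.0 || s1 >= 1.0 || s2 <= 0.0 || s2 >= 1.0) return R_NegInf;
    // uniform priors are flat: only the transform Jacobians remain
    double lp = std::log(s1 * (1.0 - s1)) + std::log(s2 * (1.0 - s2)) +
                R::dnorm(gamma, g_mean, g_sd, 1) + jac_l;
    if (!std::isfinite(lp)) return R_NegInf;
    double ll = log_lik(a, b, y, skel_p, skel_q, alpha, beta, gamma, lambda, sa);
    return lp + ll;
  }
};

// Adaptive component-wise random-walk Metropolis.
//
// Chains start at the prior medians, jittered; step sizes adapt during
// burn-in toward an acceptance rate of 0.44 per component and are then
// frozen. Draws are returned on the natural parameter scale.
// [[Rcpp::export]]
List rwm_sample(IntegerVector a_idx, IntegerVector b_idx, IntegerVector y,
                NumericVector skel_p, NumericVector skel_q,
                bool sa, bool lam_est, double lam_fixed,
                NumericVector alpha_range, NumericVector beta_range,
                double gamma_mean, double gamma_var,
                double lam_shape1, double lam_shape2,
                int n_chains, int burn_in, int keep, int thin,
                double init_jitter) {
  Target tgt;
  tgt.a = a_idx; tgt.b = b_idx; tgt.y = y;
  tgt.skel_p = skel_p; tgt.skel_q = skel_q;
  tgt.sa = sa; tgt.lam_est = lam_est; tgt.lam_fixed = lam_fixed;
  tgt.a_lo = alpha_range[0]; tgt.a_rng = alpha_range[1] - alpha_range[0];
  tgt.b_lo = beta_range[0]; tgt.b_rng = beta_range[1] - beta_range[0];
  tgt.g_mean = gamma_mean; tgt.g_sd = std::sqrt(gamma_var);
  tgt.l_s1 = lam_shape1; tgt.l_s2 = lam_shape2;

  const int d = tgt.n_par();
  const int total = n_chains * keep;
  NumericMatrix draws(total, 4);  // alpha, beta, gamma, lambda
  IntegerVector chain_id(total), iter_id(total);
  NumericMatrix acc_rate(n_chains, d);

  // unconstrained-scale prior medians
  double lam_med = lam_est ? R::qbeta(0.5, lam_shape1, lam_shape2, 1, 0) : lam_fixed;
  int row = 0;
  for (int ch = 0; ch < n_chains; ++ch) {
    NumericVector u(d);
    double lp = R_NegInf;
    for (int attempt = 0; attempt < 100 && !std::isfinite(lp); ++attempt) {
      u[0] = R::rnorm(0.0, init_jitter);             // alpha at mid-range
      u[1] = R::rnorm(0.0, init_jitter);             // beta at mid-range
      u[2] = gamma_mean + R::rnorm(0.0, init_jitter);
      if (d == 4) {
        double m = std::log(lam_med / (1.0 - lam_med));
        u[3] = m + R::rnorm(0.0, init_jitter);
      }
      lp = tgt(u);
    }
    if (!std::isfinite(lp))
      stop("could not initialise the sampler at a point of finite posterior density");

    NumericVector step(d, 0.5);
    IntegerVector acc_win(d), try_win(d), acc_tot(d), try_tot(d);
    const int n_iter = burn_in + keep * thin;
    for (int it = 0; it < n_iter; ++it) {
      for (int c = 0; c < d; ++c) {
        double old = u[c];
        u[c] = old + step[c] * R::rnorm(0.0, 1.0);
        double lp_new = tgt(u);
        ++try_win[c];
        if (std::log(R::runif(0.0, 1.0)) < lp_new - lp) {
          lp = lp_new;
          ++acc_win[c];
        } else {
          u[c] = old;
        }
      }
      if (it < burn_in && (it + 1) % 50 == 0) {
        for (int c = 0; c < d; ++c) {
          double r = (double)acc_win[c] / try_win[c];
          step[c] *= std::exp(r - 0.44);
          if (step[c] < 1e-3) step[c] = 1e-3;
          if (step[c] > 10.0) step[c] = 10.0;
          acc_win[c] = try_win[c] = 0;
        }
      }
      if (it >= burn_in) {
        for (int c = 0; c < d; ++c) {
          acc_tot[c] += acc_win[c];
          try_tot[c] += try_win[c];
          acc_win[c] = try_win[c] = 0;
        }
        int post = it - burn_in;
        if ((post + 1) % thin == 0) {
          draws(row, 0) = tgt.a_lo + tgt.a_rng * sigmoid(u[0]);
          draws(row, 1) = tgt.b_lo + tgt.b_rng * sigmoid(u[1]);
          draws(row, 2) = u[2];
          draws(row, 3) = (d == 4) ? sigmoid(u[3]) : (sa ? lam_fixed : NA_REAL);
          chain_id[row] = ch + 1;
          iter_id[row] = (post + 1) / thin;
          ++row;
        }
      }
    }
    for (int c = 0; c < d; ++c) {
      acc_rate(ch, c) = try_tot[c] > 0 ? (double)acc_tot[c] / try_tot[c] : NA_REAL;
    }
  }
  return List::create(_["draws"] = draws, _["chain"] = chain_id,
                      _["iter"] = iter_id, _["acceptance"] = acc_rate);
}

// pi_T over the grid for a matrix of parameter draws: returns a matrix with
// one row per draw and one column per (j, k) combination, k varying fastest
// within j... (column-major over j then k: column index = (k-1)*J + j).
// [[Rcpp::export]]
NumericMatrix pi_surface_draws(NumericMatrix draws, NumericVector skel_p,
                               NumericVector skel_q) {
  int n = draws.nrow(), J = skel_p.size(), K = skel_q.size();
  NumericMatrix out(n, J * K);
  for (int i = 0; i < n; ++i) {
    double alpha = draws(i, 0), beta = draws(i, 1), gamma = draws(i, 2);
    double th = std::tanh(gamma / 2.0);
    for (int k = 0; k < K; ++k) {
      double q = std::pow(skel_q[k], beta);
      for (int j = 0; j < J; ++j) {
        double p = std::pow(skel_p[j], alpha);
        out(i, k * J + j) =
            1.0 - (1.0 - p) * (1.0 - q) + p * (1.0 - p) * q * (1.0 - q) * th;
      }
    }
  }
  return out;
}
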