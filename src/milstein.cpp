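#include <Rcpp.h>
using namespace Rcpp;

// One-regime drift, diffusion and Milstein correction, kept in exact
// agreement with the R reference implementations in R/dynamics.R.
static inline double incidence(double S, double I, double beta, double alpha,
                               double h) {
  if (S <= 0.0 || I <= 0.0) return 0.0;
  double Sh = std::pow(S, h);
  return beta * Sh * I / (Sh + alpha * std::pow(I, h));
}

struct Coefs {
  double aS, aI, b, c; // bS = -b? see below: b is the I-component, bS = -b
};

static inline Coefs coefs(double S, double I, const double *p, double h) {
  // p: Lambda, mu, beta, alpha, gamma, epsilon, sigma2
  Coefs out;
  double g = incidence(S, I, p[2], p[3], h);
  out.aS = p[0] - p[1] * S - g;
  out.aI = g - (p[1] + p[4] + p[5]) * I;
  double sigma = std::sqrt(p[6]);
  double f = 0.0, cS = 0.0;
  if (S > 0.0 && I > 0.0 && p[6] > 0.0) {
    double Sh = std::pow(S, h);
    double Ih = std::pow(I, h);
    double D = Sh + p[3] * Ih;
    f = sigma * Sh * I / D;
    double fS = sigma * I * h * std::pow(S, h - 1.0) * p[3] * Ih / (D * D);
    double fI = sigma * Sh * (Sh + p[3] * Ih - p[3] * h * Ih) / (D * D);
    cS = f * (fS - fI);
  }
  out.b = f;   // b_I = f, b_S = -f
  out.c = cS;  // c_S = cS, c_I = -cS
  return out;
}

// Milstein path over a prescribed sub-step schedule.
//
// t_sub:      m+1 sub-step boundary times (increasing, t_sub[0] = 0)
// regime_sub: m regime indices (1-based), regime in force on each interval
// pars:       N x 7 matrix, rows (Lambda, mu, beta, alpha, gamma, eps, sigma2)
// dB_in:      optional vector of m Brownian increments; when supplied the
//             path is fully determined by it (no resampling on boundary
//             violations, only clamping), which is what the coupled
//             strong-order refinement needs.
//
// Boundary policy: if a step takes I below floor_I, I is set to 0 and stays
// there (absorbing, as for the exact dynamics). If a step takes S <= 0 the
// increment is resampled once, then S is clamped to 1e-12.
// [[Rcpp::export]]
List milstein_path_cpp(NumericVector t_sub, IntegerVector regime_sub,
                       NumericMatrix pars, double h, double S0, double I0,
                       double floor_I,
                       Nullable<NumericVector> dB_in = R_NilValue) {
  const int m = regime_sub.size();
  if (t_sub.size() != m + 1)
    stop("t_sub must have one more element than regime_sub");
  NumericVector S(m + 1), I(m + 1);
  S[0] = S0;
  I[0] = I0;
  bool use_dB = dB_in.isNotNull();
  NumericVector dB;
  if (use_dB) {
    dB = NumericVector(dB_in);
    if (dB.size() != m) stop("dB must have length equal to regime_sub");
  }
  int n_resampled = 0, n_clamped = 0;
  bool absorbed = (I0 <= 0.0);
  double min_I = I0;
  double s = S0, i = I0;

  for (int k = 0; k < m; ++k) {
    double dt = t_sub[k + 1] - t_sub[k];
    int r = regime_sub[k] - 1;
    if (r < 0 || r >= pars.nrow()) stop("regime index out of range");
    const double p[7] = {pars(r, 0), pars(r, 1), pars(r, 2), pars(r, 3),
                         pars(r, 4), pars(r, 5), pars(r, 6)};
    double db = use_dB ? dB[k] : R::norm_rand() * std::sqrt(dt);
    Coefs cf = coefs(s, i, p, h);
    // Tamed correction: near the S = 0 boundary the gradient product blows
    // up like S^(h-1); drop it when it stops being a small refinement of
    // the Euler-Maruyama step (same rule as milstein_step in R).
    if (std::abs(cf.c) * dt > std::abs(cf.b)) cf.c = 0.0;
    double corr = 0.5 * cf.c * (db * db - dt);
    double s_new = s + cf.aS * dt - cf.b * db + corr;
    double i_new = i + cf.aI * dt + cf.b * db - corr;
    if (s_new <= 0.0 && !use_dB) {
      db = R::norm_rand() * std::sqrt(dt);
      ++n_resampled;
      corr = 0.5 * cf.c * (db * db - dt);
      s_new = s + cf.aS * dt - cf.b * db + corr;
      i_new = i + cf.aI * dt + cf.b * db - corr;
    }
    if (s_new <= 0.0) {
      s_new = 1e-12;
      ++n_clamped;
    }
    if (!absorbed && i_new < floor_I) {
      i_new = 0.0;
      absorbed = true;
    }
    if (absorbed) i_new = 0.0;
    if (!std::isfinite(s_new) || !std::isfinite(i_new))
      stop("non-finite state during Milstein integration");
    s = s_new;
    i = i_new;
    if (i < min_I) min_I = i;
    S[k + 1] = s;
    I[k + 1] = i;
  }
  return List::create(_["S"] = S, _["I"] = I,
                      _["n_resampled"] = n_resampled,
                      _["n_clamped"] = n_clamped,
                      _["absorbed"] = absorbed,
                      _["min_I"] = min_I);
}
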