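#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-algorithm negative log-likelihood of pooled observation
// streams under the movement HMM.
//
// Emissions per state s:
//   step (sqrt-km): NA -> 1; exact zero -> zero-mass atom; positive ->
//     (1 - zero mass) * Gamma(x; shape, scale), computed from precomputed
//     log(x) so each evaluation is a handful of flops + one exp.
//   |angle| (rad): NA -> 1; else Weibull density renormalised over (0, pi]
//     and halved (symmetric sign).
// Transitions: multinomial logit with diagonal reference,
//   eta_ij(h) = b0_ij + b1_ij cos(2 pi h/24) + b2_ij sin(2 pi h/24),
// with the solar hour quantised to the integer grid 0..23 (hourly sampling),
// so only 24 matrices are built per evaluation. Streams restart from delta.
//
// [[Rcpp::export]]
double hmm_nll_cpp(NumericVector step, NumericVector log_step,
                   NumericVector angle, NumericVector log_angle,
                   IntegerVector hour_idx, // 0..23 per interval
                   IntegerVector stream_start, // 0-based first index per stream
                   NumericVector step_mean, NumericVector step_sd,
                   NumericVector zero_mass,
                   NumericVector ang_shape, NumericVector ang_scale,
                   NumericMatrix beta, // N*(N-1) x K (K = 1 or 3)
                   NumericVector delta) {
  const int T = step.size();
  const int N = step_mean.size();
  const int K = beta.ncol();

  // per-state emission constants
  std::vector<double> shape(N), inv_scale(N), lconst_step(N), log1m_z(N);
  std::vector<double> wshape(N), lconst_ang(N), wls(N);
  for (int s = 0; s < N; ++s) {
    double m = step_mean[s], sd = step_sd[s];
    if (!R_finite(m) || !R_finite(sd) || m <= 0 || sd <= 0) return 1e10;
    shape[s] = m * m / (sd * sd);
    double scale = sd * sd / m;
    inv_scale[s] = 1.0 / scale;
    lconst_step[s] = -R::lgammafn(shape[s]) - shape[s] * std::log(scale);
    double z = zero_mass[s];
    if (z < 0 || z >= 1) return 1e10;
    log1m_z[s] = std::log1p(-z);
    double ws = ang_shape[s], wsc = ang_scale[s];
    if (!R_finite(ws) || ws <= 0 || !R_finite(wsc) || wsc <= 0) return 1e10;
    double wnorm = R::pweibull(M_PI, ws, wsc, 1, 0);
    if (wnorm <= 0) return 1e10;
    wshape[s] = ws;
    wls[s] = std::log(wsc);
    lconst_ang[s] = std::log(0.5) + std::log(ws) - ws * wls[s] - std::log(wnorm);
  }

  // 24 transition matrices
  std::vector<double> gamma(24 * N * N);
  for (int h = 0; h < 24; ++h) {
    double c = std::cos(2.0 * M_PI * h / 24.0);
    double sn = std::sin(2.0 * M_PI * h / 24.0);
    int r = 0;
    double* g = &gamma[h * N * N];
    for (int i = 0; i < N; ++i) {
      double rowsum = 1.0; // diagonal reference exp(0)
      for (int j = 0; j < N; ++j) {
        if (i == j) { g[i * N + j] = 1.0; continue; }
        double eta = beta(r, 0);
        if (K >= 3) eta += beta(r, 1) * c + beta(r, 2) * sn;
        double e = std::exp(eta);
        if (!R_finite(e)) return 1e10;
        g[i * N + j] = e;
        rowsum += e;
        ++r;
      }
      for (int j = 0; j < N; ++j) g[i * N + j] /= rowsum;
    }
  }

  std::vector<double> alpha(N), tmp(N), f(N);
  double ll = 0.0;
  int next_stream = 0;
  const int n_streams = stream_start.size();

  for (int t = 0; t < T; ++t) {
    const bool has_step = !ISNAN(step[t]);
    const bool has_ang = !ISNAN(angle[t]);
    for (int s = 0; s < N; ++s) {
      double lf = 0.0;
      if (has_step) {
        if (step[t] == 0.0) {
          double z = zero_mass[s];
          if (z <= 0.0) { f[s] = 0.0; continue; }
          lf += std::log(z);
        } else {
          lf += log1m_z[s] + lconst_step[s] +
                (shape[s] - 1.0) * log_step[t] - step[t] * inv_scale[s];
        }
      }
      if (has_ang) {
        lf += lconst_ang[s] + (wshape[s] - 1.0) * log_angle[t] -
              std::exp(wshape[s] * (log_angle[t] - wls[s]));
      }
      f[s] = std::exp(lf);
    }

    bool restart = (next_stream < n_streams && stream_start[next_stream] == t);
    if (restart) {
      ++next_stream;
      for (int s = 0; s < N; ++s) alpha[s] = delta[s] * f[s];
    } else {
      const double* g = &gamma[hour_idx[t] * N * N];
      for (int j = 0; j < N; ++j) {
        double acc = 0.0;
        for (int i = 0; i < N; ++i) acc += alpha[i] * g[i * N + j];
        tmp[j] = acc * f[j];
      }
      std::swap(alpha, tmp);
    }

    double c = 0.0;
    for (int s = 0; s < N; ++s) c += alpha[s];
    if (!(c > 0) || !R_finite(c)) return 1e10;
    for (int s = 0; s < N; ++s) alpha[s] /= c;
    ll += std::log(c);
  }
  if (!R_finite(ll)) return 1e10;
  return -ll;
}
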