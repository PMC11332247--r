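#include <Rcpp.h>
using namespace Rcpp;

// Truncated-normal draw (lower bound 0) by rejection; sd <= 0 degenerates to
// max(mean, 0) and consumes no random numbers, which keeps RNG streams of
// no-shift and shift-at-zero parameterisations exactly aligned.
static double trunc_norm0(double mean, double sd) {
  if (sd <= 0.0) return mean > 0.0 ? mean : 0.0;
  for (int i = 0; i < 1000; ++i) {
    double v = R::rnorm(mean, sd);
    if (v >= 0.0) return v;
  }
  return 0.0;
}

// Time course of the expected automatic activation's derivative (DMC):
// d/dt [ zeta * (t/tp)^(alpha-1) * exp(-(alpha-1)(t-tp)/tp) ]
static double auto_drift(double t, double zeta, double tp, double alpha) {
  double am1 = alpha - 1.0;
  return zeta * std::pow(t / tp, am1) * std::exp(-am1 * (t - tp) / tp) *
         am1 * (1.0 / t - 1.0 / tp);
}

//' @keywords internal
// [[Rcpp::export(name = ".sim_diffusion_cpp")]]
List sim_diffusion_cpp(int n, int model,
                       double bound, double z_rel,
                       double drift, double zeta, double t_peak, double alpha,
                       double t0_mean, double t0_sd,
                       double shift_delta, double shift_time_mean,
                       double shift_time_sd,
                       double sigma, double dt, double deadline) {
  NumericVector rt(n, NA_REAL);
  IntegerVector response(n, NA_INTEGER);
  LogicalVector censored(n);
  double sq = sigma * std::sqrt(dt);

  for (int i = 0; i < n; ++i) {
    double t0 = trunc_norm0(t0_mean, t0_sd);
    double ts = trunc_norm0(shift_time_mean, shift_time_sd);

    double up0, lo0, x;
    if (model == 0) {            // DDM: bounds at 0 and a, start z_rel * a
      up0 = bound; lo0 = 0.0; x = z_rel * bound;
    } else {                     // DMC: bounds at +-b, start 0
      up0 = bound; lo0 = -bound; x = 0.0;
    }

    bool done = false;
    double t = 0.0;
    while (t0 + t < deadline) {
      bool shifted = (t >= ts);
      double up = up0, lo = lo0;
      if (shifted) {
        if (model == 0) { up = up0 + shift_delta / 2.0; lo = lo0 - shift_delta / 2.0; }
        else            { up = up0 + shift_delta;       lo = lo0 - shift_delta; }
      }
      if (x >= up) { rt[i] = t0 + t; response[i] = 1;  done = true; break; }
      if (x <= lo) { rt[i] = t0 + t; response[i] = -1; done = true; break; }
      double mu = (model == 0) ? drift
                               : drift + auto_drift(t + dt / 2.0, zeta, t_peak, alpha);
      x += mu * dt + sq * norm_rand();
      t += dt;
    }
    if (!done) censored[i] = true;
  }
  return List::create(_["rt"] = rt, _["response"] = response,
                      _["censored"] = censored);
}
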