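#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama first passages of the drift diffusion process
//   d theta = v dt + sigma dW
// started at z_rel * a with absorbing boundaries {0, a}.  Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
List ddm_sim_cpp(int n, NumericVector a, NumericVector v, NumericVector z_rel,
                 double sigma, double dt, double t_max) {
  NumericVector t_out(n);
  IntegerVector upper(n);
  const double sddt = sigma * std::sqrt(dt);
  const int max_steps = (int)(t_max / dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double theta = z_rel[i] * a[i];
    const double vi = v[i], ai = a[i];
    int step = 0;
    bool done = false;
    while (step < max_steps) {
      theta += vi * dt + sddt * norm_rand();
      ++step;
      if (theta >= ai) { upper[i] = 1; done = true; break; }
      if (theta <= 0.0) { upper[i] = 0; done = true; break; }
    }
    if (done) {
      t_out[i] = step * dt;
    } else {
      t_out[i] = NA_REAL;
      upper[i] = NA_INTEGER;
    }
  }
  return List::create(_["t"] = t_out, _["upper"] = upper);
}
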