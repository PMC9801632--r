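#include <Rcpp.h>
using namespace Rcpp;

// Shot (Poisson) + read (Gaussian) noise in a single pass over a stack,
// clipped at zero. Uses R's RNG so results are reproducible under
// set.seed().
// [[Rcpp::export]]
NumericVector shot_read_noise(NumericVector x, double read_sd, bool poisson) {
  R_xlen_t n = x.size();
  NumericVector out(no_init(n));
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    double y = poisson ? R::rpois(v > 0.0 ? v : 0.0) : v;
    if (read_sd > 0.0) y += R::norm_rand() * read_sd;
    out[i] = y > 0.0 ? y : 0.0;
  }
  return out;
}
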