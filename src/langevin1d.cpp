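#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) on a tabulated 1D force field with
// reflecting boundaries. The force grid is precomputed in R (reference
// gradient + analytic bias); linear interpolation between grid nodes.
// Uses R's RNG so set.seed() governs determinism.
// [[Rcpp::export]]
NumericVector sim_overdamped_1d(double x0, double x_lo, double x_hi,
                                NumericVector force_grid, double grid_x0,
                                double grid_h, double mobility, double dt,
                                int n_steps, int save_stride,
                                double noise_sd) {
  if (save_stride < 1) stop("save_stride must be >= 1");
  int n_save = n_steps / save_stride;
  NumericVector out(n_save);
  double x = x0;
  int ng = force_grid.size();
  int k = 0;
  for (int s = 1; s <= n_steps; ++s) {
    double u = (x - grid_x0) / grid_h;
    int i = (int)std::floor(u);
    if (i < 0) i = 0;
    if (i > ng - 2) i = ng - 2;
    double w = u - i;
    if (w < 0.0) w = 0.0;
    if (w > 1.0) w = 1.0;
    double F = force_grid[i] * (1.0 - w) + force_grid[i + 1] * w;
    x += mobility * F * dt + noise_sd * R::norm_rand();
    // reflecting boundaries (loop handles multi-bounce for large kicks)
    int guard = 0;
    while ((x < x_lo || x > x_hi) && guard++ < 64) {
      if (x < x_lo) x = 2.0 * x_lo - x;
      if (x > x_hi) x = 2.0 * x_hi - x;
    }
    if (x < x_lo) x = x_lo;
    if (x > x_hi) x = x_hi;
    if (s % save_stride == 0) out[k++] = x;
  }
  return out;
}
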