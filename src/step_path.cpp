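#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of the two-attractor cursor simulator. Per 60-Hz step the
// deterministic velocity is the mixture of a pull toward the responded
// button and a linearly decaying pull of strength lambda toward the
// competitor button, renormalized to constant speed (conflict bends the
// path, it does not accelerate the hand); isotropic Gaussian motor noise
// is added on top. Uses R's RNG so results are reproducible under
// set.seed().
//
// Returns a list: ok (logical; FALSE = step cap hit before reaching the
// button) and path (n x 2 matrix of positions AFTER each step).
// [[Rcpp::export]]
List step_path_cpp(NumericVector start, NumericVector target,
                   NumericVector other, double lambda, double base_speed,
                   double noise_sd, double w_frac, double stop_radius,
                   int max_steps) {
  std::vector<double> xs, ys;
  xs.reserve(128); ys.reserve(128);
  double x = start[0], y = start[1];
  double dx0 = target[0] - x, dy0 = target[1] - y;
  double dist0 = std::sqrt(dx0 * dx0 + dy0 * dy0);
  // conflict decays to zero over the first w_frac of the ideal path length
  double horizon = (base_speed > 0) ? w_frac * dist0 / base_speed : 0.0;
  bool ok = false;
  {
    double tx = target[0] - x, ty = target[1] - y;
    if (std::sqrt(tx * tx + ty * ty) <= stop_radius) ok = true;
  }
  int i = 0;
  while (!ok && i < max_steps) {
    double tx = target[0] - x, ty = target[1] - y;
    double dt = std::sqrt(tx * tx + ty * ty);
    double vx = base_speed * tx / dt;
    double vy = base_speed * ty / dt;
    double w = (horizon > 0) ? std::max(0.0, 1.0 - i / horizon) : 0.0;
    if (lambda != 0.0 && w > 0) {
      double ox = other[0] - x, oy = other[1] - y;
      double dob = std::sqrt(ox * ox + oy * oy);
      if (dob > 0) {
        vx += lambda * w * ox / dob;
        vy += lambda * w * oy / dob;
      }
      double vnorm = std::sqrt(vx * vx + vy * vy);
      if (vnorm > 1e-12) {
        vx = base_speed * vx / vnorm;
        vy = base_speed * vy / vnorm;
      } else {  // exactly cancelling pulls: fall back to the target pull
        vx = base_speed * tx / dt;
        vy = base_speed * ty / dt;
      }
    }
    if (noise_sd > 0) {
      vx += R::rnorm(0.0, noise_sd);
      vy += R::rnorm(0.0, noise_sd);
    }
    x += vx; y += vy;
    xs.push_back(x); ys.push_back(y);
    ++i;
    double rx = target[0] - x, ry = target[1] - y;
    if (std::sqrt(rx * rx + ry * ry) <= stop_radius) ok = true;
  }
  int n = xs.size();
  NumericMatrix path(n, 2);
  for (int j = 0; j < n; ++j) { path(j, 0) = xs[j]; path(j, 1) = ys[j]; }
  return List::create(_["ok"] = ok, _["path"] = path);
}
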