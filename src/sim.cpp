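#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin dynamics of hard-sphere vesicles in a cuboid with
// five reflecting faces and one absorbing membrane face (the y = 0 plane).
// Internal units: micrometres and seconds. Randomness comes from R's RNG
// (norm_rand / unif_rand) so runs are reproducible under set.seed().

static inline double fold(double x, double lo, double hi) {
  for (int it = 0; it < 64 && (x < lo || x > hi); ++it) {
    if (x < lo) x = 2.0 * lo - x;
    else if (x > hi) x = 2.0 * hi - x;
  }
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

// Push overlapping pairs apart symmetrically along the centre line to
// contact distance 2*radius, midpoint preserved; iterate up to max_sweeps.
// Operates on the raw column-major array (x | y | z). Returns the number
// of still-overlapping pairs afterwards.
static int resolve_raw(double *p, int n, double radius, int max_sweeps) {
  const double dmin = 2.0 * radius, dmin2 = dmin * dmin;
  double *X = p, *Y = p + n, *Z = p + 2 * n;
  for (int s = 0; s < max_sweeps; ++s) {
    bool any = false;
    for (int i = 0; i < n - 1; ++i) {
      const double xi = X[i], yi = Y[i], zi = Z[i];
      for (int j = i + 1; j < n; ++j) {
        double ux = X[j] - xi;
        if (ux > dmin || ux < -dmin) continue;
        double uy = Y[j] - yi;
        if (uy > dmin || uy < -dmin) continue;
        double uz = Z[j] - zi;
        double d2 = ux * ux + uy * uy + uz * uz;
        if (d2 < dmin2 * (1.0 - 1e-12)) {
          any = true;
          double d = std::sqrt(d2);
          if (d < 1e-12) {  // coincident centres: pick a random direction
            ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
            d = std::sqrt(ux * ux + uy * uy + uz * uz);
          }
          double corr = 0.5 * (dmin - std::sqrt(d2)) / d;
          X[i] -= ux * corr; Y[i] -= uy * corr; Z[i] -= uz * corr;
          X[j] += ux * corr; Y[j] += uy * corr; Z[j] += uz * corr;
        }
      }
    }
    if (!any) return 0;
  }
  int cnt = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double ux = X[j] - X[i], uy = Y[j] - Y[i], uz = Z[j] - Z[i];
      if (ux * ux + uy * uy + uz * uz < dmin2 * (1.0 - 1e-9)) ++cnt;
    }
  return cnt;
}

static int resolve_sweeps(NumericMatrix &pos, double radius, int max_sweeps) {
  return resolve_raw(REAL(pos), pos.nrow(), radius, max_sweeps);
}

// Draw a fresh, non-overlapping position for vesicle idx.
static void replace_vesicle(NumericMatrix &pos, int idx, double Lx, double Ly,
                            double Lz, double radius, bool far_wall) {
  int n = pos.nrow();
  const double dmin2 = 4.0 * radius * radius;
  for (int attempt = 0; attempt < 1000; ++attempt) {
    double x = radius + unif_rand() * (Lx - 2.0 * radius);
    double z = radius + unif_rand() * (Lz - 2.0 * radius);
    double y = far_wall ? (Ly - radius)
                        : radius + unif_rand() * (Ly - 2.0 * radius);
    bool ok = true;
    for (int j = 0; j < n; ++j) {
      if (j == idx) continue;
      double ux = pos(j, 0) - x, uy = pos(j, 1) - y, uz = pos(j, 2) - z;
      if (ux * ux + uy * uy + uz * uz < dmin2) { ok = false; break; }
    }
    if (ok) {
      pos(idx, 0) = x; pos(idx, 1) = y; pos(idx, 2) = z;
      return;
    }
  }
  stop("replacement packing failure: no non-overlapping position found");
}

// [[Rcpp::export]]
NumericMatrix reflect_positions_cpp(NumericMatrix positions, double Lx,
                                    double Ly, double Lz, double radius,
                                    bool reflect_bottom) {
  NumericMatrix pos = clone(positions);
  int n = pos.nrow();
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = fold(pos(i, 0), radius, Lx - radius);
    pos(i, 2) = fold(pos(i, 2), radius, Lz - radius);
    if (reflect_bottom) {
      pos(i, 1) = fold(pos(i, 1), radius, Ly - radius);
    } else if (pos(i, 1) > Ly - radius) {
      pos(i, 1) = 2.0 * (Ly - radius) - pos(i, 1);
    }
  }
  return pos;
}

// [[Rcpp::export]]
List resolve_overlaps_cpp(NumericMatrix positions, double radius,
                          int max_sweeps) {
  NumericMatrix pos = clone(positions);
  int unresolved = resolve_sweeps(pos, radius, max_sweeps);
  return List::create(_["positions"] = pos, _["unresolved"] = unresolved);
}

// [[Rcpp::export]]
List sim_core(NumericMatrix positions, double Lx, double Ly, double Lz,
              double radius, double sd_step, double drift_rate,
              double vy_const, double dt, int max_events, double max_time,
              int max_steps, bool absorbing, bool far_wall, bool noise_on,
              bool resolve, int sample_y_every, double t_start) {
  NumericMatrix pos = clone(positions);
  int n = pos.nrow();
  std::vector<double> events;
  std::vector<double> ysamples;
  if (max_events > 0) events.reserve(max_events);
  const double xlo = radius, xhi = Lx - radius;
  const double zlo = radius, zhi = Lz - radius;
  const double ylo = radius, yhi = Ly - radius;
  long steps = 0;
  int unresolved = 0;
  double t = t_start;
  std::vector<int> hits;
  double *X = REAL(pos), *Y = X + n, *Z = X + 2 * n;
  while ((max_events <= 0 || (int)events.size() < max_events) &&
         t < max_time && (max_steps <= 0 || steps < max_steps)) {
    ++steps;
    t = t_start + (double)steps * dt;
    for (int i = 0; i < n; ++i) {
      double dx = 0.0, dy = 0.0, dz = 0.0;
      if (noise_on) {
        dx = norm_rand() * sd_step;
        dy = norm_rand() * sd_step;
        dz = norm_rand() * sd_step;
      }
      // explicit Euler-Maruyama; harmonic drift acts on y only
      dy += (vy_const - drift_rate * Y[i]) * dt;
      X[i] = fold(X[i] + dx, xlo, xhi);
      Z[i] = fold(Z[i] + dz, zlo, zhi);
      double y = Y[i] + dy;
      if (absorbing) {
        if (y > yhi) y = 2.0 * yhi - y;  // top wall only; bottom is membrane
      } else {
        y = fold(y, ylo, yhi);
      }
      Y[i] = y;
    }
    if (resolve && n > 1) unresolved += resolve_raw(X, n, radius, 10);
    if (absorbing) {
      hits.clear();
      for (int i = 0; i < n; ++i)
        if (Y[i] <= radius) hits.push_back(i);
      int m = (int)hits.size();
      for (int j = 0; j < m; ++j) {
        // same-step arrivals are spread evenly across the step so event
        // times stay strictly increasing
        events.push_back(t - dt + dt * (double)(j + 1) / (double)m);
        replace_vesicle(pos, hits[j], Lx, Ly, Lz, radius, far_wall);
      }
    }
    if (sample_y_every > 0 && steps % sample_y_every == 0) {
      for (int i = 0; i < n; ++i) ysamples.push_back(Y[i]);
    }
    if (steps % 262144 == 0) checkUserInterrupt();
  }
  return List::create(_["events"] = wrap(events),
                      _["time"] = t,
                      _["positions"] = pos,
                      _["steps"] = (double)steps,
                      _["unresolved"] = unresolved,
                      _["y_samples"] = wrap(ysamples));
}
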