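#include <Rcpp.h>
using namespace Rcpp;

// Vicsek-like alignment escape model in a circular two-exit arena.
//
// RNG consumption (R's stream): per particle at init — radial draw, angular
// draw, heading draw. The update itself is noise-free. Mirrors init_arena()
// and the R-level alignment_update()/reflect_disc() primitives.

static inline void reflect_step(double &x, double &y, double &hx, double &hy,
                                double speed, double radius) {
  double dx = speed * hx, dy = speed * hy;
  const double inner = radius * (1.0 - 1e-12);
  for (int iter = 0; iter < 16; ++iter) {
    double pnx = x + dx, pny = y + dy;
    if (std::sqrt(pnx * pnx + pny * pny) <= inner) {
      x = pnx; y = pny;
      break;
    }
    double a = dx * dx + dy * dy;
    double b = 2.0 * (x * dx + y * dy);
    double c = x * x + y * y - radius * radius;
    double disc = std::max(b * b - 4.0 * a * c, 0.0);
    double t = (-b + std::sqrt(disc)) / (2.0 * a);
    t = std::min(std::max(t, 0.0), 1.0);
    double qx = x + t * dx, qy = y + t * dy;
    double qn = std::sqrt(qx * qx + qy * qy);
    double nx = qx / qn, ny = qy / qn;
    double rx = (1.0 - t) * dx, ry = (1.0 - t) * dy;
    double dot = rx * nx + ry * ny;
    rx -= 2.0 * dot * nx;
    ry -= 2.0 * dot * ny;
    x = qx; y = qy;
    double pn2 = std::sqrt(x * x + y * y);
    if (pn2 >= inner) { x *= inner / pn2; y *= inner / pn2; }
    dx = rx; dy = ry;
    if (std::sqrt(dx * dx + dy * dy) < 1e-15) break;
  }
  double nd = std::sqrt(dx * dx + dy * dy);
  if (nd > 1e-15) { hx = dx / nd; hy = dy / nd; }
  double pn = std::sqrt(x * x + y * y);
  if (pn > inner) { x *= inner / pn; y *= inner / pn; }
}

// [[Rcpp::export]]
List run_vicsek_cpp(double radius, double beta, double r_interact,
                    double r_capture, double speed,
                    NumericVector exit_left, NumericVector exit_right,
                    int n_ants, int max_steps) {
  std::vector<double> x(n_ants), y(n_ants), hx(n_ants), hy(n_ants);
  std::vector<double> nhx(n_ants), nhy(n_ants);
  std::vector<bool> active(n_ants, true);
  int n_left = 0, n_right = 0, n_active = n_ants;

  for (int i = 0; i < n_ants; ++i) {
    double rr = radius * std::sqrt(unif_rand());
    double th = 2.0 * M_PI * unif_rand();
    x[i] = rr * std::cos(th);
    y[i] = rr * std::sin(th);
    double ha = 2.0 * M_PI * unif_rand();
    hx[i] = std::cos(ha);
    hy[i] = std::sin(ha);
  }

  const double r2 = r_interact * r_interact;
  const double cap2 = r_capture * r_capture;
  int step = 0;
  while (n_active > 0 && step < max_steps) {
    // synchronous alignment from time-t headings of active neighbours
    for (int i = 0; i < n_ants; ++i) {
      if (!active[i]) continue;
      double sx = 0.0, sy = 0.0;
      int m = 0;
      for (int j = 0; j < n_ants; ++j) {
        if (j == i || !active[j]) continue;
        double ddx = x[j] - x[i], ddy = y[j] - y[i];
        if (ddx * ddx + ddy * ddy <= r2) {
          sx += hx[j]; sy += hy[j];
          ++m;
        }
      }
      if (m == 0 || beta == 0.0) {
        nhx[i] = hx[i]; nhy[i] = hy[i];
        continue;
      }
      double vx = (1.0 - beta) * hx[i] + beta * sx / m;
      double vy = (1.0 - beta) * hy[i] + beta * sy / m;
      double nv = std::sqrt(vx * vx + vy * vy);
      if (nv < 1e-12) {
        nhx[i] = hx[i]; nhy[i] = hy[i];
      } else {
        nhx[i] = vx / nv; nhy[i] = vy / nv;
      }
    }
    // advance, reflect, capture
    for (int i = 0; i < n_ants; ++i) {
      if (!active[i]) continue;
      hx[i] = nhx[i]; hy[i] = nhy[i];
      reflect_step(x[i], y[i], hx[i], hy[i], speed, radius);
      double dlx = x[i] - exit_left[0], dly = y[i] - exit_left[1];
      double drx = x[i] - exit_right[0], dry = y[i] - exit_right[1];
      if (dlx * dlx + dly * dly < cap2) {
        ++n_left; active[i] = false; --n_active;
      } else if (drx * drx + dry * dry < cap2) {
        ++n_right; active[i] = false; --n_active;
      }
    }
    ++step;
  }

  NumericMatrix pos(n_ants, 2), heading(n_ants, 2);
  LogicalVector act(n_ants);
  for (int i = 0; i < n_ants; ++i) {
    pos(i, 0) = x[i]; pos(i, 1) = y[i];
    heading(i, 0) = hx[i]; heading(i, 1) = hy[i];
    act[i] = active[i];
  }
  return List::create(_["n_left"] = n_left, _["n_right"] = n_right,
                      _["steps"] = step, _["truncated"] = n_active > 0,
                      _["pos"] = pos, _["heading"] = heading,
                      _["active"] = act);
}
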