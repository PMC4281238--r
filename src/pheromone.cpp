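#include <Rcpp.h>
using namespace Rcpp;

// Lattice alarm-pheromone escape model, full-run inner loop.
//
// Consumes R's RNG stream in the same documented order as the R-level
// primitives (init per ant: x, y, heading; then per step, per active ant in
// index order, one draw per sensing event with >= 2 tied maxima), so an
// R-stepped world and this runner agree exactly under the same seed.

// Moore directions in fixed scan order (must match MOORE_DIRS in R/pheromone.R)
static const int DX[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DY[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline int rand_index(int k) {
  int idx = (int)std::floor(unif_rand() * k);
  return idx >= k ? k - 1 : idx;
}

// [[Rcpp::export]]
List run_pheromone_cpp(int L, double eta, double kappa, double threshold,
                       IntegerVector exit_rows, int n_ants, int max_steps) {
  NumericMatrix field(L, L);           // field(x, y), 0-based
  IntegerVector px(n_ants), py(n_ants), vx(n_ants), vy(n_ants);
  LogicalVector active(n_ants, true);
  int n_left = 0, n_right = 0, n_active = n_ants;

  for (int i = 0; i < n_ants; ++i) {
    px[i] = std::min((int)std::floor(unif_rand() * L), L - 1);
    py[i] = std::min((int)std::floor(unif_rand() * L), L - 1);
    int d = std::min((int)std::floor(unif_rand() * 8), 7);
    vx[i] = DX[d];
    vy[i] = DY[d];
  }

  std::vector<bool> exit_row(L, false);
  for (int r = 0; r < exit_rows.size(); ++r) exit_row[exit_rows[r]] = true;
  // rows within Chebyshev distance 1 of an exit row
  std::vector<bool> near_row(L, false);
  for (int y = 0; y < L; ++y)
    for (int r = 0; r < exit_rows.size(); ++r)
      if (std::abs(y - exit_rows[r]) <= 1) near_row[y] = true;

  int step = 0;
  int tied[8];
  while (n_active > 0 && step < max_steps) {
    // deposit (ant index order, matching the R loop's summation order)
    for (int i = 0; i < n_ants; ++i)
      if (active[i]) field(px[i], py[i]) += eta;
    // evaporate, clamped at zero
    for (int x = 0; x < L; ++x)
      for (int y = 0; y < L; ++y)
        field(x, y) = std::max(field(x, y) - kappa, 0.0);
    // sense, move, check escape
    for (int i = 0; i < n_ants; ++i) {
      if (!active[i]) continue;
      // sense the clipped Moore-8 maximum
      double best = 0.0;
      int k = 0;
      for (int d = 0; d < 8; ++d) {
        int nx = px[i] + DX[d], ny = py[i] + DY[d];
        if (nx < 0 || nx >= L || ny < 0 || ny >= L) continue;
        double v = std::min(field(nx, ny), threshold);
        if (v > best) {
          best = v;
          k = 0;
          tied[k++] = d;
        } else if (v == best && v > 0.0) {
          tied[k++] = d;
        }
      }
      int nvx = vx[i], nvy = vy[i];
      if (best > 0.0) {
        int d = (k == 1) ? tied[0] : tied[rand_index(k)];
        int cx = vx[i] + DX[d], cy = vy[i] + DY[d];
        nvx = (cx > 0) - (cx < 0);
        nvy = (cy > 0) - (cy < 0);
        if (nvx == 0 && nvy == 0) { nvx = vx[i]; nvy = vy[i]; }
      }
      int nx = px[i] + nvx, ny = py[i] + nvy;
      if (nx < 0) { nx = -nx; nvx = -nvx; }
      else if (nx > L - 1) { nx = 2 * (L - 1) - nx; nvx = -nvx; }
      if (ny < 0) { ny = -ny; nvy = -nvy; }
      else if (ny > L - 1) { ny = 2 * (L - 1) - ny; nvy = -nvy; }
      px[i] = nx; py[i] = ny; vx[i] = nvx; vy[i] = nvy;
      // escape check: an exit locus within the Moore range or underfoot
      if (near_row[ny]) {
        if (nx <= 1) {
          ++n_left; active[i] = false; --n_active;
        } else if (nx >= L - 2) {
          ++n_right; active[i] = false; --n_active;
        }
      }
    }
    ++step;
  }

  IntegerMatrix pos(n_ants, 2), vel(n_ants, 2);
  for (int i = 0; i < n_ants; ++i) {
    pos(i, 0) = px[i]; pos(i, 1) = py[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i];
  }
  return List::create(_["n_left"] = n_left, _["n_right"] = n_right,
                      _["steps"] = step, _["truncated"] = n_active > 0,
                      _["field"] = field, _["pos"] = pos, _["vel"] = vel,
                      _["active"] = active);
}
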