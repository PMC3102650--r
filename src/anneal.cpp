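#include <Rcpp.h>
#include <vector>
#include <random>
using namespace Rcpp;

// Simulated-annealing cores for the two reserve-selection problems.
// The species-by-cell incidence matrix comes in dense; per-cell species
// lists are built once so each move updates representation counts
// incrementally. Randomness comes from a private mt19937 stream seeded by
// the caller, giving cross-call determinism.

namespace {

struct Instance {
  int n_sp, n_cells;
  std::vector<std::vector<int>> cell_sp; // species indices per cell
  std::vector<int> target;
};

Instance build_instance(const IntegerMatrix& pa, const IntegerVector& target) {
  Instance in;
  in.n_sp = pa.nrow();
  in.n_cells = pa.ncol();
  in.cell_sp.resize(in.n_cells);
  for (int c = 0; c < in.n_cells; ++c)
    for (int s = 0; s < in.n_sp; ++s)
      if (pa(s, c) == 1) in.cell_sp[c].push_back(s);
  in.target.assign(target.begin(), target.end());
  return in;
}

inline int rand_below(std::mt19937& rng, int n) {
  // unbiased enough for our purposes; avoids stdlib distribution variance
  return static_cast<int>(rng() % static_cast<uint32_t>(n));
}

inline double rand_unif(std::mt19937& rng) {
  return (rng() + 0.5) / 4294967296.0;
}

} // namespace

// Minimum set coverage: minimise |selection| + spf * total shortfall.
// Moves toggle one random cell; worse states accepted with prob exp(-d/T).
// [[Rcpp::export]]
List anneal_min_set_cpp(IntegerMatrix pa, IntegerVector target, double spf,
                        int iterations, double t_init, double cooling,
                        int t_interval, int restarts, int seed) {
  Instance in = build_instance(pa, target);
  std::mt19937 rng(static_cast<uint32_t>(seed));

  std::vector<char> best_sel(in.n_cells, 0);
  double best_cost = R_PosInf;

  for (int r = 0; r < restarts; ++r) {
    std::vector<char> sel(in.n_cells);
    std::vector<int> rep(in.n_sp, 0);
    int n_sel = 0;
    for (int c = 0; c < in.n_cells; ++c) {
      sel[c] = rand_unif(rng) < 0.5 ? 1 : 0;
      if (sel[c]) { ++n_sel; for (int s : in.cell_sp[c]) ++rep[s]; }
    }
    double shortfall = 0;
    for (int s = 0; s < in.n_sp; ++s)
      if (rep[s] < in.target[s]) shortfall += in.target[s] - rep[s];
    double cost = n_sel + spf * shortfall;

    // delta of toggling cell c from the current state
    auto toggle_delta = [&](int c) {
      double d = sel[c] ? -1.0 : 1.0;
      for (int s : in.cell_sp[c]) {
        if (sel[c]) { // removing
          if (rep[s] <= in.target[s]) d += spf;
        } else {      // adding
          if (rep[s] < in.target[s]) d -= spf;
        }
      }
      return d;
    };

    double T = t_init;
    if (T <= 0) { // auto: sd of candidate move deltas from the start state
      double sum = 0, sq = 0; int m = 100;
      for (int k = 0; k < m; ++k) {
        double d = toggle_delta(rand_below(rng, in.n_cells));
        sum += d; sq += d * d;
      }
      double var = sq / m - (sum / m) * (sum / m);
      T = var > 0 ? std::sqrt(var) : 1.0;
    }

    for (int it = 0; it < iterations; ++it) {
      int c = rand_below(rng, in.n_cells);
      double d = toggle_delta(c);
      if (d <= 0 || rand_unif(rng) < std::exp(-d / T)) {
        if (sel[c]) {
          sel[c] = 0; --n_sel;
          for (int s : in.cell_sp[c]) --rep[s];
        } else {
          sel[c] = 1; ++n_sel;
          for (int s : in.cell_sp[c]) ++rep[s];
        }
        cost += d;
        if (cost < best_cost) { best_cost = cost; best_sel = sel; }
      }
      if ((it + 1) % t_interval == 0) T *= cooling;
    }
    if (cost < best_cost) { best_cost = cost; best_sel = sel; }
  }

  std::vector<int> cells;
  for (int c = 0; c < in.n_cells; ++c) if (best_sel[c]) cells.push_back(c);
  return List::create(_["cells"] = wrap(cells), _["cost"] = best_cost);
}

// Maximal representation: fixed selection size (budget), maximise the count
// of species meeting their target; moves swap a selected with an unselected
// cell.
// [[Rcpp::export]]
List anneal_max_cov_cpp(IntegerMatrix pa, IntegerVector target, int budget,
                        int iterations, double t_init, double cooling,
                        int t_interval, int restarts, int seed) {
  Instance in = build_instance(pa, target);
  std::mt19937 rng(static_cast<uint32_t>(seed));

  if (budget >= in.n_cells) { // saturation: take every cell
    std::vector<int> cells(in.n_cells);
    for (int c = 0; c < in.n_cells; ++c) cells[c] = c;
    int cov = 0;
    std::vector<int> rep(in.n_sp, 0);
    for (int c = 0; c < in.n_cells; ++c)
      for (int s : in.cell_sp[c]) ++rep[s];
    for (int s = 0; s < in.n_sp; ++s) if (rep[s] >= in.target[s]) ++cov;
    return List::create(_["cells"] = wrap(cells), _["covered"] = cov);
  }

  std::vector<int> best_cells;
  int best_cov = -1;

  for (int r = 0; r < restarts; ++r) {
    // random initial selection of exactly `budget` cells
    std::vector<int> pool(in.n_cells);
    for (int c = 0; c < in.n_cells; ++c) pool[c] = c;
    for (int k = 0; k < budget; ++k) {
      int j = k + rand_below(rng, in.n_cells - k);
      std::swap(pool[k], pool[j]);
    }
    // pool[0..budget) selected, pool[budget..) unselected
    std::vector<int> pos(in.n_cells);
    for (int k = 0; k < in.n_cells; ++k) pos[pool[k]] = k;
    std::vector<int> rep(in.n_sp, 0);
    for (int k = 0; k < budget; ++k)
      for (int s : in.cell_sp[pool[k]]) ++rep[s];
    int cov = 0;
    for (int s = 0; s < in.n_sp; ++s) if (rep[s] >= in.target[s]) ++cov;

    auto swap_delta = [&](int out_c, int in_c) {
      int d = 0;
      for (int s : in.cell_sp[out_c]) {
        if (rep[s] == in.target[s]) --d;
        --rep[s];
      }
      for (int s : in.cell_sp[in_c]) {
        ++rep[s];
        if (rep[s] == in.target[s]) ++d;
      }
      // roll back; caller re-applies on acceptance
      for (int s : in.cell_sp[in_c]) --rep[s];
      for (int s : in.cell_sp[out_c]) ++rep[s];
      return d;
    };

    double T = t_init;
    if (T <= 0) {
      double sum = 0, sq = 0; int m = 100;
      for (int k = 0; k < m; ++k) {
        int oi = rand_below(rng, budget);
        int ii = budget + rand_below(rng, in.n_cells - budget);
        double d = swap_delta(pool[oi], pool[ii]);
        sum += d; sq += d * d;
      }
      double var = sq / m - (sum / m) * (sum / m);
      T = var > 0 ? std::sqrt(var) : 1.0;
    }

    if (cov > best_cov) {
      best_cov = cov;
      best_cells.assign(pool.begin(), pool.begin() + budget);
    }

    for (int it = 0; it < iterations; ++it) {
      int oi = rand_below(rng, budget);
      int ii = budget + rand_below(rng, in.n_cells - budget);
      int out_c = pool[oi], in_c = pool[ii];
      int d = swap_delta(out_c, in_c);
      if (d >= 0 || rand_unif(rng) < std::exp(d / T)) {
        for (int s : in.cell_sp[out_c]) --rep[s];
        for (int s : in.cell_sp[in_c]) ++rep[s];
        std::swap(pool[oi], pool[ii]);
        cov += d;
        if (cov > best_cov) {
          best_cov = cov;
          best_cells.assign(pool.begin(), pool.begin() + budget);
        }
      }
      if ((it + 1) % t_interval == 0) T *= cooling;
    }
  }

  std::sort(best_cells.begin(), best_cells.end());
  return List::create(_["cells"] = wrap(best_cells),
                      _["covered"] = best_cov);
}
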