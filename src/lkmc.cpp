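// Event-driven lattice kinetic Monte Carlo engine for non-interacting
// tracer diffusion on a 2D pore/cell lattice with mirror boundary
// conditions (Next Reaction method).
//
// Conventions:
//  * the lattice is a logical matrix `pore` (TRUE = accessible pore site),
//    row index = y, column index = x, both 0-based internally;
//  * particle positions are tracked UNFOLDED (integers on the infinite
//    plane); the mirror fold is applied only for occupancy lookups, so
//    displacements and MSD are free of wrap artifacts;
//  * units are nm and s throughout; the caller converts cm^2/s.
//
// Each particle carries four directional hop events with firing times
//   t_event = t_sys + h^2 * (-log r) / D_p,   r ~ U(0, 1],
// i.e. per-direction rate D_p / h^2. Moves whose folded destination is a
// cell site are inaccessible (sentinel-infinite time). After every executed
// move all four events of the moved particle are recalculated; obstacles
// are static and particles do not interact, so no other particle's events
// change. Only the per-particle minimum can therefore ever fire, and the
// global queue holds exactly one (time, particle) entry per mobile particle.

#include <Rcpp.h>
#include <queue>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

namespace {

inline int fold_idx(int x, int n) {
  // triangle-wave reflection with period 2n: ... 2,1,0,0,1,2 ... n-1,n-1 ...
  int p = 2 * n;
  int m = x % p;
  if (m < 0) m += p;
  return (m < n) ? m : p - 1 - m;
}

struct Event {
  double t;
  int p;
  bool operator>(const Event& o) const { return t > o.t; }
};

const int DX[4] = {1, -1, 0, 0};
const int DY[4] = {0, 0, 1, -1};

}  // namespace

// [[Rcpp::export(name = ".lkmc_fold_index")]]
IntegerVector lkmc_fold_index(IntegerVector x, int n) {
  if (n < 1) stop("axis length must be >= 1");
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = fold_idx(x[i], n);
  return out;
}

// [[Rcpp::export(name = ".lkmc_simulate")]]
List lkmc_simulate(LogicalMatrix pore, double h_nm, double dp_nm2s,
                   int n_particles, double t_end, double record_dt,
                   double seed) {
  const int H = pore.nrow(), W = pore.ncol();
  if (H < 1 || W < 1) stop("domain dimensions must be >= 1");
  if (dp_nm2s <= 0 || h_nm <= 0) stop("D_p and h must be positive");
  if (n_particles < 1) stop("n_particles must be >= 1");
  if (t_end <= 0) stop("t_end must be positive");
  if (record_dt <= 0) stop("record_dt must be positive");

  // enumerate pore sites for uniform initial placement
  std::vector<int> pore_y, pore_x;
  pore_y.reserve(1024);
  pore_x.reserve(1024);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (pore(i, j)) { pore_y.push_back(i); pore_x.push_back(j); }
  if (pore_y.empty()) stop("domain has no pore sites");

  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  std::uniform_int_distribution<std::size_t> pick(0, pore_y.size() - 1);

  const double tau0 = h_nm * h_nm / dp_nm2s;  // mean per-direction wait
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<long long> x(n_particles), y(n_particles);
  std::vector<long long> x0(n_particles), y0(n_particles);
  std::vector<double> t_next(n_particles, INF);
  std::vector<int> dir_next(n_particles, -1);

  std::priority_queue<Event, std::vector<Event>, std::greater<Event>> queue;

  // schedule (or reschedule) all four directional events of particle p at
  // time t_sys; keep only the minimum, push it if any direction is open
  auto reschedule = [&](int p, double t_sys) {
    double best = INF;
    int best_dir = -1;
    for (int d = 0; d < 4; ++d) {
      int fx = fold_idx(static_cast<int>(x[p] + DX[d]), W);
      int fy = fold_idx(static_cast<int>(y[p] + DY[d]), H);
      if (!pore(fy, fx)) continue;  // cell destination: sentinel-infinite
      double r = 1.0 - unif01(rng);  // in (0, 1]
      double t_event = t_sys + tau0 * (-std::log(r));
      if (t_event < best) { best = t_event; best_dir = d; }
    }
    t_next[p] = best;
    dir_next[p] = best_dir;
    if (best_dir >= 0) queue.push({best, p});
  };

  for (int p = 0; p < n_particles; ++p) {
    std::size_t k = pick(rng);
    x[p] = x0[p] = pore_x[k];
    y[p] = y0[p] = pore_y[k];
    reschedule(p, 0.0);
  }

  const int n_rec = static_cast<int>(std::floor(t_end / record_dt + 1e-9));
  NumericVector times(n_rec), msd(n_rec);
  for (int k = 0; k < n_rec; ++k) times[k] = (k + 1) * record_dt;

  // running sum of squared unfolded displacement, in lattice units
  long long sum_sq = 0;
  int k_rec = 0;
  long long n_events = 0;
  double t_sys = 0.0;

  auto flush_records = [&](double upto) {
    while (k_rec < n_rec && times[k_rec] <= upto) {
      msd[k_rec] = static_cast<double>(sum_sq) / n_particles * h_nm * h_nm;
      ++k_rec;
    }
  };

  while (!queue.empty()) {
    Event ev = queue.top();
    queue.pop();
    if (ev.t != t_next[ev.p]) continue;  // superseded entry
    if (ev.t > t_end) break;
    flush_records(ev.t);
    t_sys = ev.t;
    int p = ev.p, d = dir_next[p];
    long long ddx = x[p] - x0[p], ddy = y[p] - y0[p];
    sum_sq += 2 * (ddx * DX[d] + ddy * DY[d]) + 1;
    x[p] += DX[d];
    y[p] += DY[d];
    ++n_events;
    reschedule(p, t_sys);
  }
  flush_records(t_end);

  NumericVector ox(n_particles), oy(n_particles), fx(n_particles),
      fy(n_particles);
  for (int p = 0; p < n_particles; ++p) {
    ox[p] = static_cast<double>(x0[p]);
    oy[p] = static_cast<double>(y0[p]);
    fx[p] = static_cast<double>(x[p]);
    fy[p] = static_cast<double>(y[p]);
  }

  return List::create(
      _["times"] = times, _["msd_nm2"] = msd, _["x0"] = ox, _["y0"] = oy,
      _["x"] = fx, _["y"] = fy, _["n_events"] = static_cast<double>(n_events),
      _["t_final"] = t_sys);
}
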