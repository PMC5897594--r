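// Extended cellular Potts kernel: adhesion + area/perimeter constraints
// (the configurational Hamiltonian) plus per-event lobe, elongation and
// roundness biases on the energy change. All randomness comes from R's RNG
// so trajectories are reproducible under set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

static inline int lat_at(const IntegerMatrix &lat, int r, int c) {
  if (r < 0 || c < 0 || r >= lat.nrow() || c >= lat.ncol()) return 0;
  return lat(r, c);
}

struct CellState {
  std::vector<double> area, perim, sx, sy, phase, elong;
};

// unlike-neighbour count of site (r,c) against id
static inline int like_count(const IntegerMatrix &lat, int r, int c, int id) {
  int m = 0;
  for (int d = 0; d < 8; ++d)
    if (lat_at(lat, r + DY[d], c + DX[d]) == id) ++m;
  return m;
}

static void tabulate(const IntegerMatrix &lat, int ncell, CellState &st) {
  st.area.assign(ncell + 1, 0.0);
  st.perim.assign(ncell + 1, 0.0);
  st.sx.assign(ncell + 1, 0.0);
  st.sy.assign(ncell + 1, 0.0);
  for (int r = 0; r < lat.nrow(); ++r)
    for (int c = 0; c < lat.ncol(); ++c) {
      int id = lat(r, c);
      if (id <= 0) continue;
      st.area[id] += 1.0;
      st.sx[id] += c;
      st.sy[id] += r;
      st.perim[id] += 8 - like_count(lat, r, c, id);
    }
}

// Full configurational energy: J-coupling over unordered unlike
// second-order neighbour pairs + area and perimeter elasticity.
// [[Rcpp::export]]
double cpm_energy_cpp(IntegerMatrix lat, int ncell, double J, double A,
                      double P, double lambda_a, double lambda_p) {
  CellState st;
  tabulate(lat, ncell, st);
  double H = 0.0;
  // each unordered pair once: count pairs (site, nb) with nb "after" site
  for (int r = 0; r < lat.nrow(); ++r)
    for (int c = 0; c < lat.ncol(); ++c) {
      int id = lat(r, c);
      for (int d = 0; d < 8; ++d) {
        int rr = r + DY[d], cc = c + DX[d];
        if (rr < r || (rr == r && cc < c)) continue; // unordered: once
        int nb = lat_at(lat, rr, cc);
        if ((rr < 0 || cc < 0 || rr >= lat.nrow() || cc >= lat.ncol())) {
          // out-of-field neighbours are medium; count the pair once too
          if (id != 0) H += J;
          continue;
        }
        if (id != nb) H += J;
      }
      // pairs with out-of-field sites "before" this one (left/top edges)
      for (int d = 0; d < 8; ++d) {
        int rr = r + DY[d], cc = c + DX[d];
        if (!(rr < r || (rr == r && cc < c))) continue;
        if (rr < 0 || cc < 0 || rr >= lat.nrow() || cc >= lat.ncol()) {
          if (id != 0) H += J;
        }
      }
    }
  for (int id = 1; id <= ncell; ++id) {
    if (st.area[id] <= 0) continue;
    H += lambda_a * (st.area[id] - A) * (st.area[id] - A);
    H += lambda_p * (st.perim[id] - P) * (st.perim[id] - P);
  }
  return H;
}

static double delta_base(const IntegerMatrix &lat, const CellState &st,
                         int r, int c, int newid, double J, double A,
                         double P, double lambda_a, double lambda_p) {
  int oldid = lat(r, c);
  double dH = 0.0;
  for (int d = 0; d < 8; ++d) {
    int nb = lat_at(lat, r + DY[d], c + DX[d]);
    dH += J * ((newid != nb ? 1.0 : 0.0) - (oldid != nb ? 1.0 : 0.0));
  }
  if (oldid > 0) {
    double a = st.area[oldid];
    dH += lambda_a * ((a - 1 - A) * (a - 1 - A) - (a - A) * (a - A));
    int m = like_count(lat, r, c, oldid);
    double p = st.perim[oldid], dp = 2.0 * m - 8.0;
    dH += lambda_p * ((p + dp - P) * (p + dp - P) - (p - P) * (p - P));
  }
  if (newid > 0) {
    double a = st.area[newid];
    dH += lambda_a * ((a + 1 - A) * (a + 1 - A) - (a - A) * (a - A));
    int k = like_count(lat, r, c, newid);
    double p = st.perim[newid], dp = 8.0 - 2.0 * k;
    dH += lambda_p * ((p + dp - P) * (p + dp - P) - (p - P) * (p - P));
  }
  return dH;
}

// Incremental Eqn-2 energy change of copying `newid` into site (row, col),
// 1-based indices; state recomputed from the lattice (test/audit entry).
// [[Rcpp::export]]
double cpm_delta_base_cpp(IntegerMatrix lat, int ncell, int row, int col,
                          int newid, double J, double A, double P,
                          double lambda_a, double lambda_p) {
  CellState st;
  tabulate(lat, ncell, st);
  return delta_base(lat, st, row - 1, col - 1, newid, J, A, P, lambda_a,
                    lambda_p);
}

// Lobe + elongation + roundness energy bias for one cell involved in a copy
// event. sgn = +1 when the cell extends (gains the site), -1 when it
// retracts. Exposed for direct testing.
// [[Rcpp::export]]
double cpm_delta_shape_cpp(double x, double y, double comx, double comy,
                           double phase, int n_lobes, double nu,
                           double elong, double chi, double mu, double R,
                           double sgn) {
  double vx = x - comx, vy = y - comy;
  double r = std::sqrt(vx * vx + vy * vy);
  double beta = std::atan2(vy, vx);
  double dH = 0.0;
  dH += -sgn * nu * std::cos(n_lobes * (beta - phase));
  dH += -sgn * chi * std::cos(2.0 * (beta - elong));
  double dev = r - R;
  double s = (dev > 0) - (dev < 0);
  dH += mu * sgn * s * dev * dev;
  return dH;
}

static void update_vectors(const IntegerMatrix &lat, int ncell,
                           int n_lobes, CellState &st, int &frag_count) {
  int nr = lat.nrow(), nc = lat.ncol();
  std::vector<double> rsum(ncell + 1, 0.0), rcnt(ncell + 1, 0.0);
  std::vector<double> sxx(ncell + 1, 0.0), syy(ncell + 1, 0.0),
      sxy(ncell + 1, 0.0);
  // pass 1: boundary-radius means and second moments
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int id = lat(r, c);
      if (id <= 0) continue;
      double comx = st.sx[id] / st.area[id], comy = st.sy[id] / st.area[id];
      double vx = c - comx, vy = r - comy;
      sxx[id] += vx * vx;
      syy[id] += vy * vy;
      sxy[id] += vx * vy;
      if (like_count(lat, r, c, id) < 8) {
        rsum[id] += std::sqrt(vx * vx + vy * vy);
        rcnt[id] += 1.0;
      }
    }
  // pass 2: circular cross-correlation of the radial boundary profile
  std::vector<double> Ac(ncell + 1, 0.0), Bc(ncell + 1, 0.0);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int id = lat(r, c);
      if (id <= 0 || rcnt[id] == 0) continue;
      if (like_count(lat, r, c, id) == 8) continue;
      double comx = st.sx[id] / st.area[id], comy = st.sy[id] / st.area[id];
      double vx = c - comx, vy = r - comy;
      double rad = std::sqrt(vx * vx + vy * vy);
      double beta = std::atan2(vy, vx);
      double w = rad - rsum[id] / rcnt[id];
      Ac[id] += w * std::cos(n_lobes * beta);
      Bc[id] += w * std::sin(n_lobes * beta);
    }
  for (int id = 1; id <= ncell; ++id) {
    if (st.area[id] <= 0) continue;
    double amp = std::sqrt(Ac[id] * Ac[id] + Bc[id] * Bc[id]);
    if (amp > 1e-9) st.phase[id] = std::atan2(Bc[id], Ac[id]) / n_lobes;
    double aniso = std::sqrt((sxx[id] - syy[id]) * (sxx[id] - syy[id]) +
                             4.0 * sxy[id] * sxy[id]);
    if (aniso > 1e-9)
      st.elong[id] = 0.5 * std::atan2(2.0 * sxy[id], sxx[id] - syy[id]);
  }
  // connectivity audit (4-connectivity flood fill per cell)
  std::vector<int> seen(nr * nc, 0);
  std::vector<int> stack;
  std::vector<int> first(ncell + 1, -1);
  for (int i = 0; i < nr * nc; ++i) {
    int id = lat[i];
    if (id > 0 && first[id] < 0) first[id] = i;
  }
  for (int id = 1; id <= ncell; ++id) {
    if (first[id] < 0) continue;
    stack.clear();
    stack.push_back(first[id]);
    seen[first[id]] = id;
    int count = 0;
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      ++count;
      int r = i % nr, c = i / nr;
      const int d4r[4] = {-1, 1, 0, 0}, d4c[4] = {0, 0, -1, 1};
      for (int d = 0; d < 4; ++d) {
        int rr = r + d4r[d], cc = c + d4c[d];
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        int j = cc * nr + rr;
        if (seen[j] != id && lat(rr, cc) == id) {
          seen[j] = id;
          stack.push_back(j);
        }
      }
    }
    if (count < (int)st.area[id]) ++frag_count;
  }
}

// Exposed for fixture tests of the dynamic target-vector update.
// [[Rcpp::export]]
List cpm_update_vectors_cpp(IntegerMatrix lat, int ncell, int n_lobes,
                            NumericVector phase0, NumericVector elong0) {
  CellState st;
  tabulate(lat, ncell, st);
  st.phase.assign(phase0.begin(), phase0.end());
  st.elong.assign(elong0.begin(), elong0.end());
  st.phase.resize(ncell + 1, 0.0);
  st.elong.resize(ncell + 1, 0.0);
  int frag = 0;
  update_vectors(lat, ncell, n_lobes, st, frag);
  return List::create(_["phase"] = NumericVector(st.phase.begin() + 1, st.phase.end()),
                      _["elong"] = NumericVector(st.elong.begin() + 1, st.elong.end()),
                      _["fragmented"] = frag);
}

// Main Monte Carlo driver. One time step (MCS) = nrow*ncol elementary
// copy-event evaluations. Target vectors update every `update_every` steps.
// [[Rcpp::export]]
List cpm_run_cpp(IntegerMatrix lattice, int ncell, double J, double A,
                 double P, double lambda_a, double lambda_p, double nu,
                 int n_lobes, double chi, double mu, double temperature,
                 double yield, int steps, int snapshot_every,
                 int update_every) {
  IntegerMatrix lat = clone(lattice);
  int nr = lat.nrow(), nc = lat.ncol();
  CellState st;
  tabulate(lat, ncell, st);
  st.phase.assign(ncell + 1, 0.0);
  st.elong.assign(ncell + 1, 0.0);
  double R = std::sqrt(A / M_PI);
  int frag_count = 0;
  List snapshots;
  IntegerVector snap_steps;
  long n_eval = (long)nr * nc;
  for (int step = 1; step <= steps; ++step) {
    for (long k = 0; k < n_eval; ++k) {
      int r = (int)(unif_rand() * nr);
      int c = (int)(unif_rand() * nc);
      if (r >= nr) r = nr - 1;
      if (c >= nc) c = nc - 1;
      int d = (int)(unif_rand() * 8);
      if (d >= 8) d = 7;
      int rs = r + DY[d], cs = c + DX[d];
      if (rs < 0 || cs < 0 || rs >= nr || cs >= nc) continue;
      int newid = lat(rs, cs);
      int oldid = lat(r, c);
      if (newid == oldid) continue;
      double dH = delta_base(lat, st, r, c, newid, J, A, P, lambda_a,
                             lambda_p);
      if (newid > 0 && st.area[newid] > 0) // source cell extends
        dH += cpm_delta_shape_cpp(c, r, st.sx[newid] / st.area[newid],
                                  st.sy[newid] / st.area[newid],
                                  st.phase[newid], n_lobes, nu,
                                  st.elong[newid], chi, mu, R, +1.0);
      if (oldid > 0 && st.area[oldid] > 0) // target cell retracts
        dH += cpm_delta_shape_cpp(c, r, st.sx[oldid] / st.area[oldid],
                                  st.sy[oldid] / st.area[oldid],
                                  st.phase[oldid], n_lobes, nu,
                                  st.elong[oldid], chi, mu, R, -1.0);
      bool accept;
      if (dH <= -yield) {
        accept = true;
      } else {
        accept = unif_rand() < std::exp(-(dH + yield) / temperature);
      }
      if (!accept) continue;
      // bookkeeping
      if (oldid > 0) {
        int m = like_count(lat, r, c, oldid);
        st.perim[oldid] += 2.0 * m - 8.0;
        st.area[oldid] -= 1.0;
        st.sx[oldid] -= c;
        st.sy[oldid] -= r;
      }
      if (newid > 0) {
        int kk = like_count(lat, r, c, newid);
        st.perim[newid] += 8.0 - 2.0 * kk;
        st.area[newid] += 1.0;
        st.sx[newid] += c;
        st.sy[newid] += r;
      }
      lat(r, c) = newid;
    }
    if (update_every > 0 && step % update_every == 0) {
      update_vectors(lat, ncell, n_lobes, st, frag_count);
    }
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      snapshots.push_back(clone(lat));
      snap_steps.push_back(step);
    }
  }
  return List::create(
      _["lattice"] = lat, _["snapshots"] = snapshots,
      _["snapshot_steps"] = snap_steps,
      _["area"] = NumericVector(st.area.begin() + 1, st.area.end()),
      _["perimeter"] = NumericVector(st.perim.begin() + 1, st.perim.end()),
      _["phase"] = NumericVector(st.phase.begin() + 1, st.phase.end()),
      _["fragmentation_events"] = frag_count);
}
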