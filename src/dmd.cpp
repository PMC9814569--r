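// Event-driven (discontinuous) molecular dynamics core.
//
// Four-bead-per-residue peptide chains with hard-sphere cores, square-well
// sidechain interactions, hard pseudo-bond windows and a directional
// NH--CO hydrogen-bond well, propagated exactly between events in a cubic
// periodic box under an Andersen thermostat.
//
// Scheduling: one live event per bead (its earliest candidate) in a binary
// heap, invalidated through per-bead event counters; neighbour search via a
// cell list with exact cell-crossing events (all-pairs with horizon refresh
// events when the box is fewer than four cells across).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double BTOL = 1e-9;    // relative boundary classification band

// event kinds (boundary identity; in/out resolved from the radial velocity)
enum EvKind { K_CORE = 0, K_WELL = 1, K_BMIN = 2, K_BMAX = 3, K_HB = 4,
              K_CROSS = 5, K_REFRESH = 6 };

// resolved-event labels written to the log
enum LogKind { L_CORE = 0, L_CAPTURE = 1, L_ESCAPE = 2, L_BOUNCE = 3,
               L_BOND = 4, L_HBFORM = 5, L_HBBREAK = 6, L_HBBOUNCE = 7,
               L_PASS = 8 };

struct Ev {
  double t;
  int owner, partner;      // partner -1: crossing/refresh (axis info in aux)
  int co, cp;              // counters at scheduling
  int kind;
  int aux;                 // crossing: axis*2 + (dir > 0)
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const { return a.t > b.t; }
};

struct BondRef { int j; double min2, max2; };

struct Engine {
  int n;
  double L;
  std::vector<double> x, v;          // 3n, positions wrapped into [0, L)
  std::vector<double> tl;            // per-bead last-update time
  std::vector<double> mass;
  std::vector<int> cnt;              // event counters
  std::vector<int> ptype, kind, chainid, resi, ca_of;
  std::vector<int> hbp;              // H-bond partner, -1 if none
  int ntype;
  std::vector<double> sig, lam, eps; // ntype x ntype, row-major
  double hb_dist, hb_eps, hb_aux_max;
  double max_range2;                 // square of the largest interaction range
  double Tstar, ghost_rate;
  std::vector<std::vector<BondRef>> bonds;
  // cells
  bool use_cells;
  int nc; double cw;
  std::vector<int> cx, cy, cz, chead, cnext, cprev;
  // heap
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> heap;
  double next_ghost;
  // rng
  uint64_t rng_state;
  double gauss_spare; bool has_spare;
  // bookkeeping
  double tnow, U;
  long long n_coll, n_ghost, n_pass, n_cross;

  double runif01() {   // splitmix64
    uint64_t z = (rng_state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    z = z ^ (z >> 31);
    return (z >> 11) * (1.0 / 9007199254740992.0) + 5e-17;
  }
  double rnorm01() {
    if (has_spare) { has_spare = false; return gauss_spare; }
    double u1 = runif01(), u2 = runif01();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    gauss_spare = r * std::sin(a); has_spare = true;
    return r * std::cos(a);
  }
  int rint(int m) { return (int)(runif01() * m) % m; }

  inline double wrap(double a) {
    a -= L * std::floor(a / L);
    if (a >= L) a = 0;   // guard against floor rounding at the boundary
    return a;
  }
  inline void advance(int i, double t) {
    double dt = t - tl[i];
    if (dt != 0) {
      for (int a = 0; a < 3; ++a) x[3*i+a] = wrap(x[3*i+a] + v[3*i+a] * dt);
      tl[i] = t;
    }
  }
  // minimum-image relative position j - i at time t (virtual advance);
  // positions stay in [0, L), so the difference is in (-L, L) and one
  // conditional shift suffices
  inline void relpos(int i, int j, double t, double* r, double* w) {
    const double Lh = 0.5 * L;
    const double dti = t - tl[i], dtj = t - tl[j];
    for (int a = 0; a < 3; ++a) {
      double d = (x[3*j+a] + v[3*j+a] * dtj) - (x[3*i+a] + v[3*i+a] * dti);
      if (d > Lh) d -= L; else if (d < -Lh) d += L;
      r[a] = d;
      w[a] = v[3*j+a] - v[3*i+a];
    }
  }

  inline bool samechain_near(int i, int j, int dmax) {
    return chainid[i] == chainid[j] && std::abs(resi[i] - resi[j]) <= dmax;
  }
  inline double core2(int i, int j) {
    double s = sig[ptype[i]*ntype + ptype[j]];
    if (samechain_near(i, j, 1)) s *= 0.75;
    return s * s;
  }
  inline bool well_pair(int i, int j, double& l2, double& de) {
    double l = lam[ptype[i]*ntype + ptype[j]];
    if (l <= 0) return false;
    if (chainid[i] == chainid[j] && std::abs(resi[i] - resi[j]) < 3)
      return false;
    l2 = l * l; de = eps[ptype[i]*ntype + ptype[j]];
    return true;
  }
  // NH--CO pairs: intra-chain bonds are allowed only between residues at
  // least 4 apart (closer pairs sit inside the capture sphere by chain
  // geometry alone and would register spurious bonds)
  inline bool hb_pair(int i, int j) {
    if (!((kind[i] == 0 && kind[j] == 2) || (kind[i] == 2 && kind[j] == 0)))
      return false;
    if (chainid[i] == chainid[j] && std::abs(resi[i] - resi[j]) <= 3)
      return false;
    return true;
  }
  inline bool is_bonded(int i, int j) {
    for (const BondRef& b : bonds[i]) if (b.j == j) return true;
    return false;
  }

  // earliest hit of |r + w t| = d coming from outside (requires approach)
  static inline double t_outer(double r2, double bb, double v2, double d2) {
    if (bb >= 0) return INF;
    double disc = bb * bb - v2 * (r2 - d2);
    if (disc <= 0) return INF;
    double t = (-bb - std::sqrt(disc)) / v2;
    return t < 0 ? 0 : t;
  }
  // exit time through |r + w t| = d from inside
  static inline double t_inner(double r2, double bb, double v2, double d2) {
    if (v2 == 0) return INF;
    double disc = bb * bb - v2 * (r2 - d2);
    if (disc < 0) return INF;
    double t = (-bb + std::sqrt(disc)) / v2;
    return t < 0 ? 0 : t;
  }

  // earliest bond-window event for a bonded pair, measured from t0
  double predict_bonded(int i, const BondRef& b, double t0, int& ekind) {
    double r[3], w[3];
    relpos(i, b.j, t0, r, w);
    double r2 = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
    double bb = r[0]*w[0] + r[1]*w[1] + r[2]*w[2];
    double v2 = w[0]*w[0] + w[1]*w[1] + w[2]*w[2];
    double best = INF; int bk = -1;
    bool inside_max = (r2 < b.max2) || (bb < 0);
    if (inside_max) {
      double t = t_inner(r2, bb, v2, b.max2);
      if (t < best) { best = t; bk = K_BMAX; }
      double tm = t_outer(r2, bb, v2, b.min2);
      if (tm < best) { best = tm; bk = K_BMIN; }
    } else {
      best = 0; bk = K_BMAX;   // numerical drift out of window: bounce now
    }
    ekind = bk;
    return best == INF ? INF : t0 + best;
  }

  // earliest boundary event for a non-bonded pair, measured from t0
  double predict_nonbonded(int i, int j, double t0, int& ekind) {
    double r[3], w[3];
    relpos(i, j, t0, r, w);
    double r2 = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
    double bb = r[0]*w[0] + r[1]*w[1] + r[2]*w[2];
    double v2 = w[0]*w[0] + w[1]*w[1] + w[2]*w[2];
    // a receding pair outside every interaction range can produce no event
    // before the next velocity change of either bead (ballistic separation
    // is monotone once the closest approach has passed)
    if (bb >= 0 && r2 > max_range2) { ekind = -1; return INF; }
    double best = INF; int bk = -1;
    // hard core (always present)
    double s2 = core2(i, j);
    if (r2 <= s2 * (1 + BTOL)) {
      if (bb < 0) { ekind = K_CORE; return t0; }   // touching, approaching
    } else {
      double t = t_outer(r2, bb, v2, s2);
      if (t < best) { best = t; bk = K_CORE; }
    }
    // sidechain square well
    double l2, de;
    if (well_pair(i, j, l2, de)) {
      bool inside = (r2 < l2 * (1 - BTOL)) || (r2 < l2 * (1 + BTOL) && bb < 0);
      double t = inside ? t_inner(r2, bb, v2, l2) : t_outer(r2, bb, v2, l2);
      if (t < best) { best = t; bk = K_WELL; }
    }
    // hydrogen-bond well edge
    if (hb_pair(i, j)) {
      double h2 = hb_dist * hb_dist;
      bool inside = (r2 < h2 * (1 - BTOL)) || (r2 < h2 * (1 + BTOL) && bb < 0);
      double t = inside ? t_inner(r2, bb, v2, h2) : t_outer(r2, bb, v2, h2);
      if (t < best) { best = t; bk = K_HB; }
    }
    ekind = bk;
    return best == INF ? INF : t0 + best;
  }

  // dispatcher used on stale-partner rescheduling and at init
  double predict_pair(int i, int j, double t0, int& ekind) {
    for (const BondRef& b : bonds[i])
      if (b.j == j) return predict_bonded(i, b, t0, ekind);
    return predict_nonbonded(i, j, t0, ekind);
  }

  // ---- cells ----
  inline int cid(int a, int b, int c) {
    return (a * nc + b) * nc + c;
  }
  void cell_insert(int i) {
    int c = cid(cx[i], cy[i], cz[i]);
    cnext[i] = chead[c]; cprev[i] = -1;
    if (chead[c] >= 0) cprev[chead[c]] = i;
    chead[c] = i;
  }
  void cell_remove(int i) {
    int c = cid(cx[i], cy[i], cz[i]);
    if (cprev[i] >= 0) cnext[cprev[i]] = cnext[i]; else chead[c] = cnext[i];
    if (cnext[i] >= 0) cprev[cnext[i]] = cprev[i];
  }
  void cell_assign(int i) {
    cx[i] = std::min((int)(x[3*i] / cw), nc - 1);
    cy[i] = std::min((int)(x[3*i+1] / cw), nc - 1);
    cz[i] = std::min((int)(x[3*i+2] / cw), nc - 1);
  }
  // time and axis of next cell boundary crossing for bead i (from tl[i]).
  // Distances to the boundary are taken modulo the box length so that a
  // bead sitting exactly on a boundary of the periodic image (e.g. x = 0,
  // cell 0, moving down) advances by one full cell width instead of
  // cycling the torus with zero-time crossings.
  double crossing_time(int i, int& aux) {
    double best = INF; aux = -1;
    int cc[3] = { cx[i], cy[i], cz[i] };
    for (int a = 0; a < 3; ++a) {
      double va = v[3*i+a];
      if (va == 0) continue;
      double num = (va > 0) ? (cc[a] + 1) * cw - x[3*i+a]
                            : x[3*i+a] - cc[a] * cw;
      if (num < -0.5 * cw) num += L;       // periodic-image desync
      else if (num < 0) num = 0;           // float jitter at the boundary
      double t = num / std::fabs(va);
      if (t < best) { best = t; aux = a * 2 + (va > 0 ? 1 : 0); }
    }
    return best == INF ? INF : tl[i] + best;
  }

  // earliest candidate event for bead i at current time; push onto heap
  void schedule(int i) {
    double best = INF; int bkind = -1, bpartner = -1, baux = 0;
    if (use_cells) {
      int aux;
      double t = crossing_time(i, aux);
      if (t < best) { best = t; bkind = K_CROSS; baux = aux; }
    } else {
      // horizon refresh: re-predict before minimum-image wrap can matter
      double sp = std::sqrt(v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] +
                            v[3*i+2]*v[3*i+2]);
      if (sp > 0) {
        double t = tnow + 0.25 * L / sp;
        if (t < best) { best = t; bkind = K_REFRESH; }
      }
    }
    for (const BondRef& b : bonds[i]) {
      int ek;
      double t = predict_bonded(i, b, tnow, ek);
      if (t < best) { best = t; bkind = ek; bpartner = b.j; }
    }
    if (use_cells) {
      for (int da = -1; da <= 1; ++da)
        for (int db = -1; db <= 1; ++db)
          for (int dc = -1; dc <= 1; ++dc) {
            int a = (cx[i] + da + nc) % nc, b = (cy[i] + db + nc) % nc,
                c = (cz[i] + dc + nc) % nc;
            for (int j = chead[cid(a, b, c)]; j >= 0; j = cnext[j]) {
              if (j == i) continue;
              if (samechain_near(i, j, 1) && is_bonded(i, j)) continue;
              int ek;
              double t = predict_nonbonded(i, j, tnow, ek);
              if (t < best) { best = t; bkind = ek; bpartner = j; }
            }
          }
    } else {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (samechain_near(i, j, 1) && is_bonded(i, j)) continue;
        int ek;
        double t = predict_nonbonded(i, j, tnow, ek);
        if (t < best) { best = t; bkind = ek; bpartner = j; }
      }
    }
    if (best == INF) return;
    Ev e; e.t = best; e.owner = i; e.partner = bpartner;
    e.co = cnt[i]; e.cp = bpartner >= 0 ? cnt[bpartner] : 0;
    e.kind = bkind; e.aux = baux;
    heap.push(e);
  }

  // apply a radial impulse changing relative radial speed b -> bp
  void impulse(int i, int j, const double* rhat, double b, double bp) {
    double mu = mass[i] * mass[j] / (mass[i] + mass[j]);
    double dv = bp - b;
    for (int a = 0; a < 3; ++a) {
      v[3*i+a] -= (mu / mass[i]) * dv * rhat[a];
      v[3*j+a] += (mu / mass[j]) * dv * rhat[a];
    }
  }

  // attempt boundary crossing with potential step dU; true if crossed
  bool cross_or_bounce(int i, int j, const double* rhat, double b, double dU) {
    double mu = mass[i] * mass[j] / (mass[i] + mass[j]);
    double ek = 0.5 * mu * b * b;
    if (ek > dU) {
      double bp = (b >= 0 ? 1.0 : -1.0) * std::sqrt(b*b - 2.0 * dU / mu);
      impulse(i, j, rhat, b, bp);
      U += dU;
      return true;
    }
    impulse(i, j, rhat, b, -b);
    return false;
  }

  bool hb_aux_ok(int i, int j, double t) {
    // i, j are NH/CO in either order; check flanking C-alpha distances
    int nh = kind[i] == 0 ? i : j;
    int co = kind[i] == 0 ? j : i;
    double r[3], w[3];
    relpos(ca_of[nh], co, t, r, w);
    if (r[0]*r[0] + r[1]*r[1] + r[2]*r[2] > hb_aux_max * hb_aux_max)
      return false;
    relpos(nh, ca_of[co], t, r, w);
    if (r[0]*r[0] + r[1]*r[1] + r[2]*r[2] > hb_aux_max * hb_aux_max)
      return false;
    return true;
  }
};

// [[Rcpp::export]]
List dmd_run_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                 double box,
                 IntegerVector ptype, IntegerVector bead_kind,
                 IntegerVector chain, IntegerVector resi, IntegerVector ca_of,
                 NumericMatrix sig_mat, NumericMatrix lam_mat,
                 NumericMatrix eps_mat,
                 IntegerMatrix bond_ij, NumericVector bond_min,
                 NumericVector bond_max,
                 double hb_dist, double hb_eps, double hb_aux_max,
                 IntegerVector hb_partner0,
                 double T_star, double ghost_rate,
                 double n_collisions, double snapshot_every,
                 int seed, int log_events, bool stop_after_log,
                 double start_time) {
  Engine E;
  E.n = pos.nrow();
  E.L = box;
  E.x.resize(3 * E.n); E.v.resize(3 * E.n);
  E.tl.assign(E.n, start_time);
  E.mass.assign(mass.begin(), mass.end());
  E.cnt.assign(E.n, 0);
  E.ptype.assign(ptype.begin(), ptype.end());
  E.kind.assign(bead_kind.begin(), bead_kind.end());
  E.chainid.assign(chain.begin(), chain.end());
  E.resi.assign(resi.begin(), resi.end());
  E.ca_of.assign(ca_of.begin(), ca_of.end());
  E.hbp.assign(hb_partner0.begin(), hb_partner0.end());
  E.ntype = sig_mat.nrow();
  E.sig.assign(sig_mat.begin(), sig_mat.end());
  E.lam.assign(lam_mat.begin(), lam_mat.end());
  E.eps.assign(eps_mat.begin(), eps_mat.end());
  E.hb_dist = hb_dist; E.hb_eps = hb_eps; E.hb_aux_max = hb_aux_max;
  E.Tstar = T_star; E.ghost_rate = ghost_rate;
  E.tnow = start_time;
  E.U = 0; E.n_coll = E.n_ghost = E.n_pass = E.n_cross = 0;
  E.rng_state = 0x5deece66dULL + (uint64_t)seed * 0x100000001b3ULL;
  E.has_spare = false;
  for (int k = 0; k < 7; ++k) E.runif01();   // warm up

  for (int i = 0; i < E.n; ++i)
    for (int a = 0; a < 3; ++a) {
      E.x[3*i+a] = pos(i, a);
      E.x[3*i+a] = E.wrap(E.x[3*i+a]);
      E.v[3*i+a] = vel(i, a);
    }
  E.bonds.assign(E.n, {});
  for (int b = 0; b < bond_ij.nrow(); ++b) {
    int i = bond_ij(b, 0), j = bond_ij(b, 1);
    double mn = bond_min[b], mx = bond_max[b];
    E.bonds[i].push_back({ j, mn * mn, mx * mx });
    E.bonds[j].push_back({ i, mn * mn, mx * mx });
  }

  // interaction range and cells
  double rmax = hb_dist;
  for (int a = 0; a < E.ntype * E.ntype; ++a) {
    if (E.sig[a] > rmax) rmax = E.sig[a];
    if (E.lam[a] > rmax) rmax = E.lam[a];
  }
  E.max_range2 = rmax * rmax;
  E.nc = (int)std::floor(box / rmax);
  E.use_cells = E.nc >= 4;
  if (E.use_cells) {
    E.cw = box / E.nc;
    E.cx.resize(E.n); E.cy.resize(E.n); E.cz.resize(E.n);
    E.chead.assign(E.nc * E.nc * E.nc, -1);
    E.cnext.assign(E.n, -1); E.cprev.assign(E.n, -1);
    for (int i = 0; i < E.n; ++i) { E.cell_assign(i); E.cell_insert(i); }
  }

  for (int i = 0; i < E.n; ++i) E.schedule(i);
  E.next_ghost = ghost_rate > 0
    ? E.tnow - std::log(E.runif01()) / (ghost_rate * E.n) : INF;

  // initial U from geometry (occupied wells) + registry
  auto exact_U = [&](double& umin_gap, int& nhb) {
    double u = 0; umin_gap = INF; nhb = 0;
    double r[3], w[3];
    for (int i = 0; i < E.n; ++i) {
      if (E.hbp[i] >= 0 && E.kind[i] == 0) { u -= hb_eps; ++nhb; }
      for (int j = i + 1; j < E.n; ++j) {
        if (E.is_bonded(i, j)) continue;
        E.relpos(i, j, E.tnow, r, w);
        double r2 = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
        double s2 = E.core2(i, j);
        double gap = std::sqrt(r2) - std::sqrt(s2);
        if (gap < umin_gap) umin_gap = gap;
        double l2, de;
        if (E.well_pair(i, j, l2, de) && r2 < l2) u -= de;
      }
    }
    return u;
  };
  auto kinetic = [&]() {
    double k = 0;
    for (int i = 0; i < E.n; ++i)
      k += 0.5 * E.mass[i] * (E.v[3*i]*E.v[3*i] + E.v[3*i+1]*E.v[3*i+1] +
                              E.v[3*i+2]*E.v[3*i+2]);
    return k;
  };
  {
    double g; int nhb;
    E.U = exact_U(g, nhb);
  }

  // snapshot storage
  std::vector<double> snap_t, snap_KE, snap_Uinc, snap_Uex, snap_gap;
  std::vector<double> snap_px, snap_py, snap_pz;
  std::vector<long long> snap_coll, snap_ghost;
  std::vector<int> snap_nhb;
  std::vector<NumericMatrix> snaps;
  std::vector<IntegerVector> snap_hbp;

  auto take_snapshot = [&]() {
    for (int i = 0; i < E.n; ++i) E.advance(i, E.tnow);
    NumericMatrix P(E.n, 3);
    for (int i = 0; i < E.n; ++i)
      for (int a = 0; a < 3; ++a) P(i, a) = E.x[3*i+a];
    snaps.push_back(P);
    IntegerVector hb(E.n);
    for (int i = 0; i < E.n; ++i) hb[i] = E.hbp[i];
    snap_hbp.push_back(hb);
    double gap; int nhb;
    double uex = exact_U(gap, nhb);
    snap_t.push_back(E.tnow);
    snap_KE.push_back(kinetic());
    snap_Uinc.push_back(E.U);
    snap_Uex.push_back(uex);
    snap_gap.push_back(gap);
    snap_nhb.push_back(nhb);
    double px = 0, py = 0, pz = 0;
    for (int i = 0; i < E.n; ++i) {
      px += E.mass[i] * E.v[3*i];
      py += E.mass[i] * E.v[3*i+1];
      pz += E.mass[i] * E.v[3*i+2];
    }
    snap_px.push_back(px); snap_py.push_back(py); snap_pz.push_back(pz);
    snap_coll.push_back(E.n_coll);
    snap_ghost.push_back(E.n_ghost);
  };
  take_snapshot();

  std::vector<double> log_t; std::vector<int> log_kind, log_i, log_j;
  long long next_snap = (long long)(snapshot_every > 0 ? snapshot_every
                                                       : n_collisions);
  long long max_pops = (long long)(400.0 * n_collisions) + 2000000LL;
  if (stop_after_log) max_pops = 50000000LL;   // peek mode: bounded search
  long long pops = 0;
  bool done = false;

  while (!done && E.n_coll < (long long)n_collisions) {
    if (++pops > max_pops) {
      if (stop_after_log) break;   // no boundary event within the horizon
      stop("DMD scheduler exceeded its event-pop budget "
           "(pops=%f, collisions=%f, t=%f): possible stall",
           (double)pops, (double)E.n_coll, E.tnow);
    }
    if ((pops & 0xFFFF) == 0) Rcpp::checkUserInterrupt();

    bool do_ghost = false;
    if (E.next_ghost < INF) {
      if (E.heap.empty() || E.next_ghost <= E.heap.top().t) do_ghost = true;
    }
    if (do_ghost) {
      E.tnow = E.next_ghost;
      int k = E.rint(E.n);
      E.advance(k, E.tnow);
      double sd = std::sqrt(E.Tstar / E.mass[k]);
      for (int a = 0; a < 3; ++a) E.v[3*k+a] = sd * E.rnorm01();
      E.cnt[k]++;
      E.n_ghost++;
      E.schedule(k);
      E.next_ghost = E.tnow - std::log(E.runif01()) / (E.ghost_rate * E.n);
      continue;
    }
    if (E.heap.empty()) break;   // nothing can ever happen again
    Ev e = E.heap.top(); E.heap.pop();
    if (E.cnt[e.owner] != e.co) continue;   // owner superseded
    if (e.partner >= 0 && E.cnt[e.partner] != e.cp) { // partner moved on
      E.schedule(e.owner);
      continue;
    }
    E.tnow = e.t;
    int i = e.owner, j = e.partner;

    if (e.kind == K_CROSS) {
      E.advance(i, E.tnow);
      E.cell_remove(i);
      int axis = e.aux / 2, dir = (e.aux % 2) ? 1 : -1;
      if (axis == 0) E.cx[i] = (E.cx[i] + dir + E.nc) % E.nc;
      if (axis == 1) E.cy[i] = (E.cy[i] + dir + E.nc) % E.nc;
      if (axis == 2) E.cz[i] = (E.cz[i] + dir + E.nc) % E.nc;
      E.cell_insert(i);
      E.n_cross++;
      E.schedule(i);
      continue;
    }
    if (e.kind == K_REFRESH) {
      E.advance(i, E.tnow);
      E.schedule(i);
      continue;
    }

    // two-body boundary event
    E.advance(i, E.tnow);
    E.advance(j, E.tnow);
    double r[3], w[3];
    E.relpos(i, j, E.tnow, r, w);
    double d = std::sqrt(r[0]*r[0] + r[1]*r[1] + r[2]*r[2]);
    if (d <= 0) { E.cnt[i]++; E.cnt[j]++; E.schedule(i); E.schedule(j);
                  continue; }
    double rhat[3] = { r[0]/d, r[1]/d, r[2]/d };
    double b = rhat[0]*w[0] + rhat[1]*w[1] + rhat[2]*w[2];
    int lab = -1;
    bool counted = true;

    switch (e.kind) {
    case K_CORE:
      if (b < 0) { E.impulse(i, j, rhat, b, -b); lab = L_CORE; }
      else counted = false;
      break;
    case K_BMIN: case K_BMAX:
      E.impulse(i, j, rhat, b, -b); lab = L_BOND;
      break;
    case K_WELL: {
      double l2, de;
      if (!E.well_pair(i, j, l2, de)) { counted = false; break; }
      if (b < 0) {  // entering: potential steps from 0 to -de
        bool crossed = E.cross_or_bounce(i, j, rhat, b, -de);
        lab = crossed ? L_CAPTURE : L_BOUNCE;
      } else {      // leaving: potential steps from -de to 0
        bool crossed = E.cross_or_bounce(i, j, rhat, b, de);
        lab = crossed ? L_ESCAPE : L_BOUNCE;
      }
      break;
    }
    case K_HB: {
      bool bonded = E.hbp[i] == j;
      if (b < 0) {
        if (!bonded && E.hbp[i] < 0 && E.hbp[j] < 0 &&
            E.hb_aux_ok(i, j, E.tnow)) {
          E.cross_or_bounce(i, j, rhat, b, -E.hb_eps);  // always crosses
          E.hbp[i] = j; E.hbp[j] = i;
          lab = L_HBFORM;
        } else {
          lab = L_PASS; counted = false; E.n_pass++;
        }
      } else {
        if (bonded) {
          bool crossed = E.cross_or_bounce(i, j, rhat, b, E.hb_eps);
          if (crossed) { E.hbp[i] = -1; E.hbp[j] = -1; lab = L_HBBREAK; }
          else lab = L_HBBOUNCE;
        } else {
          lab = L_PASS; counted = false; E.n_pass++;
        }
      }
      break;
    }
    default:
      counted = false;
    }

    E.cnt[i]++; E.cnt[j]++;
    if (counted) E.n_coll++;
    if (lab >= 0 && (int)log_t.size() < log_events) {
      log_t.push_back(E.tnow); log_kind.push_back(lab);
      log_i.push_back(i + 1); log_j.push_back(j + 1);
      if (stop_after_log && (int)log_t.size() >= log_events) done = true;
    }
    E.schedule(i);
    E.schedule(j);

    if (E.n_coll >= next_snap && snapshot_every > 0) {
      take_snapshot();
      next_snap += (long long)snapshot_every;
    }
  }

  for (int i = 0; i < E.n; ++i) E.advance(i, E.tnow);
  if (snap_t.empty() || snap_t.back() != E.tnow) take_snapshot();

  NumericMatrix Pf(E.n, 3), Vf(E.n, 3);
  for (int i = 0; i < E.n; ++i)
    for (int a = 0; a < 3; ++a) { Pf(i, a) = E.x[3*i+a]; Vf(i, a) = E.v[3*i+a]; }
  IntegerVector hbf(E.n);
  for (int i = 0; i < E.n; ++i) hbf[i] = E.hbp[i];

  List snl(snaps.size()), hbl(snap_hbp.size());
  for (size_t k = 0; k < snaps.size(); ++k) { snl[k] = snaps[k];
                                              hbl[k] = snap_hbp[k]; }
  return List::create(
    _["time"] = E.tnow,
    _["positions"] = Pf, _["velocities"] = Vf, _["hb_partner"] = hbf,
    _["collision_count"] = (double)E.n_coll,
    _["ghost_count"] = (double)E.n_ghost,
    _["pass_count"] = (double)E.n_pass,
    _["pop_count"] = (double)pops,
    _["cross_count"] = (double)E.n_cross,
    _["snapshots"] = snl,
    _["snapshot_hb_partner"] = hbl,
    _["snapshot_time"] = wrap(snap_t),
    _["snapshot_KE"] = wrap(snap_KE),
    _["snapshot_U_incremental"] = wrap(snap_Uinc),
    _["snapshot_U_exact"] = wrap(snap_Uex),
    _["snapshot_min_gap"] = wrap(snap_gap),
    _["snapshot_n_hbonds"] = wrap(snap_nhb),
    _["snapshot_momentum"] = DataFrame::create(_["px"] = wrap(snap_px),
                                               _["py"] = wrap(snap_py),
                                               _["pz"] = wrap(snap_pz)),
    _["snapshot_collisions"] = wrap(std::vector<double>(snap_coll.begin(),
                                                        snap_coll.end())),
    _["snapshot_ghosts"] = wrap(std::vector<double>(snap_ghost.begin(),
                                                    snap_ghost.end())),
    _["event_log"] = DataFrame::create(_["time"] = wrap(log_t),
                                       _["kind"] = wrap(log_kind),
                                       _["i"] = wrap(log_i),
                                       _["j"] = wrap(log_j)),
    _["used_cell_list"] = E.use_cells);
}
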