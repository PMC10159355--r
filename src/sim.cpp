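#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// Discrete headings, counter-clockwise from East (Moore directions).
static const int DXS[8] = {1, 1, 0, -1, -1, -1, 0, 1};
static const int DYS[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const double UX[8] = {1.0, M_SQRT1_2, 0.0, -M_SQRT1_2, -1.0, -M_SQRT1_2, 0.0, M_SQRT1_2};
static const double UY[8] = {0.0, M_SQRT1_2, 1.0, M_SQRT1_2, 0.0, -M_SQRT1_2, -1.0, -M_SQRT1_2};

// Square types in the lattice overlay.
static const int SQ_FREE = 0, SQ_NOURISHED = 1, SQ_LUMEN = 2;

struct Params {
  double L, dt, d, tau, tG1, deltaD, Vbonus;
  double p_div_high, p_div_low, p_intr, p_exit;
  int ns, nn;
  bool contact_resident;  // true: every step spent in a lumen-adjacent square is a
                          // contact; false: only a move landing there is.
};

struct Grid {
  int nx;
  std::vector<int> type;       // nx*nx, SQ_*
  std::vector<int> lumen_adj;  // 0/1, Moore-adjacent to a lumen square
};

static Params parse_params(const List &pl) {
  Params P;
  P.L = as<double>(pl["L"]);
  P.dt = as<double>(pl["dt"]);
  P.d = as<double>(pl["d_cell"]);
  P.tau = as<double>(pl["tau"]);
  P.tG1 = as<double>(pl["t_G1"]);
  P.deltaD = as<double>(pl["delta_D"]);
  double adv = as<double>(pl["nourished_advantage"]);
  // Nourished cells cycle at rate (1+adv): effective cycle tau/(1+adv), so the
  // score bonus is tau * (1 - 1/(1+adv)) hours.
  P.Vbonus = P.tau * (1.0 - 1.0 / (1.0 + adv));
  P.p_div_high = as<double>(pl["p_div_high"]);
  P.p_div_low = as<double>(pl["p_div_low"]);
  P.p_intr = as<double>(pl["p_intr"]);
  P.p_exit = as<double>(pl["p_exit_nourished"]);
  P.ns = as<int>(pl["n_s"]);
  P.nn = as<int>(pl["n_n"]);
  P.contact_resident = as<std::string>(pl["contact_mode"]) == "resident";
  return P;
}

static Grid parse_grid(const List &gl) {
  Grid G;
  G.nx = as<int>(gl["nx"]);
  IntegerVector t = gl["type"], a = gl["lumen_adj"];
  G.type.assign(t.begin(), t.end());
  G.lumen_adj.assign(a.begin(), a.end());
  return G;
}

struct Sim {
  Params P;
  Grid G;
  // Cohorts: one per (phenotype, migratory group). A cell references a cohort.
  std::vector<std::vector<double>> coh_speed;  // length-1 = constant profile
  std::vector<double> coh_pers, coh_fold;
  std::vector<int> coh_phen;                        // 1-based phenotype id
  std::vector<std::vector<int>> phen_cohorts;       // cohort ids per phenotype
  std::vector<std::vector<double>> phen_abund;      // abundances, same shape
  std::vector<double> phen_frac;                    // population phenotype mix
  // Cell state (grow-only arrays; removed cells keep their slot, alive = 0).
  std::vector<double> x, y, T, g1, ntot, birth;
  std::vector<int> heading, coh;
  std::vector<char> alive;
  std::vector<std::vector<int>> occ;  // square -> cell ids
  long births, necro, intra;
  int n_alive;
  double clock;
  Streams *S;

  int sq_at(double px, double py) const {
    int ix = (int)std::floor(px / P.d), iy = (int)std::floor(py / P.d);
    if (ix >= G.nx) ix = G.nx - 1; if (ix < 0) ix = 0;
    if (iy >= G.nx) iy = G.nx - 1; if (iy < 0) iy = 0;
    return ix + G.nx * iy;
  }
  double wrapc(double v) const {
    v -= P.L * std::floor(v / P.L);
    if (v >= P.L || v < 0) v = 0.0;  // floating-point edge of the fold
    return v;
  }
  double pdist2(double x1, double y1, double x2, double y2) const {
    double dx = std::fabs(x1 - x2); if (dx > P.L - dx) dx = P.L - dx;
    double dy = std::fabs(y1 - y2); if (dy > P.L - dy) dy = P.L - dy;
    return dx * dx + dy * dy;
  }
  void occ_add(int i) { occ[sq_at(x[i], y[i])].push_back(i); }
  void occ_remove(int i) {
    std::vector<int> &v = occ[sq_at(x[i], y[i])];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); return; }
  }

  // Would a cell center at (px,py) overlap any living cell other than `excl`?
  bool blocked(double px, double py, int excl) const {
    int ix = (int)std::floor(px / P.d), iy = (int)std::floor(py / P.d);
    double lim = P.d * P.d - 1e-9;  // strict: distance < d blocks, == d allowed
    // A step can exceed one square, but only centers within distance d matter,
    // and d == square side, so the 3x3 block around the destination suffices.
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b) {
        int jx = (ix + a + G.nx) % G.nx, jy = (iy + b + G.nx) % G.nx;
        const std::vector<int> &v = occ[jx + G.nx * jy];
        for (size_t k = 0; k < v.size(); ++k) {
          int j = v[k];
          if (j == excl || !alive[j]) continue;
          if (pdist2(px, py, x[j], y[j]) < lim) return true;
        }
      }
    return false;
  }

  // Moore density: number of the 8 neighbouring squares holding >= 1 cell center.
  int moore_n(int i) const {
    int ix = (int)std::floor(x[i] / P.d), iy = (int)std::floor(y[i] / P.d);
    int n = 0;
    for (int k = 0; k < 8; ++k) {
      int jx = (ix + DXS[k] + G.nx) % G.nx, jy = (iy + DYS[k] + G.nx) % G.nx;
      if (!occ[jx + G.nx * jy].empty()) ++n;
    }
    return n;
  }

  void add_cell(double px, double py, int cohort, int hd, double T0, double birth_t) {
    x.push_back(px); y.push_back(py); T.push_back(T0); g1.push_back(0.0);
    ntot.push_back(0.0); birth.push_back(birth_t);
    heading.push_back(hd); coh.push_back(cohort); alive.push_back(1);
    ++n_alive;
    occ_add((int)x.size() - 1);
  }

  double sample_speed(int cohort) {
    const std::vector<double> &prof = coh_speed[cohort];
    if (prof.size() == 1) return prof[0];
    return prof[S->s[STR_MOVEMENT].pick((int)prof.size())];
  }

  // Fill dirs with the candidate heading set given a previous heading.
  // forward = angular difference <= 90 deg inclusive (5 headings), backward = 3.
  static int heading_set(int prev, bool forward, int *dirs) {
    if (forward) {
      for (int k = 0; k < 5; ++k) dirs[k] = (prev + k - 2 + 8) % 8;
      return 5;
    }
    for (int k = 0; k < 3; ++k) dirs[k] = (prev + k + 3) % 8;
    return 3;
  }

  // Returns 0 = stayed, 1 = moved. Does not handle intravasation (caller does).
  int move_cell(int i) {
    double speed = sample_speed(coh[i]);
    if (speed <= 0) return 0;
    double step = speed * P.dt;
    int dirs[8], nd;
    if (heading[i] < 0) {
      nd = 8; for (int k = 0; k < 8; ++k) dirs[k] = k;
    } else {
      bool fwd = S->s[STR_MOVEMENT].unif_oc() <= coh_pers[coh[i]];
      nd = heading_set(heading[i], fwd, dirs);
    }
    bool in_zone = G.type[sq_at(x[i], y[i])] == SQ_NOURISHED;
    int cand[8], nc = 0;
    int exit_state = 0;  // 0 undrawn, 1 allowed, 2 denied (one draw per step)
    for (int k = 0; k < nd; ++k) {
      double px = wrapc(x[i] + UX[dirs[k]] * step);
      double py = wrapc(y[i] + UY[dirs[k]] * step);
      int dsq = sq_at(px, py);
      if (G.type[dsq] == SQ_LUMEN) continue;           // lumen is impenetrable
      if (blocked(px, py, i)) continue;                 // destination-only check
      if (in_zone && G.type[dsq] != SQ_NOURISHED) {     // would leave the zone
        if (exit_state == 0)
          exit_state = (S->s[STR_ZONE_EXIT].unif_oc() <= P.p_exit) ? 1 : 2;
        if (exit_state == 2) continue;
      }
      cand[nc++] = dirs[k];
    }
    if (nc == 0) return 0;  // blocked movement is legal: stay, keep heading
    int dir = cand[S->s[STR_MOVEMENT].pick(nc)];
    occ_remove(i);
    x[i] = wrapc(x[i] + UX[dir] * step);
    y[i] = wrapc(y[i] + UY[dir] * step);
    heading[i] = dir;
    occ_add(i);
    return 1;
  }

  void remove_cell(int i) { occ_remove(i); alive[i] = 0; --n_alive; }

  // One intravasation draw for a cell currently in contact with a lumen square.
  bool try_intravasate(int i) {
    double p = P.p_intr * coh_fold[coh[i]];
    if (S->s[STR_INTRAVASATION].unif_oc() <= p) {
      remove_cell(i);
      ++intra;
      return true;
    }
    return false;
  }

  // Each newborn cell develops a phenotype according to the population
  // fractions (not by clonal inheritance), then draws its migratory group.
  int draw_phenotype() {
    if (phen_frac.size() <= 1) return 1;
    double u = S->s[STR_PHENOTYPE].unif_oc(), acc = 0.0;
    for (size_t k = 0; k < phen_frac.size(); ++k) {
      acc += phen_frac[k];
      if (u <= acc + 1e-12) return (int)k + 1;
    }
    return (int)phen_frac.size();
  }

  int draw_cohort(int phen) {
    const std::vector<int> &ids = phen_cohorts[phen - 1];
    if (ids.size() == 1) return ids[0];
    const std::vector<double> &ab = phen_abund[phen - 1];
    double u = S->s[STR_PHENOTYPE].unif_oc(), acc = 0.0;
    for (size_t k = 0; k < ids.size(); ++k) {
      acc += ab[k];
      if (u <= acc) return ids[k];
    }
    return ids.back();
  }

  void divide_phase(int i) {
    int n = moore_n(i);
    double p;
    bool in_zone = G.type[sq_at(x[i], y[i])] == SQ_NOURISHED;
    if (n == 8) {
      p = 0.0;  // fully enclosed: proliferation completely inhibited
    } else {
      double D = P.deltaD * (8 - n) / 8.0;
      double V = in_zone ? P.Vbonus : 0.0;
      double PS = T[i] + D + V;
      bool g1fast = g1[i] >= P.tG1 - 1e-9;
      p = (PS >= P.tau || g1fast) ? P.p_div_high : P.p_div_low;
    }
    if (!(S->s[STR_DIVISION].unif_oc() <= p)) return;

    // Daughter placement: free Moore spots of the mother, forward/backward rule.
    double fx[8], fy[8];
    int fdir[8], nf = 0;
    for (int k = 0; k < 8; ++k) {
      double px = wrapc(x[i] + DXS[k] * P.d);
      double py = wrapc(y[i] + DYS[k] * P.d);
      int dsq = sq_at(px, py);
      if (G.type[dsq] == SQ_LUMEN) continue;
      if (blocked(px, py, -1)) continue;
      fx[nf] = px; fy[nf] = py; fdir[nf] = k; ++nf;
    }
    if (nf == 0) return;  // division fails for lack of space; T is NOT reset

    int pick_idx;
    if (heading[i] < 0) {
      pick_idx = S->s[STR_DIVISION].pick(nf);
    } else {
      bool fwd = S->s[STR_DIVISION].unif_oc() <= coh_pers[coh[i]];
      int want[8], nw = heading_set(heading[i], fwd, want);
      int sel[8], nsel = 0;
      for (int k = 0; k < nf; ++k)
        for (int w = 0; w < nw; ++w)
          if (fdir[k] == want[w]) { sel[nsel++] = k; break; }
      if (nsel == 0) {  // chosen half empty: fall back to any free spot
        pick_idx = S->s[STR_DIVISION].pick(nf);
      } else {
        pick_idx = sel[S->s[STR_DIVISION].pick(nsel)];
      }
    }
    int dcoh = draw_cohort(draw_phenotype());
    add_cell(fx[pick_idx], fy[pick_idx], dcoh, -1, 0.0, clock + P.dt);
    ++births;
    T[i] = 0.0;  // both cells restart the cycle (and the G1 clock)
    g1[i] = 0.0;
  }

  // Clock updates + necrosis. Returns false if the cell was removed.
  bool fate_phase(int i) {
    T[i] += P.dt;
    if (G.type[sq_at(x[i], y[i])] == SQ_NOURISHED) {
      g1[i] += P.dt;
      ntot[i] += P.dt;
    }
    if (T[i] >= P.nn * P.tau - 1e-9) {
      remove_cell(i);
      ++necro;
      return false;
    }
    return true;
  }

  void do_step() {
    std::vector<int> idx;
    idx.reserve(n_alive);
    for (size_t i = 0; i < x.size(); ++i)
      if (alive[i]) idx.push_back((int)i);
    // Randomized update order each step (no systematic update bias).
    for (int k = (int)idx.size() - 1; k > 0; --k) {
      int j = S->s[STR_SCHEDULER].pick(k + 1);
      std::swap(idx[k], idx[j]);
    }
    for (size_t q = 0; q < idx.size(); ++q) {
      int i = idx[q];
      if (!alive[i]) continue;
      if (!fate_phase(i)) continue;
      int moved = move_cell(i);
      int cs = sq_at(x[i], y[i]);
      if (G.lumen_adj[cs] && (P.contact_resident || moved == 1)) {
        if (try_intravasate(i)) continue;
      }
      divide_phase(i);
    }
    clock += P.dt;
  }

  int quiescent_count() const {
    int q = 0;
    double lo = P.ns * P.tau;
    for (size_t i = 0; i < x.size(); ++i)
      if (alive[i] && T[i] >= lo - 1e-9) ++q;
    return q;
  }

  double ui(int k_quadrats) const {
    if (n_alive == 0) return NA_REAL;
    int qs = (int)std::lround(std::sqrt((double)k_quadrats));
    double side = P.L / qs;
    std::vector<int> c(qs * qs, 0);
    for (size_t i = 0; i < x.size(); ++i) {
      if (!alive[i]) continue;
      int ix = (int)(x[i] / side); if (ix >= qs) ix = qs - 1;
      int iy = (int)(y[i] / side); if (iy >= qs) iy = qs - 1;
      ++c[ix + qs * iy];
    }
    double N = n_alive, k = (double)(qs * qs), sum = 0.0;
    for (size_t i = 0; i < c.size(); ++i) sum += std::fabs(c[i] - N / k);
    double ui = 1.0 - sum / (2.0 * N * (1.0 - 1.0 / k));
    if (ui < 0.0) ui = 0.0;
    if (ui > 1.0) ui = 1.0;
    return ui;
  }
};

static Sim make_sim(const List &params, const List &grid, const List &cohorts,
                    Streams *S) {
  Sim s;
  s.P = parse_params(params);
  s.G = parse_grid(grid);
  s.S = S;
  List sp = cohorts["speed"];
  NumericVector pers = cohorts["persistence"], fold = cohorts["fold"];
  IntegerVector phen = cohorts["phenotype"];
  List pc = cohorts["phen_cohorts"], pa = cohorts["phen_abund"];
  for (int i = 0; i < sp.size(); ++i) {
    NumericVector v = sp[i];
    s.coh_speed.push_back(std::vector<double>(v.begin(), v.end()));
  }
  s.coh_pers.assign(pers.begin(), pers.end());
  s.coh_fold.assign(fold.begin(), fold.end());
  s.coh_phen.assign(phen.begin(), phen.end());
  for (int i = 0; i < pc.size(); ++i) {
    IntegerVector ids = pc[i];
    NumericVector ab = pa[i];
    s.phen_cohorts.push_back(std::vector<int>(ids.begin(), ids.end()));
    s.phen_abund.push_back(std::vector<double>(ab.begin(), ab.end()));
  }
  if (cohorts.containsElementNamed("phen_frac")) {
    NumericVector fr = cohorts["phen_frac"];
    s.phen_frac.assign(fr.begin(), fr.end());
  }
  s.occ.assign(s.G.nx * s.G.nx, std::vector<int>());
  s.births = s.necro = s.intra = 0;
  s.n_alive = 0;
  s.clock = 0.0;
  return s;
}

// [[Rcpp::export]]
SEXP make_streams_cpp(int seed) {
  Streams *S = new Streams();
  S->seed_all((uint64_t)(unsigned int)seed);
  XPtr<Streams> p(S, true);
  return p;
}

// [[Rcpp::export]]
NumericVector stream_uniform_cpp(SEXP sp, int stream, int n) {
  XPtr<Streams> S(sp);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = S->s[stream].unif_oc();
  return out;
}

// [[Rcpp::export]]
List run_sim_cpp(List params, List grid, List cohorts, List init,
                 double duration, double record_every, int stop_alive,
                 int k_quadrats, SEXP sp) {
  XPtr<Streams> S(sp);
  Sim s = make_sim(params, grid, cohorts, S);
  NumericVector ix = init["x"], iy = init["y"], iT = init["T"];
  IntegerVector ih = init["heading"], ic = init["cohort"];
  for (int i = 0; i < ix.size(); ++i)
    s.add_cell(ix[i], iy[i], ic[i], ih[i], iT[i], 0.0);

  std::vector<double> r_t, r_ui;
  std::vector<int> r_alive, r_intra, r_necro, r_quies, r_births;
  int rec_steps = (record_every > 0) ? (int)std::lround(record_every / s.P.dt) : 0;
  int n_steps = (int)std::lround(duration / s.P.dt);

  r_t.push_back(0.0); r_alive.push_back(s.n_alive);
  r_intra.push_back(0); r_necro.push_back(0); r_births.push_back(0);
  r_quies.push_back(s.quiescent_count()); r_ui.push_back(s.ui(k_quadrats));

  for (int st = 1; st <= n_steps; ++st) {
    s.do_step();
    bool stop = (stop_alive > 0 && s.n_alive >= stop_alive) || s.n_alive == 0;
    if ((rec_steps > 0 && st % rec_steps == 0) || st == n_steps || stop) {
      r_t.push_back(s.clock); r_alive.push_back(s.n_alive);
      r_intra.push_back((int)s.intra); r_necro.push_back((int)s.necro);
      r_births.push_back((int)s.births);
      r_quies.push_back(s.quiescent_count()); r_ui.push_back(s.ui(k_quadrats));
    }
    if (stop) break;
  }

  int ncell = (int)s.x.size();
  NumericVector fx(ncell), fy(ncell), fT(ncell), fg1(ncell), fn(ncell), fb(ncell);
  IntegerVector fh(ncell), fc(ncell), fsq(ncell);
  LogicalVector fa(ncell);
  double nour_sum = 0.0;
  for (int i = 0; i < ncell; ++i) {
    fx[i] = s.x[i]; fy[i] = s.y[i]; fT[i] = s.T[i]; fg1[i] = s.g1[i];
    fn[i] = s.ntot[i]; fb[i] = s.birth[i]; fh[i] = s.heading[i];
    fc[i] = s.coh[i]; fa[i] = s.alive[i] != 0;
    fsq[i] = NA_INTEGER;
    nour_sum += s.ntot[i];
  }
  // Occupancy as the engine sees it, for from-scratch rebuild checks.
  for (size_t q = 0; q < s.occ.size(); ++q)
    for (size_t k = 0; k < s.occ[q].size(); ++k) fsq[s.occ[q][k]] = (int)q;

  return List::create(
    _["time"] = r_t, _["alive"] = r_alive, _["intravasated"] = r_intra,
    _["necrotic"] = r_necro, _["quiescent"] = r_quies, _["ui"] = r_ui,
    _["births_series"] = r_births,
    _["cells"] = List::create(_["x"] = fx, _["y"] = fy, _["T"] = fT,
                              _["g1"] = fg1, _["nourished_h"] = fn,
                              _["birth_time"] = fb, _["heading"] = fh,
                              _["cohort"] = fc, _["alive"] = fa,
                              _["occ_square"] = fsq),
    _["births"] = (double)s.births, _["necrotic_total"] = (double)s.necro,
    _["intravasated_total"] = (double)s.intra,
    _["mean_nourished_h"] = ncell > 0 ? nour_sum / ncell : NA_REAL,
    _["final_clock"] = s.clock);
}

// Single-cell move proposal against a fixed field of other cells. Exercises the
// same internals as the engine loop.
// [[Rcpp::export]]
List propose_move_cpp(double x, double y, int heading, double persistence,
                      NumericVector speed_profile, double fold,
                      NumericMatrix others, List params, List grid, SEXP sp) {
  XPtr<Streams> S(sp);
  List cohorts = List::create(
    _["speed"] = List::create(speed_profile),
    _["persistence"] = NumericVector::create(persistence),
    _["fold"] = NumericVector::create(fold),
    _["phenotype"] = IntegerVector::create(1),
    _["phen_cohorts"] = List::create(IntegerVector::create(0)),
    _["phen_abund"] = List::create(NumericVector::create(1.0)));
  Sim s = make_sim(params, grid, cohorts, S);
  for (int i = 0; i < others.nrow(); ++i)
    s.add_cell(others(i, 0), others(i, 1), 0, -1, 0.0, 0.0);
  s.add_cell(x, y, 0, heading, 0.0, 0.0);
  int self = (int)s.x.size() - 1;
  int moved = s.move_cell(self);
  std::string outcome = moved ? "moved" : "stayed";
  int cs = s.sq_at(s.x[self], s.y[self]);
  if (s.G.lumen_adj[cs] && (s.P.contact_resident || moved == 1)) {
    if (s.try_intravasate(self)) outcome = "intravasated";
  }
  return List::create(_["outcome"] = outcome, _["x"] = s.x[self],
                      _["y"] = s.y[self], _["heading"] = s.heading[self]);
}

// Daughter placement for a mother at (x, y) against a fixed field.
// [[Rcpp::export]]
List place_daughter_cpp(double x, double y, int heading, double persistence,
                        NumericMatrix others, List params, List grid, SEXP sp) {
  XPtr<Streams> S(sp);
  List cohorts = List::create(
    _["speed"] = List::create(NumericVector::create(0.0)),
    _["persistence"] = NumericVector::create(persistence),
    _["fold"] = NumericVector::create(1.0),
    _["phenotype"] = IntegerVector::create(1),
    _["phen_cohorts"] = List::create(IntegerVector::create(0)),
    _["phen_abund"] = List::create(NumericVector::create(1.0)));
  Sim s = make_sim(params, grid, cohorts, S);
  for (int i = 0; i < others.nrow(); ++i)
    s.add_cell(others(i, 0), others(i, 1), 0, -1, 0.0, 0.0);
  s.add_cell(x, y, 0, heading, s.P.tau, 0.0);  // mother, PS irrelevant here
  int self = (int)s.x.size() - 1;
  // Force the division draw to succeed deterministically by temporarily
  // setting p_div so only placement logic runs.
  s.P.p_div_high = 1.0;
  s.P.p_div_low = 1.0;
  long before = s.births;
  s.divide_phase(self);
  bool ok = s.births > before;
  double dx_ = NA_REAL, dy_ = NA_REAL;
  if (ok) {
    dx_ = s.x.back();
    dy_ = s.y.back();
  }
  return List::create(_["success"] = ok, _["x"] = dx_, _["y"] = dy_,
                      _["mother_T"] = s.T[self]);
}

// Unobstructed single-cell tracks generated with the motility heading rule in
// unwrapped coordinates (as a tracking microscope would report them).
// [[Rcpp::export]]
DataFrame generate_tracks_cpp(NumericVector speed_profile, double persistence,
                              int n_tracks, int n_steps, double dt, SEXP sp) {
  XPtr<Streams> S(sp);
  int per = n_steps + 1;
  int total = n_tracks * per;
  IntegerVector id(total), frame(total);
  NumericVector t(total), xs(total), ys(total);
  int row = 0;
  for (int tr = 0; tr < n_tracks; ++tr) {
    double x = 0.0, y = 0.0;
    int heading = -1;
    id[row] = tr + 1; frame[row] = 0; t[row] = 0.0; xs[row] = x; ys[row] = y;
    ++row;
    for (int st = 1; st <= n_steps; ++st) {
      double speed;
      if (speed_profile.size() == 1) speed = speed_profile[0];
      else speed = speed_profile[S->s[STR_MOVEMENT].pick(speed_profile.size())];
      if (speed > 0) {
        int dirs[8], nd;
        if (heading < 0) {
          nd = 8; for (int k = 0; k < 8; ++k) dirs[k] = k;
        } else {
          bool fwd = S->s[STR_MOVEMENT].unif_oc() <= persistence;
          nd = Sim::heading_set(heading, fwd, dirs);
        }
        int dir = dirs[S->s[STR_MOVEMENT].pick(nd)];
        x += UX[dir] * speed * dt;
        y += UY[dir] * speed * dt;
        heading = dir;
      }
      id[row] = tr + 1; frame[row] = st; t[row] = st * dt;
      xs[row] = x; ys[row] = y;
      ++row;
    }
  }
  return DataFrame::create(_["track_id"] = id, _["frame"] = frame, _["t"] = t,
                           _["x"] = xs, _["y"] = ys);
}
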