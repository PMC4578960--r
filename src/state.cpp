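// Incremental evaluation state for the raster zoning objective.
//
// A solution is a binary protection map over an n_rows x n_cols raster.  The
// objective (maximized) is
//   w1 * mean(Eco | protected) + w2 * (1 - mean(Dev | protected))
//     + w3 * mean(Com | protected)
// with Com_i = (# protected cells in the w x w window around i) /
//              (# configurable cells in that window), windows truncated at the
// raster border and including the center cell.  All means divide by the fixed
// quota Q, not by the current count, so partial solutions met during repair
// evaluate consistently.
//
// The state keeps, per cell,
//   P[i]  = number of protected cells in the window around i
//   Tp[i] = sum of 1/D[j] over protected j in the window around i
// so that toggling one cell updates O(w^2) entries and the exact fitness
// change of a single toggle is O(1).  Best-gain scans are O(N) with
// row-major tie-breaking (lowest row, then lowest column).
//
// RNG never lives here: every stochastic choice is drawn on the R side.

#include <Rcpp.h>
#include <memory>
#include <vector>
using namespace Rcpp;

struct GridC {
  int nr, nc, N, h;            // h = (window - 1) / 2
  std::vector<double> eco, dev, invD;
  std::vector<double> sg;          // (w1*eco - w2*dev)/Q, the static site gain
  std::vector<char> conf;
  double w1, w2, w3;
  double Q, w3Q;                   // w3Q = w3/Q
};

struct StateC {
  std::shared_ptr<GridC> g;
  std::vector<char> x;         // protection indicator
  std::vector<char> forb;      // region cells excluded from repair scans
  std::vector<double> P, Tp;
  double sumEco, sumDev, sumCom;
  int count;
};

typedef XPtr<StateC> SP;

static inline void win_bounds(const GridC& g, int idx,
                              int& r0, int& r1, int& c0, int& c1) {
  const int r = idx % g.nr, c = idx / g.nr;
  r0 = r - g.h; if (r0 < 0) r0 = 0;
  r1 = r + g.h; if (r1 > g.nr - 1) r1 = g.nr - 1;
  c0 = c - g.h; if (c0 < 0) c0 = 0;
  c1 = c + g.h; if (c1 > g.nc - 1) c1 = g.nc - 1;
}

// row-major key for tie-breaking (internal indices are column-major)
static inline long rm_key(const GridC& g, int idx) {
  return (long)(idx % g.nr) * g.nc + (idx / g.nr);
}

static void recompute_sums(StateC& s) {
  const GridC& g = *s.g;
  std::fill(s.P.begin(), s.P.end(), 0.0);
  std::fill(s.Tp.begin(), s.Tp.end(), 0.0);
  s.sumEco = s.sumDev = s.sumCom = 0.0;
  s.count = 0;
  for (int i = 0; i < g.N; ++i) {
    if (!s.x[i]) continue;
    ++s.count;
    s.sumEco += g.eco[i];
    s.sumDev += g.dev[i];
    int r0, r1, c0, c1;
    win_bounds(g, i, r0, r1, c0, c1);
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        const int j = c * g.nr + r;
        s.P[j] += 1.0;
        s.Tp[j] += g.invD[i];
      }
  }
  for (int i = 0; i < g.N; ++i)
    if (s.x[i]) s.sumCom += s.P[i] * g.invD[i];
}

static inline double fitness_of(const StateC& s) {
  const GridC& g = *s.g;
  return (g.w1 * s.sumEco + g.w2 * (g.Q - s.sumDev) + g.w3 * s.sumCom) / g.Q;
}

// exact fitness change of protecting cell i (requires x[i] == 0)
static inline double gain_add(const StateC& s, int i) {
  const GridC& g = *s.g;
  return g.sg[i] + g.w3Q * ((s.P[i] + 1.0) * g.invD[i] + s.Tp[i]);
}

// exact fitness change of unprotecting cell i (requires x[i] == 1)
static inline double gain_rem(const StateC& s, int i) {
  const GridC& g = *s.g;
  return -(g.sg[i] + g.w3Q * (s.P[i] * g.invD[i] + s.Tp[i] - g.invD[i]));
}

static void do_toggle(StateC& s, int i) {
  const GridC& g = *s.g;
  int r0, r1, c0, c1;
  win_bounds(g, i, r0, r1, c0, c1);
  if (s.x[i]) {
    s.sumCom -= s.P[i] * g.invD[i] + (s.Tp[i] - g.invD[i]);
    s.x[i] = 0; --s.count;
    s.sumEco -= g.eco[i]; s.sumDev -= g.dev[i];
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        const int j = c * g.nr + r;
        s.P[j] -= 1.0;
        s.Tp[j] -= g.invD[i];
      }
  } else {
    s.sumCom += (s.P[i] + 1.0) * g.invD[i] + s.Tp[i];
    s.x[i] = 1; ++s.count;
    s.sumEco += g.eco[i]; s.sumDev += g.dev[i];
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        const int j = c * g.nr + r;
        s.P[j] += 1.0;
        s.Tp[j] += g.invD[i];
      }
  }
}

// [[Rcpp::export]]
SEXP zb_new(NumericVector eco, NumericVector dev, LogicalVector conf,
            int nr, int nc, int window, LogicalVector x,
            NumericVector w, double Q) {
  auto g = std::make_shared<GridC>();
  g->nr = nr; g->nc = nc; g->N = nr * nc; g->h = (window - 1) / 2;
  g->eco.assign(eco.begin(), eco.end());
  g->dev.assign(dev.begin(), dev.end());
  g->conf.resize(g->N);
  for (int i = 0; i < g->N; ++i) g->conf[i] = conf[i] ? 1 : 0;
  g->w1 = w[0]; g->w2 = w[1]; g->w3 = w[2]; g->Q = Q;
  g->w3Q = g->w3 / Q;
  g->sg.resize(g->N);
  for (int i = 0; i < g->N; ++i)
    g->sg[i] = (g->w1 * g->eco[i] - g->w2 * g->dev[i]) / Q;
  // window counts of configurable cells (D), stored as reciprocals
  g->invD.assign(g->N, 0.0);
  for (int i = 0; i < g->N; ++i) {
    int r0, r1, c0, c1;
    win_bounds(*g, i, r0, r1, c0, c1);
    int d = 0;
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r)
        if (g->conf[c * g->nr + r]) ++d;
    if (d > 0) g->invD[i] = 1.0 / d;
  }
  StateC* s = new StateC();
  s->g = g;
  s->x.resize(g->N);
  for (int i = 0; i < g->N; ++i) s->x[i] = x[i] ? 1 : 0;
  s->forb.assign(g->N, 0);
  s->P.assign(g->N, 0.0);
  s->Tp.assign(g->N, 0.0);
  recompute_sums(*s);
  return SP(s, true);
}

// [[Rcpp::export]]
SEXP zb_clone(SEXP xp) {
  SP p(xp);
  StateC* s = new StateC(*p);   // shares the GridC
  return SP(s, true);
}

// [[Rcpp::export]]
void zb_set_x(SEXP xp, LogicalVector x) {
  SP p(xp);
  for (int i = 0; i < p->g->N; ++i) p->x[i] = x[i] ? 1 : 0;
  recompute_sums(*p);
}

// [[Rcpp::export]]
void zb_toggle(SEXP xp, int i1) { SP p(xp); do_toggle(*p, i1 - 1); }

// Overwrite cells `idx` (1-based) with `vals`, toggling only where they
// differ.  Returns the number of cells changed.
// [[Rcpp::export]]
int zb_apply_values(SEXP xp, IntegerVector idx, LogicalVector vals) {
  SP p(xp);
  int changed = 0;
  for (int k = 0; k < idx.size(); ++k) {
    const int i = idx[k] - 1;
    const char v = vals[k] ? 1 : 0;
    if (p->x[i] != v) { do_toggle(*p, i); ++changed; }
  }
  return changed;
}

// [[Rcpp::export]]
double zb_fitness(SEXP xp) { SP p(xp); return fitness_of(*p); }

// [[Rcpp::export]]
NumericVector zb_parts(SEXP xp) {
  SP p(xp);
  const GridC& g = *p->g;
  return NumericVector::create(
    _["ecological"]  = p->sumEco / g.Q,
    _["development"] = p->sumDev / g.Q,
    _["compactness"] = p->sumCom / g.Q,
    _["count"]       = (double)p->count);
}

// [[Rcpp::export]]
int zb_count(SEXP xp) { SP p(xp); return p->count; }

// [[Rcpp::export]]
LogicalVector zb_x(SEXP xp) {
  SP p(xp);
  LogicalVector out(p->g->N);
  for (int i = 0; i < p->g->N; ++i) out[i] = p->x[i] != 0;
  return out;
}

// [[Rcpp::export]]
double zb_gain_add(SEXP xp, int i1) { SP p(xp); return gain_add(*p, i1 - 1); }

// [[Rcpp::export]]
double zb_gain_rem(SEXP xp, int i1) { SP p(xp); return gain_rem(*p, i1 - 1); }

// [[Rcpp::export]]
void zb_set_region(SEXP xp, IntegerVector idx) {
  SP p(xp);
  std::fill(p->forb.begin(), p->forb.end(), 0);
  for (int k = 0; k < idx.size(); ++k) p->forb[idx[k] - 1] = 1;
}

// [[Rcpp::export]]
void zb_clear_region(SEXP xp) {
  SP p(xp);
  std::fill(p->forb.begin(), p->forb.end(), 0);
}

// Best cell to protect among configurable, unprotected, non-forbidden cells.
// Ties broken by lowest row-major position.  Returns (index, gain); index 0
// when no eligible cell exists.
// [[Rcpp::export]]
List zb_best_add(SEXP xp) {
  SP p(xp);
  const GridC& g = *p->g;
  int best = -1; double bg = 0.0; long bkey = 0;
  for (int i = 0; i < g.N; ++i) {
    if (p->x[i] || !g.conf[i] || p->forb[i]) continue;
    const double gi = gain_add(*p, i);
    if (best < 0 || gi > bg || (gi == bg && rm_key(g, i) < bkey)) {
      best = i; bg = gi; bkey = rm_key(g, i);
    }
  }
  if (best < 0) return List::create(_["index"] = 0, _["gain"] = NA_REAL);
  return List::create(_["index"] = best + 1, _["gain"] = bg);
}

// Best cell to unprotect among protected, non-forbidden cells.
// [[Rcpp::export]]
List zb_best_rem(SEXP xp) {
  SP p(xp);
  const GridC& g = *p->g;
  int best = -1; double bg = 0.0; long bkey = 0;
  for (int i = 0; i < g.N; ++i) {
    if (!p->x[i] || p->forb[i]) continue;
    const double gi = gain_rem(*p, i);
    if (best < 0 || gi > bg || (gi == bg && rm_key(g, i) < bkey)) {
      best = i; bg = gi; bkey = rm_key(g, i);
    }
  }
  if (best < 0) return List::create(_["index"] = 0, _["gain"] = NA_REAL);
  return List::create(_["index"] = best + 1, _["gain"] = bg);
}

// Eligible cells for random (A2) repair picks, honoring the forbidden region.
// [[Rcpp::export]]
IntegerVector zb_eligible(SEXP xp, bool protected_side) {
  SP p(xp);
  const GridC& g = *p->g;
  std::vector<int> out;
  for (int i = 0; i < g.N; ++i) {
    if (p->forb[i]) continue;
    if (protected_side) { if (p->x[i]) out.push_back(i + 1); }
    else { if (!p->x[i] && g.conf[i]) out.push_back(i + 1); }
  }
  return wrap(out);
}

// Uniform random eligible cell without materializing the eligible set:
// R supplies u ~ Uniform(0,1); the floor(u * count)-th eligible cell is
// returned (1-based), or 0 when none exists.
// [[Rcpp::export]]
int zb_rand_eligible(SEXP xp, bool protected_side, double u) {
  SP p(xp);
  const GridC& g = *p->g;
  int n = 0;
  for (int i = 0; i < g.N; ++i) {
    if (p->forb[i]) continue;
    if (protected_side ? (bool)p->x[i] : (!p->x[i] && g.conf[i])) ++n;
  }
  if (n == 0) return 0;
  int k = (int)(u * n); if (k >= n) k = n - 1;
  for (int i = 0; i < g.N; ++i) {
    if (p->forb[i]) continue;
    if (protected_side ? (bool)p->x[i] : (!p->x[i] && g.conf[i])) {
      if (k == 0) return i + 1;
      --k;
    }
  }
  return 0;  // unreachable
}
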