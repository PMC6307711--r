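#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-strain stochastic lattice stepper.
//
// Conventions shared with the pure-R implementations (see R/update.R):
//  * matrices are width x height; row index = x (periodic), column = y,
//  * the colony grows towards larger y,
//  * migration coefficients are direction-relative: for a migrant moving in
//    direction d, "left" is 90 degrees counterclockwise from d, "right" is
//    clockwise, "back" is opposite,
//  * migration across the top/bottom lattice edge is forbidden; for the
//    density-dependence coefficients, sites below row 0 count as saturated
//    when bottom_full (linear fronts) and empty otherwise (radial colonies),
//    sites above the last row count as empty.
//
// Floating-point note: sums of left/right and +x/-x contributions are grouped
// as commutative pairs so that reflecting x while swapping ml and mr gives
// bit-identical results, and so that the vectorized R implementation computes
// the exact same doubles.

struct Strain {
  double g, m0, ms, md, ml, mb, mr;
};

static Strain as_strain(const NumericVector &p) {
  Strain s;
  s.g = p[0]; s.m0 = p[1]; s.ms = p[2]; s.md = p[3];
  s.ml = p[4]; s.mb = p[5]; s.mr = p[6];
  return s;
}

struct Grid {
  int W, H;
  double N;
  bool bottom_full;
  std::vector<double> nt; // total occupancy, W*H

  inline int xp(int i) const { return i + 1 < W ? i + 1 : 0; }
  inline int xm(int i) const { return i > 0 ? i - 1 : W - 1; }
  inline double tot(int i, int j) const {
    if (j < 0) return bottom_full ? N : 0.0;
    if (j >= H) return 0.0;
    return nt[i + (size_t)j * W];
  }
};

// Expected migrants of one strain from (i, j) towards direction dir
// (0 = +x, 1 = +y, 2 = -x, 3 = -y).
static inline double dirflux(const Grid &L, const std::vector<double> &na,
                             const Strain &s, int i, int j, int dir) {
  if (j < 0 || j >= L.H) return 0.0; // off-lattice source sends nothing
  double nsrc = na[i + (size_t)j * L.W];
  if (nsrc <= 0.0) return 0.0;
  int di, dj, li, lj, bi, bj, ri, rj;
  switch (dir) {
  case 0: // +x
    di = L.xp(i); dj = j;     li = i;       lj = j + 1;
    bi = L.xm(i); bj = j;     ri = i;       rj = j - 1; break;
  case 1: // +y
    di = i;       dj = j + 1; li = L.xm(i); lj = j;
    bi = i;       bj = j - 1; ri = L.xp(i); rj = j;     break;
  case 2: // -x
    di = L.xm(i); dj = j;     li = i;       lj = j - 1;
    bi = L.xp(i); bj = j;     ri = i;       rj = j + 1; break;
  default: // -y
    di = i;       dj = j - 1; li = L.xp(i); lj = j;
    bi = i;       bj = j + 1; ri = L.xm(i); rj = j;     break;
  }
  if (dj < 0 || dj >= L.H) return 0.0; // no migration off the lattice
  const double N = L.N;
  double ntd = L.nt[di + (size_t)dj * L.W];
  double excl = 1.0 - ntd / N;
  if (excl <= 0.0) return 0.0;
  double nts = L.nt[i + (size_t)j * L.W];
  double coeff = s.m0 + s.ms * (nts / N) + s.md * (ntd / N) +
    s.mb * (L.tot(bi, bj) / N) +
    (s.ml * (L.tot(li, lj) / N) + s.mr * (L.tot(ri, rj) / N));
  return nsrc * excl * coeff;
}

// rho for one strain at one site: n + (G + M) * dt
static inline double rho_site(const Grid &L, const std::vector<double> &na,
                              const Strain &s, int i, int j, double dt) {
  size_t idx = i + (size_t)j * L.W;
  double n = na[idx];
  double nt = L.nt[idx];
  double G = s.g * n * (1.0 - nt / L.N);
  double out = (dirflux(L, na, s, i, j, 0) + dirflux(L, na, s, i, j, 2)) +
               (dirflux(L, na, s, i, j, 1) + dirflux(L, na, s, i, j, 3));
  double in  = (dirflux(L, na, s, L.xp(i), j, 2) + dirflux(L, na, s, L.xm(i), j, 0)) +
               (dirflux(L, na, s, i, j + 1, 3) + dirflux(L, na, s, i, j - 1, 1));
  return n + (G + (in - out)) * dt;
}

static inline bool uniform_hood(const Grid &L, int i, int j, double val) {
  size_t idx = i + (size_t)j * L.W;
  if (L.nt[idx] != val) return false;
  return L.tot(L.xp(i), j) == val && L.tot(L.xm(i), j) == val &&
         L.tot(i, j + 1) == val && L.tot(i, j - 1) == val;
}

static void fill_totals(Grid &L, const std::vector<double> &n1,
                        const std::vector<double> &n2, int jlo, int jhi) {
  for (int j = jlo; j <= jhi; ++j)
    for (int i = 0; i < L.W; ++i) {
      size_t idx = i + (size_t)j * L.W;
      L.nt[idx] = n1[idx] + n2[idx];
    }
}

// [[Rcpp::export]]
List cpp_deterministic_update(IntegerMatrix n1_, IntegerMatrix n2_,
                              NumericVector pa, NumericVector pb,
                              double N, double dt, int ylo, int yhi,
                              bool bottom_full) {
  int W = n1_.nrow(), H = n1_.ncol();
  Strain s1 = as_strain(pa), s2 = as_strain(pb);
  Grid L; L.W = W; L.H = H; L.N = N; L.bottom_full = bottom_full;
  L.nt.resize((size_t)W * H);
  std::vector<double> n1((size_t)W * H), n2((size_t)W * H);
  for (size_t k = 0; k < n1.size(); ++k) {
    n1[k] = n1_[k]; n2[k] = n2_[k];
  }
  fill_totals(L, n1, n2, 0, H - 1);

  NumericMatrix rho1(W, H), rho2(W, H);
  for (size_t k = 0; k < n1.size(); ++k) { rho1[k] = n1[k]; rho2[k] = n2[k]; }

  int clamped = 0;
  for (int j = ylo; j <= yhi; ++j) {
    for (int i = 0; i < W; ++i) {
      size_t idx = i + (size_t)j * W;
      if (uniform_hood(L, i, j, N) || uniform_hood(L, i, j, 0.0)) continue;
      double r1 = rho_site(L, n1, s1, i, j, dt);
      double r2 = rho_site(L, n2, s2, i, j, dt);
      if (r1 < 0.0 || r2 < 0.0) {
        if (r1 < 0.0) r1 = 0.0;
        if (r2 < 0.0) r2 = 0.0;
        ++clamped;
      }
      double rt = r1 + r2;
      if (rt > N) {
        double sc = N / rt;
        r1 *= sc; r2 *= sc;
        ++clamped;
      }
      rho1[idx] = r1; rho2[idx] = r2;
    }
  }
  return List::create(_["rho1"] = rho1, _["rho2"] = rho2,
                      _["clamp_events"] = clamped);
}

// Run nsteps of the full update (deterministic + two binomial rounds) inside
// the active window. Returns the updated fields and window bookkeeping.
// [[Rcpp::export]]
List cpp_run(IntegerMatrix n1_, IntegerMatrix n2_,
             NumericVector pa, NumericVector pb,
             double N, double dt, int nsteps,
             int ylo, int yhi,
             bool advance_window, int wback, int wahead,
             bool bottom_full, bool freeze_saturated) {
  int W = n1_.nrow(), H = n1_.ncol();
  Strain s1 = as_strain(pa), s2 = as_strain(pb);
  Grid L; L.W = W; L.H = H; L.N = N; L.bottom_full = bottom_full;
  L.nt.resize((size_t)W * H);
  std::vector<double> n1((size_t)W * H), n2((size_t)W * H);
  std::vector<double> rho1((size_t)W * H), rho2((size_t)W * H);
  for (size_t k = 0; k < n1.size(); ++k) { n1[k] = n1_[k]; n2[k] = n2_[k]; }
  fill_totals(L, n1, n2, 0, H - 1);

  int clamped = 0, steps_done = 0, front = -1;
  bool hit_top = false;
  if (ylo < 0) ylo = 0;
  if (yhi > H - 1) yhi = H - 1;

  for (int step = 0; step < nsteps; ++step) {
    // deterministic update over the window
    for (int j = ylo; j <= yhi; ++j) {
      for (int i = 0; i < W; ++i) {
        size_t idx = i + (size_t)j * W;
        if (uniform_hood(L, i, j, N) || uniform_hood(L, i, j, 0.0)) {
          rho1[idx] = n1[idx]; rho2[idx] = n2[idx];
          continue;
        }
        double r1 = rho_site(L, n1, s1, i, j, dt);
        double r2 = rho_site(L, n2, s2, i, j, dt);
        if (r1 < 0.0 || r2 < 0.0) {
          if (r1 < 0.0) r1 = 0.0;
          if (r2 < 0.0) r2 = 0.0;
          ++clamped;
        }
        double rt = r1 + r2;
        if (rt > N) {
          double sc = N / rt;
          r1 *= sc; r2 *= sc;
          ++clamped;
        }
        rho1[idx] = r1; rho2[idx] = r2;
      }
    }
    // stochastic update: demographic round then drift round
    for (int j = ylo; j <= yhi; ++j) {
      for (int i = 0; i < W; ++i) {
        size_t idx = i + (size_t)j * W;
        if (freeze_saturated && uniform_hood(L, i, j, N)) continue;
        double r1 = rho1[idx], r2 = rho2[idx];
        double rt = r1 + r2;
        double nn, k1;
        if (rt <= 0.0) {
          nn = 0.0; k1 = 0.0;
        } else {
          double p = rt / N;
          nn = (p >= 1.0) ? N : R::rbinom(N, p);
          if (nn <= 0.0) {
            nn = 0.0; k1 = 0.0;
          } else {
            double q = r1 / rt;
            if (q <= 0.0) k1 = 0.0;
            else if (q >= 1.0) k1 = nn;
            else k1 = R::rbinom(nn, q);
          }
        }
        n1[idx] = k1; n2[idx] = nn - k1;
      }
    }
    fill_totals(L, n1, n2, ylo, yhi);
    ++steps_done;

    // locate the front (deepest occupied row) within/above the window
    front = -1;
    for (int j = yhi; j >= 0 && front < 0; --j)
      for (int i = 0; i < W; ++i)
        if (L.nt[i + (size_t)j * W] > 0.0) { front = j; break; }

    if (advance_window) {
      if (front + wahead > H - 1) { hit_top = true; break; }
      int new_lo = front - wback; if (new_lo < 0) new_lo = 0;
      ylo = new_lo;
      yhi = front + wahead;
    }
    if ((step & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix o1(W, H), o2(W, H);
  for (size_t k = 0; k < n1.size(); ++k) {
    o1[k] = (int)n1[k]; o2[k] = (int)n2[k];
  }
  return List::create(_["n1"] = o1, _["n2"] = o2,
                      _["steps"] = steps_done,
                      _["ylo"] = ylo, _["yhi"] = yhi,
                      _["front"] = front, _["hit_top"] = hit_top,
                      _["clamp_events"] = clamped);
}
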