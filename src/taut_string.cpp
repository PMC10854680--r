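#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Taut-string estimate of a discrete signal inside the tube
// [lo_i, hi_i] = [f_i - eps, f_i + eps]: the unique g with lo <= g <= hi
// minimising sum_i (g_{i+1} - g_i)^2.  The minimiser of any strictly
// convex function of the first differences inside a tube is the shortest
// path ("taut string") through the corridor of vertical gates, so it is
// computed geometrically with a funnel algorithm in O(n) per pass.
// Endpoints are free inside their gates; they are located by convex
// line search on the pinned-endpoint subproblem (see taut_free below).

struct Pt {
  double x, y;
};

// cross(o, a, b) > 0  <=>  slope(o, b) > slope(o, a) for a.x, b.x > o.x
static inline double cross(const Pt &o, const Pt &a, const Pt &b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

// chain with amortised O(1) back pushes/pops and front pops (points are
// only ever appended at the back, so no real deque is needed)
struct Chain {
  std::vector<Pt> buf;
  size_t head = 0;
  bool empty() const { return head >= buf.size(); }
  size_t size() const { return buf.size() - head; }
  const Pt &front() const { return buf[head]; }
  const Pt &back() const { return buf.back(); }
  const Pt &operator[](size_t i) const { return buf[head + i]; }
  void push_back(const Pt &p) { buf.push_back(p); }
  void pop_back() { buf.pop_back(); }
  void pop_front() { ++head; }
  void clear() { buf.clear(); head = 0; }
};

// Shortest path through gates [lo_i, hi_i], i = 0..n-1, pinned to v0 at
// column 0 and vn at column n-1.  Emits the bend points (knots) incl. ends.
static void taut_pinned(const std::vector<double> &lo,
                        const std::vector<double> &hi,
                        double v0, double vn,
                        std::vector<Pt> &knots) {
  const int n = (int)lo.size();
  knots.clear();
  Pt apex = {0.0, v0};
  knots.push_back(apex);
  if (n == 2) {
    knots.push_back(Pt{1.0, vn});
    return;
  }
  static thread_local Chain U, L; // ceiling (convex) / floor (concave) candidates
  U.clear();
  L.clear();

  auto clean_fronts = [&](void) {
    while (!U.empty() && U.front().x <= apex.x) U.pop_front();
    while (!L.empty() && L.front().x <= apex.x) L.pop_front();
    // keep front elements tangent-minimal from the current apex
    while (U.size() >= 2 && cross(apex, U[0], U[1]) <= 0) U.pop_front();
    while (L.size() >= 2 && cross(apex, L[0], L[1]) >= 0) L.pop_front();
  };

  auto closure = [&](void) {
    // funnel closes while max floor tangent exceeds min ceiling tangent
    while (!U.empty() && !L.empty() && cross(apex, U.front(), L.front()) > 0) {
      // decide which contact fixes first: the chain fronts cannot cross,
      // so the earlier-column front is the true bend point
      if (U.front().x < L.front().x) {
        apex = U.front();
        U.pop_front();
      } else {
        apex = L.front();
        L.pop_front();
      }
      knots.push_back(apex);
      clean_fronts();
    }
  };

  for (int i = 1; i < n; ++i) {
    double hi_i = (i == n - 1) ? vn : hi[i];
    double lo_i = (i == n - 1) ? vn : lo[i];
    Pt p = {(double)i, hi_i};
    Pt q = {(double)i, lo_i};
    // ceiling chain: slopes from apex strictly increasing (left turns)
    while (!U.empty()) {
      const Pt &prev = (U.size() >= 2) ? U[U.size() - 2] : apex;
      if (cross(prev, U.back(), p) <= 0) U.pop_back(); else break;
    }
    U.push_back(p);
    // floor chain: slopes from apex strictly decreasing (right turns)
    while (!L.empty()) {
      const Pt &prev = (L.size() >= 2) ? L[L.size() - 2] : apex;
      if (cross(prev, L.back(), q) >= 0) L.pop_back(); else break;
    }
    L.push_back(q);
    closure();
  }

  // walk out the remaining funnel towards the pinned end point
  Pt e = {(double)(n - 1), vn};
  for (;;) {
    clean_fronts();
    bool moved = false;
    if (!U.empty() && U.front().x < e.x && cross(apex, e, U.front()) < 0) {
      // straight line to the end would pass above a ceiling contact
      apex = U.front();
      U.pop_front();
      knots.push_back(apex);
      moved = true;
    } else if (!L.empty() && L.front().x < e.x && cross(apex, e, L.front()) > 0) {
      apex = L.front();
      L.pop_front();
      knots.push_back(apex);
      moved = true;
    }
    if (!moved) break;
  }
  if (knots.back().x < e.x) knots.push_back(e);
}

// linear interpolation of the knot sequence onto integer columns
static void interp_knots(const std::vector<Pt> &knots, int n,
                         std::vector<double> &g) {
  g.assign(n, 0.0);
  size_t k = 0;
  for (int i = 0; i < n; ++i) {
    while (k + 1 < knots.size() && knots[k + 1].x < (double)i) ++k;
    if ((double)i <= knots[k].x) {
      g[i] = knots[k].y;
    } else if (k + 1 < knots.size()) {
      const Pt &a = knots[k], &b = knots[k + 1];
      double t = ((double)i - a.x) / (b.x - a.x);
      g[i] = a.y + t * (b.y - a.y);
    } else {
      g[i] = knots[k].y;
    }
  }
}

struct Solution {
  std::vector<Pt> knots;
  std::vector<double> g;
};

static void solve_pinned(const std::vector<double> &lo,
                         const std::vector<double> &hi,
                         double v0, double vn, Solution &sol) {
  taut_pinned(lo, hi, v0, vn, sol.knots);
  interp_knots(sol.knots, (int)lo.size(), sol.g);
}

// derivative sign of the total objective w.r.t. a pinned start value is
// sign(v0 - g1); by symmetry sign(vn - g_{n-2}) for the pinned end.
// Optimal free endpoints are found by guarded bisection on that sign,
// with a one-step "first knot value" prediction that usually lands
// exactly on the optimum (the optimal first segment is horizontal
// whenever the tube allows it).
static double optimise_end(const std::vector<double> &lo,
                           const std::vector<double> &hi,
                           bool left, double fixed_other,
                           double cur, Solution &sol) {
  const int n = (int)lo.size();
  const double bl = left ? lo[0] : lo[n - 1];
  const double bu = left ? hi[0] : hi[n - 1];
  const double scale = 1.0 + std::fabs(bu) + std::fabs(bl);
  auto deriv = [&](double v) {
    if (left) solve_pinned(lo, hi, v, fixed_other, sol);
    else solve_pinned(lo, hi, fixed_other, v, sol);
    double neighbour = left ? sol.g[1] : sol.g[n - 2];
    return v - neighbour;
  };
  double dl = deriv(bl);
  if (dl >= 0.0) return bl; // objective increasing on the whole gate
  double du = deriv(bu);
  if (du <= 0.0) return bu;
  double a = bl, b = bu;
  double trial = std::fmin(std::fmax(cur, a), b);
  for (int it = 0; it < 60 && (b - a) > 1e-10 * scale; ++it) {
    // predicted optimum: value of the nearest interior knot (horizontal
    // first segment); fall back to bisection when not strictly inside
    double d = deriv(trial);
    if (std::fabs(d) <= 1e-12 * scale) return trial;
    if (d > 0.0) b = trial; else a = trial;
    double pred = b;
    if (sol.knots.size() >= 2) {
      pred = left ? sol.knots[1].y : sol.knots[sol.knots.size() - 2].y;
    }
    if (pred > a && pred < b && std::fabs(pred - trial) > 1e-14 * scale) {
      trial = pred;
    } else {
      trial = 0.5 * (a + b);
    }
  }
  return 0.5 * (a + b);
}

static void taut_free(const std::vector<double> &lo,
                      const std::vector<double> &hi, Solution &sol) {
  const int n = (int)lo.size();
  double lmax = lo[0], umin = hi[0];
  for (int i = 1; i < n; ++i) {
    if (lo[i] > lmax) lmax = lo[i];
    if (hi[i] < umin) umin = hi[i];
  }
  if (lmax <= umin) {
    // a horizontal line fits inside the tube: zero objective, ties broken
    // towards the middle of the feasible band
    double c = 0.5 * (lmax + umin);
    sol.knots.clear();
    sol.knots.push_back(Pt{0.0, c});
    sol.knots.push_back(Pt{(double)(n - 1), c});
    sol.g.assign(n, c);
    return;
  }
  double v0 = 0.5 * (lo[0] + hi[0]);
  double vn = 0.5 * (lo[n - 1] + hi[n - 1]);
  const double scale = 1.0 + std::fabs(lmax) + std::fabs(umin);

  // A free endpoint only shapes the string up to its first few tube
  // contacts, so on long signals each end is optimised on a short
  // prefix/suffix anchored at an interior knot of a midpoint-pinned
  // solve; small signals fall back to exact alternation on the full
  // problem.  The decomposition is validated against a brute-force QP
  // oracle in the test suite.
  const size_t KDEEP = 12;
  solve_pinned(lo, hi, v0, vn, sol);
  if (sol.knots.size() >= 2 * KDEEP + 4) {
    int cpre = (int)sol.knots[KDEEP].x;
    int csuf = (int)sol.knots[sol.knots.size() - 1 - KDEEP].x;
    if (cpre + 4 < csuf) {
      Solution tmp;
      std::vector<double> plo(lo.begin(), lo.begin() + cpre + 1);
      std::vector<double> phi(hi.begin(), hi.begin() + cpre + 1);
      v0 = optimise_end(plo, phi, true, sol.g[cpre], v0, tmp);
      std::vector<double> slo(lo.begin() + csuf, lo.end());
      std::vector<double> shi(hi.begin() + csuf, hi.end());
      vn = optimise_end(slo, shi, false, sol.g[csuf], vn, tmp);
      solve_pinned(lo, hi, v0, vn, sol);
      return;
    }
  }
  // Long signals with few contacts (wide tubes): iterate between the
  // exact solve pinned at candidate endpoints and a knot-compressed
  // box-QP (variables = string values at the contact columns, weights =
  // inter-contact distances) whose solution proposes new endpoints.
  // A fixed point satisfies the free-endpoint optimality conditions;
  // if it is not reached the exact alternation below takes over.
  if (n > 2000) {
    bool converged = false;
    for (int it = 0; it < 8 && !converged; ++it) {
      std::vector<int> cols;
      cols.push_back(0);
      for (size_t k = 1; k + 1 < sol.knots.size(); ++k)
        cols.push_back((int)sol.knots[k].x);
      cols.push_back(n - 1);
      const size_t K = cols.size();
      std::vector<double> y(K);
      for (size_t k = 0; k < K; ++k) y[k] = sol.g[cols[k]];
      for (int sweep = 0; sweep < 5000; ++sweep) {
        double moved = 0.0;
        for (size_t k = 0; k < K; ++k) {
          double target;
          if (k == 0) {
            target = y[1];
          } else if (k == K - 1) {
            target = y[K - 2];
          } else {
            double wl = (double)(cols[k] - cols[k - 1]);
            double wr = (double)(cols[k + 1] - cols[k]);
            target = (y[k - 1] / wl + y[k + 1] / wr) / (1.0 / wl + 1.0 / wr);
          }
          double nv = std::fmin(std::fmax(target, lo[cols[k]]), hi[cols[k]]);
          moved += std::fabs(nv - y[k]);
          y[k] = nv;
        }
        if (moved <= 1e-14 * scale) break;
      }
      double v0_new = y.front(), vn_new = y.back();
      converged = std::fabs(v0_new - v0) + std::fabs(vn_new - vn) <=
        1e-10 * scale;
      v0 = v0_new;
      vn = vn_new;
      solve_pinned(lo, hi, v0, vn, sol);
    }
    if (converged) return;
  }
  for (int round = 0; round < 20; ++round) {
    double v0_new = optimise_end(lo, hi, true, vn, v0, sol);
    double vn_new = optimise_end(lo, hi, false, v0_new, vn, sol);
    double moved = std::fabs(v0_new - v0) + std::fabs(vn_new - vn);
    v0 = v0_new;
    vn = vn_new;
    if (moved <= 1e-11 * scale) break;
  }
  solve_pinned(lo, hi, v0, vn, sol);
}

// [[Rcpp::export(name = ".taut_string_tube")]]
List taut_string_tube(NumericVector f, double epsilon) {
  const int n = f.size();
  std::vector<double> lo(n), hi(n);
  for (int i = 0; i < n; ++i) {
    lo[i] = f[i] - epsilon;
    hi[i] = f[i] + epsilon;
  }
  Solution sol;
  taut_free(lo, hi, sol);
  NumericVector g(n);
  for (int i = 0; i < n; ++i) g[i] = sol.g[i];
  IntegerVector kx(sol.knots.size());
  for (size_t k = 0; k < sol.knots.size(); ++k)
    kx[k] = (int)sol.knots[k].x + 1; // 1-based for R
  return List::create(_["estimate"] = g, _["knots"] = kx);
}
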