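#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>
using namespace Rcpp;

// Dense tableau simplex for
//   max / min  c'x   s.t.  A x {<=,>=} b,  x >= 0.
// Rows with dir '>=' (b >= 0) receive surplus + artificial columns; rows
// with '<=' receive a basic slack.  Phase 1 drives the artificials to zero;
// phase 2 optimizes the true objective with artificial columns barred from
// entering.  When all rows are '<=', some b are negative, and the all-slack
// basis is dual feasible (reduced costs of the right sign), a dual-simplex
// sweep restores primal feasibility first -- this is the fast path for the
// optimistic BoD dual, which needs no phase 1 that way.
// Duals are read as c_B' B^{-1} through the initial identity columns, so no
// sign bookkeeping on slack vs artificial columns is needed.
//
// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit,
//         4 dual-simplex precondition failed (negative rhs but start not
//           dual feasible; callers reformulate with artificials instead)

struct LPResult {
  int status;
  double obj;
  std::vector<double> x;
  std::vector<double> dual;
};

static LPResult simplex_core(const std::vector<double>& Aflat, int m, int n,
                             const std::vector<double>& b,
                             const std::vector<int>& dir,
                             const std::vector<double>& cin,
                             bool maximize) {
  const double EPS = 1e-9;
  std::vector<double> c(cin);
  if (!maximize) for (int j = 0; j < n; ++j) c[j] = -c[j];

  bool neg_rhs = false;
  for (int i = 0; i < m; ++i) if (b[i] < 0) neg_rhs = true;
  int n_art = 0;
  for (int i = 0; i < m; ++i) if (dir[i] == 1) ++n_art;
  if (neg_rhs && n_art > 0) { LPResult res; res.status = 4; return res; }
  int N = n + m + n_art;                       // structural + slack/surplus + artificial
  std::vector<double> T((size_t)m * N, 0.0);   // row-major tableau body
  std::vector<double> rhs(b);
  std::vector<int> basis(m);
  std::vector<int> idcol(m);                   // initial identity column of each row
  std::vector<bool> is_art(N, false);

  int art = n + m;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T[(size_t)i * N + j] = Aflat[(size_t)i * n + j];
    if (dir[i] == 0) {                         // <= : slack basic
      T[(size_t)i * N + n + i] = 1.0;
      basis[i] = n + i;
      idcol[i] = n + i;
    } else {                                   // >= : surplus + artificial basic
      T[(size_t)i * N + n + i] = -1.0;
      T[(size_t)i * N + art] = 1.0;
      is_art[art] = true;
      basis[i] = art;
      idcol[i] = art;
      ++art;
    }
  }

  // phase cost vectors over all N columns
  std::vector<double> cost(N, 0.0);
  bool phase1 = n_art > 0;
  if (phase1) {
    for (int j = n + m; j < N; ++j) cost[j] = -1.0;  // max -(sum artificials)
  } else {
    for (int j = 0; j < n; ++j) cost[j] = c[j];
  }

  // reduced costs rc_j = cost_j - c_B' T_j
  std::vector<double> rc(N);
  auto recompute_rc = [&]() {
    for (int j = 0; j < N; ++j) {
      double z = 0.0;
      for (int i = 0; i < m; ++i) {
        double cb = cost[basis[i]];
        if (cb != 0.0) z += cb * T[(size_t)i * N + j];
      }
      rc[j] = cost[j] - z;
    }
  };
  recompute_rc();

  long iter = 0;
  const long bland_after = 200L + 20L * (long)(m + N);
  const long max_iter = 2000L + 400L * (long)(m + N);
  bool in_phase1 = phase1;

  auto pivot = [&](int r, int q) {
    double piv = T[(size_t)r * N + q];
    double inv = 1.0 / piv;
    for (int j = 0; j < N; ++j) T[(size_t)r * N + j] *= inv;
    rhs[r] *= inv;
    for (int i = 0; i < m; ++i) {
      if (i == r) continue;
      double f = T[(size_t)i * N + q];
      if (f != 0.0) {
        for (int j = 0; j < N; ++j) T[(size_t)i * N + j] -= f * T[(size_t)r * N + j];
        rhs[i] -= f * rhs[r];
        if (rhs[i] < 0 && rhs[i] > -1e-11) rhs[i] = 0.0;
      }
    }
    double f = rc[q];
    if (f != 0.0) for (int j = 0; j < N; ++j) rc[j] -= f * T[(size_t)r * N + j];
    basis[r] = q;
  };

  if (neg_rhs) {
    for (int j = 0; j < N; ++j)
      if (rc[j] > EPS) { LPResult res; res.status = 4; return res; }
    while (true) {
      ++iter;
      if (iter > max_iter) { LPResult res; res.status = 3; return res; }
      int r = -1; double most = -1e-9;
      for (int i = 0; i < m; ++i)
        if (rhs[i] < most) { most = rhs[i]; r = i; }
      if (r < 0) break;  // primal feasible, hand over to the primal loop
      int q = -1; double best = 0.0;
      for (int j = 0; j < N; ++j) {
        double a = T[(size_t)r * N + j];
        if (a < -EPS) {
          double ratio = rc[j] / a;  // rc <= 0, a < 0 -> ratio >= 0
          if (q < 0 || ratio < best - 1e-12 ||
              (ratio < best + 1e-12 && j < q)) { q = j; best = ratio; }
        }
      }
      if (q < 0) { LPResult res; res.status = 1; return res; }
      pivot(r, q);
    }
  }

  while (true) {
    ++iter;
    if (iter > max_iter) { LPResult res; res.status = 3; return res; }
    bool bland = iter > bland_after;

    // pricing
    int q = -1; double bestrc = EPS;
    for (int j = 0; j < N; ++j) {
      if (!in_phase1 && is_art[j]) continue;   // artificials barred in phase 2
      if (rc[j] > (bland ? EPS : bestrc)) {
        q = j;
        if (bland) break;
        bestrc = rc[j];
      }
    }

    if (q < 0) {  // optimal for current phase
      if (in_phase1) {
        double p1 = 0.0;
        for (int i = 0; i < m; ++i)
          if (is_art[basis[i]]) p1 += rhs[i];
        if (p1 > 1e-7) { LPResult res; res.status = 1; return res; }
        // pivot remaining (degenerate) artificials out where possible
        for (int i = 0; i < m; ++i) {
          if (!is_art[basis[i]]) continue;
          int qq = -1;
          for (int j = 0; j < n + m; ++j) {
            if (std::fabs(T[(size_t)i * N + j]) > 1e-7) { qq = j; break; }
          }
          if (qq >= 0) pivot(i, qq);
          // else: redundant zero row; harmless to leave
        }
        std::fill(cost.begin(), cost.end(), 0.0);
        for (int j = 0; j < n; ++j) cost[j] = c[j];
        recompute_rc();
        in_phase1 = false;
        continue;
      }
      break;  // phase 2 optimal
    }

    // ratio test (smallest ratio; ties -> smallest basis index)
    int r = -1; double best = 0.0;
    for (int i = 0; i < m; ++i) {
      double a = T[(size_t)i * N + q];
      if (a > EPS) {
        double ratio = rhs[i] / a;
        if (r < 0 || ratio < best - 1e-12 ||
            (ratio < best + 1e-12 && basis[i] < basis[r])) {
          r = i; best = ratio;
        }
      }
    }
    if (r < 0) {
      if (in_phase1) { LPResult res; res.status = 1; return res; }  // cannot happen
      LPResult res; res.status = 2; return res;                     // unbounded
    }
    pivot(r, q);
  }

  LPResult res;
  res.status = 0;
  res.x.assign(n, 0.0);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) res.x[basis[i]] = rhs[i];
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += c[j] * res.x[j];
  res.obj = maximize ? obj : -obj;

  // duals: y_i = c_B' B^{-1} e_i, with B^{-1} e_i sitting under idcol[i]
  res.dual.assign(m, 0.0);
  for (int i = 0; i < m; ++i) {
    double y = 0.0;
    int col = idcol[i];
    for (int r2 = 0; r2 < m; ++r2) {
      double cb = cost[basis[r2]];
      if (cb != 0.0) y += cb * T[(size_t)r2 * N + col];
    }
    res.dual[i] = maximize ? y : -y;
  }
  return res;
}

// [[Rcpp::export]]
List simplex_lp_cpp(NumericMatrix A, NumericVector b, IntegerVector dir,
                    NumericVector c, bool maximize) {
  int m = A.nrow(), n = A.ncol();
  std::vector<double> Aflat((size_t)m * n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) Aflat[(size_t)i * n + j] = A(i, j);
  std::vector<double> bb(b.begin(), b.end());
  std::vector<int> dd(dir.begin(), dir.end());
  std::vector<double> cc(c.begin(), c.end());
  LPResult res = simplex_core(Aflat, m, n, bb, dd, cc, maximize);
  if (res.status != 0)
    return List::create(_["status"] = res.status);
  return List::create(_["status"] = 0, _["obj"] = res.obj,
                      _["x"] = NumericVector(res.x.begin(), res.x.end()),
                      _["dual"] = NumericVector(res.dual.begin(), res.dual.end()));
}

// Pareto filter: returns 1-based indices of rows of Y not weakly dominated
// by another row (direction +1: keep maximal rows, i.e. drop rows r with
// some q having Y[q,] >= Y[r,] and > somewhere; direction -1: keep minimal
// rows).  For BoD reference sets this pruning is exact: with alpha >= 0 a
// dominated row's constraint is implied by its dominator's.
// Ties (duplicate rows) keep the earliest row.
// [[Rcpp::export]]
IntegerVector pareto_filter_cpp(NumericMatrix Y, int direction) {
  int m = Y.nrow(), n = Y.ncol();
  std::vector<bool> drop(m, false);
  for (int r = 0; r < m; ++r) {
    for (int q = 0; q < m && !drop[r]; ++q) {
      if (q == r || drop[q]) continue;
      bool ge = true, gt = false;
      for (int j = 0; j < n; ++j) {
        double d = direction > 0 ? Y(q, j) - Y(r, j) : Y(r, j) - Y(q, j);
        if (d < 0) { ge = false; break; }
        if (d > 0) gt = true;
      }
      if (ge && (gt || q < r)) drop[r] = true;  // q < r breaks exact ties
    }
  }
  std::vector<int> keep;
  for (int r = 0; r < m; ++r) if (!drop[r]) keep.push_back(r + 1);
  return IntegerVector(keep.begin(), keep.end());
}

// BoD group scorer.  Yref is the reference set of one peer group
// (meta-frontier reference set, possibly Pareto-pruned); every row of Ytar
// is scored against it.
// Solves the n-row dual of each BoD program; by LP duality the dual values
// of the dual's rows are exactly the primal multipliers alpha:
//   optimistic:  primal max y_t'a, Ya <= 1, G a >= 0, a >= 0
//     dual: min 1'lam  s.t. Y'lam - G'mu >= y_t, lam,mu >= 0   (n rows)
//     solved in negated form  max -1'lam s.t. -Y'lam + G'mu <= -y_t,
//     whose all-slack basis is dual feasible (dual-simplex fast path)
//   pessimistic: primal min y_t'a, Ya >= 1, G a >= 0, a >= 0
//     dual: max 1'lam  s.t. Y'lam + G'mu <= y_t, lam,mu >= 0   (n rows)
// restriction 0 = none, 1 = multiplier_share, 2 = pie_share
// [[Rcpp::export]]
List bod_score_group_cpp(NumericMatrix Yref, NumericMatrix Ytar,
                         NumericVector w, int orientation,
                         int restriction) {
  int m = Yref.nrow(), n = Yref.ncol();
  bool optimistic = orientation == 0;
  int k = (restriction == 0) ? 0 : n;
  int ncols = m + k;                 // dual variables: lam (m) + mu (k)
  int nt = Ytar.nrow();
  double lam_sgn = optimistic ? -1.0 : 1.0;

  // dual constraint matrix D: n rows x ncols
  std::vector<double> D((size_t)n * ncols, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i)
      D[(size_t)j * ncols + i] = lam_sgn * Yref(i, j);

  // mu block carries +G' in both orientations (the optimistic system is
  // stated in negated form); multiplier_share G is target-independent
  if (restriction == 1) {
    for (int j = 0; j < n; ++j)        // row of D = variable j (column of G)
      for (int r = 0; r < n; ++r)      // mu_r ~ restriction row r
        D[(size_t)j * ncols + m + r] = (j == r ? 1.0 : 0.0) - w[r];
  }

  std::vector<int> dir(n, 0);          // all rows <=
  std::vector<double> cobj(ncols, 0.0);
  for (int i = 0; i < m; ++i) cobj[i] = lam_sgn;

  // fallback formulation for the optimistic dual: >= rows + phase 1
  std::vector<int> dir_ge(n, 1);

  NumericVector scores(nt);
  NumericMatrix alphas(nt, n);
  IntegerVector status(nt);

  for (int t = 0; t < nt; ++t) {
    int ti = t;
    if (restriction == 2) {            // pie-share G depends on the target
      for (int j = 0; j < n; ++j)
        for (int r = 0; r < n; ++r)
          D[(size_t)j * ncols + m + r] =
            (j == r ? Ytar(t, j) : 0.0) - w[r] * Ytar(t, j);
    }
    std::vector<double> b(n);
    for (int j = 0; j < n; ++j) b[j] = lam_sgn * Ytar(t, j);

    LPResult res = simplex_core(D, n, ncols, b, dir, cobj, true);
    if (optimistic && res.status != 0 && res.status != 1) {
      // robust fallback: same dual in >= form via two-phase simplex
      std::vector<double> D2((size_t)n * ncols);
      std::vector<double> b2(n), c2(ncols, 0.0);
      for (size_t z = 0; z < D.size(); ++z) D2[z] = -D[z];
      for (int j = 0; j < n; ++j) b2[j] = -b[j];
      for (int i = 0; i < m; ++i) c2[i] = 1.0;
      res = simplex_core(D2, n, ncols, b2, dir_ge, c2, false);
      if (res.status == 0) res.obj = -res.obj;  // back to the negated-max scale
    }
    status[ti] = res.status;
    if (res.status == 0) {
      scores[ti] = optimistic ? -res.obj : res.obj;
      for (int j = 0; j < n; ++j) {
        double a = res.dual[j];
        alphas(ti, j) = (a < 0 && a > -1e-9) ? 0.0 : a;
      }
    } else {
      scores[ti] = NA_REAL;
      for (int j = 0; j < n; ++j) alphas(ti, j) = NA_REAL;
    }
  }
  return List::create(_["score"] = scores, _["alpha"] = alphas,
                      _["status"] = status);
}
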