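// Exact solver for small 0/1 integer programs:
//   maximize c'v  subject to  rlb <= A v <= rub,  v binary.
// Depth-first branch and bound with bound-consistency propagation on the
// rows and the trivial objective bound (sum of attainable coefficients).
// Deterministic: fixed branching order, value 1 tried before 0.
#include <Rcpp.h>
#include <chrono>
#include <vector>
using namespace Rcpp;

namespace {

struct Problem {
  int nvar;
  std::vector<double> obj;
  // rows in compressed form
  std::vector<std::vector<int>> rcols;
  std::vector<std::vector<double>> rcoefs;
  std::vector<double> rlb, rub;
  std::vector<std::vector<int>> var_rows;  // rows touching each var
  std::vector<int> branch_order;
  double eps = 1e-9;
};

struct Search {
  const Problem* p;
  double best_obj;
  std::vector<int> best_sol;
  bool have_incumbent = false;
  long nodes = 0;
  double time_limit;  // seconds; <=0 means none
  bool aborted = false;
  std::chrono::steady_clock::time_point t0;

  double elapsed() const {
    return std::chrono::duration<double>(
               std::chrono::steady_clock::now() - t0)
        .count();
  }

  bool time_up() const {
    return time_limit > 0 && elapsed() > time_limit;
  }

  // returns false on infeasibility
  bool propagate(std::vector<int>& lo, std::vector<int>& hi) {
    bool changed = true;
    while (changed) {
      changed = false;
      for (size_t r = 0; r < p->rcols.size(); ++r) {
        const auto& cols = p->rcols[r];
        const auto& cf = p->rcoefs[r];
        double minA = 0, maxA = 0;
        for (size_t t = 0; t < cols.size(); ++t) {
          double a = cf[t];
          int j = cols[t];
          minA += a > 0 ? a * lo[j] : a * hi[j];
          maxA += a > 0 ? a * hi[j] : a * lo[j];
        }
        if (minA > p->rub[r] + p->eps || maxA < p->rlb[r] - p->eps)
          return false;
        for (size_t t = 0; t < cols.size(); ++t) {
          int j = cols[t];
          if (lo[j] == hi[j]) continue;
          double a = cf[t];
          double cmin = a > 0 ? a * lo[j] : a * hi[j];
          double cmax = a > 0 ? a * hi[j] : a * lo[j];
          bool ok0 = !(minA - cmin > p->rub[r] + p->eps ||
                       maxA - cmax < p->rlb[r] - p->eps);
          bool ok1 = !(minA - cmin + a > p->rub[r] + p->eps ||
                       maxA - cmax + a < p->rlb[r] - p->eps);
          if (!ok0 && !ok1) return false;
          if (!ok0) { lo[j] = 1; changed = true; }
          else if (!ok1) { hi[j] = 0; changed = true; }
        }
      }
    }
    return true;
  }

  void dfs(std::vector<int> lo, std::vector<int> hi) {
    if (aborted) return;
    ++nodes;
    if ((nodes & 255) == 0 && have_incumbent && time_up()) {
      aborted = true;
      return;
    }
    if (!propagate(lo, hi)) return;
    double bound = 0;
    for (int j = 0; j < p->nvar; ++j)
      bound += p->obj[j] > 0 ? p->obj[j] * hi[j] : p->obj[j] * lo[j];
    if (have_incumbent && bound <= best_obj + p->eps) return;
    int branch = -1;
    for (int j : p->branch_order)
      if (lo[j] < hi[j]) { branch = j; break; }
    if (branch < 0) {
      double val = 0;
      for (int j = 0; j < p->nvar; ++j) val += p->obj[j] * lo[j];
      if (!have_incumbent || val > best_obj) {
        best_obj = val;
        best_sol.assign(lo.begin(), lo.end());
        have_incumbent = true;
      }
      return;
    }
    {
      std::vector<int> lo1 = lo, hi1 = hi;
      lo1[branch] = 1;
      dfs(std::move(lo1), std::move(hi1));
    }
    if (aborted) return;
    hi[branch] = 0;
    dfs(std::move(lo), std::move(hi));
  }
};

}  // namespace

// [[Rcpp::export(name = ".bnb_solve")]]
List bnb_solve(int nvar, NumericVector obj, IntegerVector rowptr_col,
               IntegerVector rowptr_len, IntegerVector cols,
               NumericVector coefs, NumericVector rlb, NumericVector rub,
               IntegerVector branch_order, double time_limit) {
  Problem p;
  p.nvar = nvar;
  p.obj.assign(obj.begin(), obj.end());
  int nrow = rlb.size();
  p.rlb.assign(rlb.begin(), rlb.end());
  p.rub.assign(rub.begin(), rub.end());
  p.rcols.resize(nrow);
  p.rcoefs.resize(nrow);
  for (int r = 0; r < nrow; ++r) {
    int off = rowptr_col[r], len = rowptr_len[r];
    for (int t = 0; t < len; ++t) {
      p.rcols[r].push_back(cols[off + t]);
      p.rcoefs[r].push_back(coefs[off + t]);
    }
  }
  p.branch_order.assign(branch_order.begin(), branch_order.end());
  for (int j = 0; j < nvar; ++j)
    if (std::find(p.branch_order.begin(), p.branch_order.end(), j) ==
        p.branch_order.end())
      p.branch_order.push_back(j);

  Search s;
  s.p = &p;
  s.best_obj = -std::numeric_limits<double>::infinity();
  s.time_limit = time_limit;
  s.t0 = std::chrono::steady_clock::now();
  std::vector<int> lo(nvar, 0), hi(nvar, 1);
  s.dfs(lo, hi);

  int status;  // 0 optimal, 1 time-limit incumbent, 2 no incumbent
  if (!s.have_incumbent)
    status = 2;
  else if (s.aborted)
    status = 1;
  else
    status = 0;
  IntegerVector sol(nvar, NA_INTEGER);
  if (s.have_incumbent)
    for (int j = 0; j < nvar; ++j) sol[j] = s.best_sol[j];
  return List::create(_["solution"] = sol,
                      _["objective"] = s.have_incumbent
                          ? s.best_obj
                          : NA_REAL,
                      _["status"] = status, _["nodes"] = (double)s.nodes,
                      _["seconds"] = s.elapsed());
}
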