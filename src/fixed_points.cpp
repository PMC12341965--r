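#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact enumeration of the fixed points x = f(x) of a link-operator Boolean
// model by depth-first search with unit propagation.  Node update rule:
//   f_v = Act_v            (activators only)
//   f_v = !Inh_v           (inhibitors only)
//   f_v = Act_v && !Inh_v  (op == 1, AND-NOT)
//   f_v = Act_v || !Inh_v  (op == 2, OR-NOT)
// where Act_v / Inh_v are ORs over the regulator lists.  fixedv[v] in {0,1}
// overrides the rule with a constant (perturbed node); -1 means free.

namespace {

struct Solver {
  int n;
  std::vector< std::vector<int> > act, inh;
  std::vector<int> op, fixedv;
  std::vector< std::vector<int> > found;
  int max_fp;
  bool overflow;

  // Three-valued (0/1/-1=unknown) evaluation of f_v under partial state s.
  int eval(const std::vector<int> &s, int v) const {
    if (fixedv[v] >= 0) return fixedv[v];
    int a = 0;
    for (size_t k = 0; k < act[v].size(); ++k) {
      int sv = s[act[v][k]];
      if (sv == 1) { a = 1; break; }
      if (sv < 0) a = -1;
    }
    int i = 0;
    for (size_t k = 0; k < inh[v].size(); ++k) {
      int sv = s[inh[v][k]];
      if (sv == 1) { i = 1; break; }
      if (sv < 0) i = -1;
    }
    if (inh[v].empty()) return a;
    if (act[v].empty()) return i < 0 ? -1 : 1 - i;
    if (op[v] == 1) {                 // Act && !Inh
      if (a == 0 || i == 1) return 0;
      if (a == 1 && i == 0) return 1;
      return -1;
    }
    // Act || !Inh
    if (a == 1 || i == 0) return 1;
    if (a == 0 && i == 1) return 0;
    return -1;
  }

  // Returns false on contradiction with the fixed-point constraints.
  bool propagate(std::vector<int> &s) const {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int v = 0; v < n; ++v) {
        int fv = eval(s, v);
        if (fv < 0) continue;
        if (s[v] < 0) { s[v] = fv; changed = true; }
        else if (s[v] != fv) return false;
      }
    }
    return true;
  }

  void search(std::vector<int> s) {
    if (overflow) return;
    if (!propagate(s)) return;
    int branch = -1;
    for (int v = 0; v < n; ++v) if (s[v] < 0) { branch = v; break; }
    if (branch < 0) {
      if ((int)found.size() >= max_fp) { overflow = true; return; }
      found.push_back(s);
      return;
    }
    std::vector<int> s0(s);
    s0[branch] = 0;
    search(s0);
    s[branch] = 1;
    search(s);
  }
};

} // namespace

// [[Rcpp::export(name = ".fp_enumerate_cpp")]]
List fp_enumerate_cpp(List act, List inh, IntegerVector op,
                      IntegerVector fixedv, int max_fp) {
  Solver sol;
  sol.n = op.size();
  sol.max_fp = max_fp;
  sol.overflow = false;
  sol.act.resize(sol.n);
  sol.inh.resize(sol.n);
  sol.op.assign(op.begin(), op.end());
  sol.fixedv.assign(fixedv.begin(), fixedv.end());
  for (int v = 0; v < sol.n; ++v) {
    IntegerVector a = act[v], i = inh[v];
    for (int k = 0; k < a.size(); ++k) sol.act[v].push_back(a[k] - 1);
    for (int k = 0; k < i.size(); ++k) sol.inh[v].push_back(i[k] - 1);
  }
  std::vector<int> s(sol.n, -1);
  sol.search(s);

  int nfp = sol.found.size();
  IntegerMatrix fp(nfp, sol.n);
  for (int r = 0; r < nfp; ++r)
    for (int v = 0; v < sol.n; ++v) fp(r, v) = sol.found[r][v];
  return List::create(_["fixed_points"] = fp, _["overflow"] = sol.overflow);
}

// Synchronous update image f(x) for a batch of full states (rows of `states`).
// Used for truth-table style checks and cheap simulation utilities.
// [[Rcpp::export(name = ".fp_update_cpp")]]
IntegerMatrix fp_update_cpp(List act, List inh, IntegerVector op,
                            IntegerVector fixedv, IntegerMatrix states) {
  int n = op.size(), m = states.nrow();
  IntegerMatrix out(m, n);
  for (int r = 0; r < m; ++r) {
    for (int v = 0; v < n; ++v) {
      if (fixedv[v] >= 0) { out(r, v) = fixedv[v]; continue; }
      IntegerVector a = act[v], i = inh[v];
      int A = 0, I = 0;
      for (int k = 0; k < a.size(); ++k) if (states(r, a[k] - 1) == 1) { A = 1; break; }
      for (int k = 0; k < i.size(); ++k) if (states(r, i[k] - 1) == 1) { I = 1; break; }
      int fv;
      if (i.size() == 0) fv = A;
      else if (a.size() == 0) fv = 1 - I;
      else if (op[v] == 1) fv = (A == 1 && I == 0) ? 1 : 0;
      else fv = (A == 1 || I == 0) ? 1 : 0;
      out(r, v) = fv;
    }
  }
  return out;
}
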