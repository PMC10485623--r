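// Simulation / scoring core.
//
// A model arrives from R in "compiled" form: per-species activator and
// inhibitor terms (0-based member index vectors) plus an optional frozen
// clause in disjunctive normal form (signed 1-based literals; +i = species
// i-1 must be on, -i = off). Species without a rule are external inputs and
// hold their initial value. All state vectors are synchronous-update binary
// vectors; cyclic attractors are averaged into fractional representatives.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstring>
#include <cmath>
using namespace Rcpp;

struct Term {
  std::vector<int> members;
};

struct Rule {
  bool has_rule = false;
  std::vector<Term> acts;
  std::vector<Term> inhs;
  std::vector<std::vector<int>> frozen; // DNF clauses, signed 1-based literals
  bool frozen_true = false;             // frozen clause is the constant TRUE
};

struct CModel {
  int n = 0;
  std::vector<Rule> rules;
};

typedef std::vector<uint8_t> BState;

static inline bool eval_term(const Term& t, const BState& s) {
  for (int m : t.members) if (!s[m]) return false;
  return true;
}

static inline bool eval_frozen(const Rule& r, const BState& s) {
  if (r.frozen_true) return true;
  for (const auto& clause : r.frozen) {
    bool ok = true;
    for (int lit : clause) {
      if (lit > 0) { if (!s[lit - 1]) { ok = false; break; } }
      else         { if (s[-lit - 1]) { ok = false; break; } }
    }
    if (ok) return true;
  }
  return false;
}

static inline bool eval_rule(const Rule& r, const BState& s) {
  bool act = eval_frozen(r, s);
  if (!act) {
    for (const auto& t : r.acts) if (eval_term(t, s)) { act = true; break; }
  }
  if (!act) return false;
  for (const auto& t : r.inhs) if (eval_term(t, s)) return false;
  return true;
}

// mask: species forced to constant 0 (gene knockouts)
static void do_step(const CModel& m, const BState& cur, BState& nxt,
                    const std::vector<uint8_t>& mask) {
  for (int i = 0; i < m.n; ++i) {
    if (mask[i]) { nxt[i] = 0; continue; }
    const Rule& r = m.rules[i];
    nxt[i] = r.has_rule ? (eval_rule(r, cur) ? 1 : 0) : cur[i];
  }
}

static inline std::string state_key(const BState& s) {
  return std::string(reinterpret_cast<const char*>(s.data()), s.size());
}

struct Traj {
  std::vector<BState> states;
  int attractor_start = 0;
  int period = 1;
};

static bool run_to_attractor_c(const CModel& m, BState init,
                               const std::vector<uint8_t>& mask,
                               int max_steps, Traj& out) {
  for (int i = 0; i < m.n; ++i) if (mask[i]) init[i] = 0;
  out.states.clear();
  std::unordered_map<std::string, int> seen;
  BState cur = init, nxt(m.n);
  for (int step = 0; step <= max_steps; ++step) {
    auto it = seen.find(state_key(cur));
    if (it != seen.end()) {
      out.attractor_start = it->second;
      out.period = (int)out.states.size() - it->second;
      out.states.push_back(cur); // record the closing repeat
      return true;
    }
    seen[state_key(cur)] = (int)out.states.size();
    out.states.push_back(cur);
    do_step(m, cur, nxt, mask);
    std::swap(cur, nxt);
  }
  return false;
}

static std::vector<double> representative(const Traj& t) {
  int n = (int)t.states[0].size();
  std::vector<double> rep(n, 0.0);
  for (int k = 0; k < t.period; ++k) {
    const BState& s = t.states[t.attractor_start + k];
    for (int i = 0; i < n; ++i) rep[i] += s[i];
  }
  for (int i = 0; i < n; ++i) rep[i] /= t.period;
  return rep;
}

// ---- census ---------------------------------------------------------------

struct Census {
  // keys kept lexicographically sorted via std::map on the value vector
  std::map<std::vector<double>, int> entries;
  int total = 0;
};

static bool census_c(const CModel& m, const std::vector<BState>& initials,
                     const std::vector<uint8_t>& mask, int max_steps,
                     Census& out) {
  out.entries.clear();
  out.total = 0;
  Traj t;
  for (const BState& ini : initials) {
    if (!run_to_attractor_c(m, ini, mask, max_steps, t)) return false;
    out.entries[representative(t)] += 1;
    out.total += 1;
  }
  return true;
}

// ---- greedy attractor edit distance --------------------------------------

static inline double manhattan(const std::vector<double>& a,
                               const std::vector<double>& b) {
  double d = 0;
  for (size_t i = 0; i < a.size(); ++i) d += std::fabs(a[i] - b[i]);
  return d;
}

struct EditStepRec {
  int sim, ref, transferred;
  double dist, cost;
};

// sim/ref entries must be lexicographically sorted by state (std::map order);
// ties among equal-distance pairs break to the smallest (sim, ref) pair.
static double edit_distance_c(const std::vector<std::vector<double>>& sim_states,
                              std::vector<int> sim_counts,
                              const std::vector<std::vector<double>>& ref_states,
                              std::vector<int> ref_counts,
                              int n_species, int n_c,
                              std::vector<EditStepRec>* steps) {
  double total = 0;
  int remaining = n_c;
  while (remaining > 0) {
    double best = -1;
    int bi = -1, bj = -1;
    for (size_t i = 0; i < sim_states.size(); ++i) {
      if (sim_counts[i] <= 0) continue;
      for (size_t j = 0; j < ref_states.size(); ++j) {
        if (ref_counts[j] <= 0) continue;
        double d = manhattan(sim_states[i], ref_states[j]);
        if (best < 0 || d < best) { best = d; bi = (int)i; bj = (int)j; }
      }
    }
    int k = std::min(sim_counts[bi], ref_counts[bj]);
    sim_counts[bi] -= k;
    ref_counts[bj] -= k;
    remaining -= k;
    total += best * k;
    if (steps) steps->push_back({bi, bj, k, best, best * k});
  }
  return total / ((double)n_species * (double)n_c);
}

// ---- R-facing model conversion -------------------------------------------

static CModel model_from_list(const List& ml) {
  CModel m;
  m.n = as<int>(ml["n"]);
  LogicalVector has_rule = ml["has_rule"];
  List acts = ml["acts"], inhs = ml["inhs"], frozen = ml["frozen"];
  LogicalVector ftrue = ml["frozen_true"];
  m.rules.resize(m.n);
  for (int i = 0; i < m.n; ++i) {
    Rule& r = m.rules[i];
    r.has_rule = has_rule[i];
    if (!r.has_rule) continue;
    List ai = acts[i], ii = inhs[i], fi = frozen[i];
    for (int k = 0; k < ai.size(); ++k) {
      Term t; IntegerVector v = ai[k];
      t.members.assign(v.begin(), v.end());
      r.acts.push_back(t);
    }
    for (int k = 0; k < ii.size(); ++k) {
      Term t; IntegerVector v = ii[k];
      t.members.assign(v.begin(), v.end());
      r.inhs.push_back(t);
    }
    r.frozen_true = ftrue[i];
    for (int k = 0; k < fi.size(); ++k) {
      IntegerVector v = fi[k];
      r.frozen.push_back(std::vector<int>(v.begin(), v.end()));
    }
  }
  return m;
}

static std::vector<BState> states_from_matrix(const IntegerMatrix& mat) {
  std::vector<BState> out(mat.nrow(), BState(mat.ncol()));
  for (int i = 0; i < mat.nrow(); ++i)
    for (int j = 0; j < mat.ncol(); ++j)
      out[i][j] = (uint8_t)mat(i, j);
  return out;
}

static std::vector<uint8_t> mask_from_ids(int n, const IntegerVector& ids) {
  std::vector<uint8_t> mask(n, 0);
  for (int id : ids) mask[id] = 1; // 0-based
  return mask;
}

// [[Rcpp::export]]
IntegerVector cpp_step(List model, IntegerVector state) {
  CModel m = model_from_list(model);
  BState cur(state.begin(), state.end()), nxt(m.n);
  std::vector<uint8_t> mask(m.n, 0);
  do_step(m, cur, nxt, mask);
  return IntegerVector(nxt.begin(), nxt.end());
}

// [[Rcpp::export]]
List cpp_run_to_attractor(List model, IntegerVector state, int max_steps) {
  CModel m = model_from_list(model);
  BState init(state.begin(), state.end());
  std::vector<uint8_t> mask(m.n, 0);
  Traj t;
  if (!run_to_attractor_c(m, init, mask, max_steps, t))
    stop("no repeated state within max_steps = %d steps", max_steps);
  IntegerMatrix states((int)t.states.size(), m.n);
  for (size_t i = 0; i < t.states.size(); ++i)
    for (int j = 0; j < m.n; ++j) states((int)i, j) = t.states[i][j];
  return List::create(_["states"] = states,
                      _["attractor_start"] = t.attractor_start + 1,
                      _["period"] = t.period);
}

// [[Rcpp::export]]
List cpp_census(List model, IntegerMatrix initials, IntegerVector mask_ids,
                int max_steps) {
  CModel m = model_from_list(model);
  std::vector<uint8_t> mask = mask_from_ids(m.n, mask_ids);
  Census c;
  if (!census_c(m, states_from_matrix(initials), mask, max_steps, c))
    stop("no repeated state within max_steps = %d steps", max_steps);
  NumericMatrix states((int)c.entries.size(), m.n);
  IntegerVector counts((int)c.entries.size());
  int row = 0;
  for (const auto& kv : c.entries) {
    for (int j = 0; j < m.n; ++j) states(row, j) = kv.first[j];
    counts[row] = kv.second;
    ++row;
  }
  return List::create(_["states"] = states, _["counts"] = counts,
                      _["total"] = c.total);
}

static std::vector<std::vector<double>> rows_of(const NumericMatrix& m) {
  std::vector<std::vector<double>> out(m.nrow(), std::vector<double>(m.ncol()));
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j) out[i][j] = m(i, j);
  return out;
}

// Sorts both censuses lexicographically before the greedy loop so the
// documented tie-break (smallest sim state, then smallest ref state) holds.
// [[Rcpp::export]]
List cpp_edit_distance(NumericMatrix sim_states, IntegerVector sim_counts,
                       NumericMatrix ref_states, IntegerVector ref_counts,
                       int n_species) {
  std::map<std::vector<double>, int> sim, ref;
  auto ss = rows_of(sim_states), rs = rows_of(ref_states);
  for (size_t i = 0; i < ss.size(); ++i) sim[ss[i]] += sim_counts[(int)i];
  for (size_t i = 0; i < rs.size(); ++i) ref[rs[i]] += ref_counts[(int)i];
  int ntot = 0, rtot = 0;
  std::vector<std::vector<double>> s2, r2;
  std::vector<int> sc, rc;
  for (auto& kv : sim) { s2.push_back(kv.first); sc.push_back(kv.second); ntot += kv.second; }
  for (auto& kv : ref) { r2.push_back(kv.first); rc.push_back(kv.second); rtot += kv.second; }
  if (ntot != rtot) stop("occurrence totals must match (%d vs %d)", ntot, rtot);
  if (ntot == 0) stop("empty censuses");
  std::vector<EditStepRec> steps;
  double d = edit_distance_c(s2, sc, r2, rc, n_species, ntot, &steps);
  int ns = (int)steps.size();
  IntegerVector si(ns), ri(ns), tr(ns);
  NumericVector dist(ns), cost(ns);
  double total = 0;
  for (int i = 0; i < ns; ++i) {
    si[i] = steps[i].sim + 1; ri[i] = steps[i].ref + 1;
    tr[i] = steps[i].transferred; dist[i] = steps[i].dist; cost[i] = steps[i].cost;
    total += steps[i].cost;
  }
  NumericMatrix s2m((int)s2.size(), n_species);
  NumericMatrix r2m((int)r2.size(), n_species);
  for (size_t i = 0; i < s2.size(); ++i)
    for (int j = 0; j < n_species; ++j) s2m((int)i, j) = s2[i][j];
  for (size_t i = 0; i < r2.size(); ++i)
    for (int j = 0; j < n_species; ++j) r2m((int)i, j) = r2[i][j];
  return List::create(_["sim_idx"] = si, _["ref_idx"] = ri,
                      _["transferred"] = tr, _["per_state_distance"] = dist,
                      _["cost"] = cost, _["total_cost"] = total,
                      _["d_edit"] = d, _["n_c"] = ntot,
                      _["sim_states"] = s2m, _["ref_states"] = r2m);
}

// ---- compiled search problem ----------------------------------------------

struct ActionInstance {
  int target;
  int sign; // 0 activate, 1 inhibit
  std::vector<int> members;
};

struct CProblem {
  CModel base;
  std::vector<std::vector<ActionInstance>> actions; // per action id
  std::vector<int> opp;                             // opposite-sign partner or -1
  struct Cond {
    std::vector<BState> initials;
    std::vector<uint8_t> mask;
    std::vector<std::vector<double>> ref_states;
    std::vector<int> ref_counts;
    int ref_total;
  };
  std::vector<Cond> conds;
  int max_steps_sim = 10000;
};

// [[Rcpp::export]]
SEXP cpp_compile_problem(List base_model, List actions, IntegerVector opp,
                         List conditions, int max_steps_sim) {
  CProblem* p = new CProblem();
  p->base = model_from_list(base_model);
  p->max_steps_sim = max_steps_sim;
  for (int a = 0; a < actions.size(); ++a) {
    List inst = actions[a];
    std::vector<ActionInstance> vec;
    for (int k = 0; k < inst.size(); ++k) {
      List one = inst[k];
      ActionInstance ai;
      ai.target = as<int>(one["target"]);
      ai.sign = as<int>(one["sign"]);
      IntegerVector mem = one["members"];
      ai.members.assign(mem.begin(), mem.end());
      vec.push_back(ai);
    }
    p->actions.push_back(vec);
  }
  p->opp.assign(opp.begin(), opp.end());
  for (int c = 0; c < conditions.size(); ++c) {
    List cl = conditions[c];
    CProblem::Cond cond;
    cond.initials = states_from_matrix(as<IntegerMatrix>(cl["initials"]));
    cond.mask = mask_from_ids(p->base.n, as<IntegerVector>(cl["mask"]));
    NumericMatrix rstates = cl["ref_states"];
    // aggregate duplicate reference states into one multiset entry
    std::map<std::vector<double>, int> agg;
    IntegerVector rcounts = cl["ref_counts"];
    auto rows = rows_of(rstates);
    for (size_t i = 0; i < rows.size(); ++i) agg[rows[i]] += rcounts[(int)i];
    cond.ref_total = 0;
    for (auto& kv : agg) {
      cond.ref_states.push_back(kv.first);
      cond.ref_counts.push_back(kv.second);
      cond.ref_total += kv.second;
    }
    p->conds.push_back(cond);
  }
  XPtr<CProblem> ptr(p, true);
  return ptr;
}

static void apply_action(CModel& m, const ActionInstance& ai) {
  Rule& r = m.rules[ai.target];
  r.has_rule = true;
  Term t; t.members = ai.members;
  if (ai.sign == 0) r.acts.push_back(t); else r.inhs.push_back(t);
}

static double score_model(const CProblem& p, const CModel& m, bool* ok) {
  double acc = 0;
  Census c;
  for (const auto& cond : p.conds) {
    if (!census_c(m, cond.initials, cond.mask, p.max_steps_sim, c)) {
      *ok = false;
      return 0;
    }
    if (c.total != cond.ref_total)
      stop("occurrence totals must match (%d vs %d)", c.total, cond.ref_total);
    std::vector<std::vector<double>> ss;
    std::vector<int> sc;
    for (const auto& kv : c.entries) { ss.push_back(kv.first); sc.push_back(kv.second); }
    double d = edit_distance_c(ss, sc, cond.ref_states, cond.ref_counts,
                               m.n, c.total, nullptr);
    acc += 1.0 - d;
  }
  *ok = true;
  return acc / (double)p.conds.size();
}

static CModel build_model(const CProblem& p, const std::vector<int>& ids) {
  CModel m = p.base;
  for (int id : ids)
    for (const auto& ai : p.actions[id]) apply_action(m, ai);
  return m;
}

// [[Rcpp::export]]
double cpp_score_ids(SEXP ptr, IntegerVector ids) {
  XPtr<CProblem> p(ptr);
  std::vector<int> v(ids.begin(), ids.end());
  CModel m = build_model(*p, v);
  bool ok;
  double s = score_model(*p, m, &ok);
  if (!ok) stop("simulation exceeded step cap");
  return s;
}

// Uniform random rollout: starting from the model defined by `ids`, add
// uniformly sampled valid actions (not present, opposite sign not present)
// until the model holds `depth_target` actions or no valid action remains,
// then score the terminal model. Uses the R RNG stream.
// [[Rcpp::export]]
List cpp_rollout_score(SEXP ptr, IntegerVector ids, int depth_target) {
  XPtr<CProblem> p(ptr);
  int nact = (int)p->actions.size();
  std::vector<uint8_t> present(nact, 0);
  std::vector<int> cur(ids.begin(), ids.end());
  for (int id : cur) present[id] = 1;
  std::vector<int> valid;
  valid.reserve(nact);
  for (int a = 0; a < nact; ++a) {
    if (present[a]) continue;
    if (p->opp[a] >= 0 && present[p->opp[a]]) continue;
    valid.push_back(a);
  }
  std::vector<int> added;
  while ((int)cur.size() < depth_target && !valid.empty()) {
    int pick = (int)std::floor(unif_rand() * valid.size());
    if (pick >= (int)valid.size()) pick = (int)valid.size() - 1;
    int a = valid[pick];
    cur.push_back(a);
    added.push_back(a);
    present[a] = 1;
    int o = p->opp[a];
    // compact the valid list, dropping the chosen action and its opposite
    size_t w = 0;
    for (size_t r = 0; r < valid.size(); ++r) {
      if (valid[r] == a || (o >= 0 && valid[r] == o)) continue;
      valid[w++] = valid[r];
    }
    valid.resize(w);
  }
  CModel m = build_model(*p, cur);
  bool ok;
  double s = score_model(*p, m, &ok);
  if (!ok) stop("simulation exceeded step cap");
  return List::create(_["added"] = IntegerVector(added.begin(), added.end()),
                      _["score"] = s);
}

// [[Rcpp::export]]
IntegerVector cpp_valid_ids(SEXP ptr, IntegerVector ids) {
  XPtr<CProblem> p(ptr);
  int nact = (int)p->actions.size();
  std::vector<uint8_t> present(nact, 0);
  for (int id : ids) present[id] = 1;
  std::vector<int> valid;
  for (int a = 0; a < nact; ++a) {
    if (present[a]) continue;
    if (p->opp[a] >= 0 && present[p->opp[a]]) continue;
    valid.push_back(a);
  }
  return IntegerVector(valid.begin(), valid.end());
}
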