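// Compiled simulation engine.
//
// Implements the same per-agent cycle as the R reference engine
// (death-birth; learning dispatched between algorithmic mediation and
// social learning; innovation on learning failure) but runs the whole
// horizon in one call.  All randomness comes from R's global RNG stream
// (RNGScope), so set.seed() at the R level fully determines a run.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline long long trait_key(int branch, int level) {
  return (static_cast<long long>(branch) << 32) |
         static_cast<unsigned int>(level);
}

// uniform integer in 0..(m-1); unif_rand() < 1 strictly, guard anyway
static inline int runif_int(int m) {
  int v = static_cast<int>(unif_rand() * m);
  return (v >= m) ? m - 1 : v;
}

namespace {

struct ArchiveLevel {
  int maxz = 0;
  std::vector<int> best;  // branches whose payoff equals maxz
};

struct Engine {
  int n, branches, strategy, horizon;
  double budget0, ci, cs, cr, r, q, rate;

  std::vector<std::vector<int>> adj;

  // agent state (index = node id - 1)
  std::vector<double> budget, zsum;
  std::vector<int> level;
  std::vector<std::vector<int>> rep_branch, rep_payoff;
  std::vector<int> n_social, n_rec, n_innov;

  // world state
  std::unordered_map<long long, int> payoffs;
  std::unordered_set<long long> archived;
  std::vector<ArchiveLevel> archive;
  int total_traits = 0;

  // run-level counters
  long long replacements = 0, n_mediated = 0, n_social_dispatch = 0;

  int payoff_of(int branch, int lvl) {
    long long k = trait_key(branch, lvl);
    auto it = payoffs.find(k);
    if (it != payoffs.end()) return it->second;
    double d = exp_rand() / rate;
    int z = static_cast<int>(std::floor(2.0 * d * d + 0.5));
    payoffs.emplace(k, z);
    return z;
  }

  void acquire(int i, int branch, int z) {
    rep_branch[i].push_back(branch);
    rep_payoff[i].push_back(z);
    level[i] += 1;
    zsum[i] += z;
  }

  void archive_add(int branch, int lvl, int z) {
    if (!archived.insert(trait_key(branch, lvl)).second) return;
    total_traits += 1;
    if (static_cast<int>(archive.size()) < lvl) archive.resize(lvl);
    ArchiveLevel& al = archive[lvl - 1];
    if (z > al.maxz) {
      al.maxz = z;
      al.best.assign(1, branch);
    } else if (z == al.maxz) {
      al.best.push_back(branch);
    }
  }

  void reset_agent(int i) {
    budget[i] = budget0;
    zsum[i] = 0.0;
    level[i] = 0;
    rep_branch[i].clear();
    rep_payoff[i].clear();
    n_social[i] = n_rec[i] = n_innov[i] = 0;
  }

  void step_agent(int i) {
    // (i) death-birth
    if (q > 0 && unif_rand() < q) {
      reset_agent(i);
      replacements += 1;
    }
    // (ii) learning
    bool learned = false;
    bool mediated = unif_rand() < r;
    if (mediated) {
      n_mediated += 1;
      int lvl = level[i] + 1;
      if (lvl <= static_cast<int>(archive.size()) &&
          !archive[lvl - 1].best.empty() && budget[i] >= cr) {
        const ArchiveLevel& al = archive[lvl - 1];
        int m = static_cast<int>(al.best.size());
        int branch = al.best[m > 1 ? runif_int(m) : 0];
        acquire(i, branch, al.maxz);
        budget[i] -= cr;
        n_rec[i] += 1;
        learned = true;
      }
    } else {
      n_social_dispatch += 1;
      const std::vector<int>& nb = adj[i];
      if (!nb.empty()) {
        int teacher = -1;
        if (strategy == 2) {  // random neighbour
          teacher = nb[runif_int(static_cast<int>(nb.size()))];
        } else {              // payoff- or level-biased, uniform tie-break
          double best = -1.0;
          int ties = 0;
          for (int j : nb) {
            double v = (strategy == 0) ? zsum[j]
                                       : static_cast<double>(level[j]);
            if (v > best) { best = v; ties = 1; }
            else if (v == best) { ties += 1; }
          }
          int pick = (ties > 1) ? runif_int(ties) : 0;
          int seen = 0;
          for (int j : nb) {
            double v = (strategy == 0) ? zsum[j]
                                       : static_cast<double>(level[j]);
            if (v == best && seen++ == pick) { teacher = j; break; }
          }
        }
        if (teacher >= 0 && level[teacher] >= level[i] + 1 &&
            budget[i] >= cs) {
          int li = level[i];  // teacher's trait at level li+1 = index li
          acquire(i, rep_branch[teacher][li], rep_payoff[teacher][li]);
          budget[i] -= cs;
          n_social[i] += 1;
          learned = true;
        }
      }
    }
    // (iii) innovation, only if learning did not succeed
    if (!learned && budget[i] >= ci) {
      budget[i] -= ci;
      n_innov[i] += 1;
      int branch = runif_int(branches) + 1;
      int lvl = level[i] + 1;
      int z = payoff_of(branch, lvl);
      if (z > 0) {
        acquire(i, branch, z);
        archive_add(branch, lvl, z);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List engine_run(List adj, int n, double budget0, double ci, double cs,
                double cr, int branches, double r, double q, double rate,
                int strategy, int horizon, bool detail) {
  Engine e;
  e.n = n; e.branches = branches; e.strategy = strategy;
  e.horizon = horizon;
  e.budget0 = budget0; e.ci = ci; e.cs = cs; e.cr = cr;
  e.r = r; e.q = q; e.rate = rate;

  e.adj.resize(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    e.adj[i].assign(v.begin(), v.end());
    for (int& x : e.adj[i]) x -= 1;  // to 0-based
  }
  e.budget.assign(n, budget0);
  e.zsum.assign(n, 0.0);
  e.level.assign(n, 0);
  e.rep_branch.resize(n);
  e.rep_payoff.resize(n);
  e.n_social.assign(n, 0);
  e.n_rec.assign(n, 0);
  e.n_innov.assign(n, 0);

  NumericVector zbar(horizon), lbar(horizon);
  IntegerVector tser(horizon), tcol(horizon);

  // optional per-step snapshots for invariant auditing (small n only)
  NumericMatrix snap_budget, snap_z;
  IntegerMatrix snap_level, snap_ns, snap_nr, snap_ni;
  if (detail) {
    snap_budget = NumericMatrix(horizon, n);
    snap_z = NumericMatrix(horizon, n);
    snap_level = IntegerMatrix(horizon, n);
    snap_ns = IntegerMatrix(horizon, n);
    snap_nr = IntegerMatrix(horizon, n);
    snap_ni = IntegerMatrix(horizon, n);
  }

  std::vector<int> order(n);
  for (int t = 0; t < horizon; ++t) {
    // fresh uniformly random agent order, sequential updates
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = runif_int(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int i : order) e.step_agent(i);

    double sz = 0.0, sl = 0.0;
    for (int i = 0; i < n; ++i) { sz += e.zsum[i]; sl += e.level[i]; }
    zbar[t] = sz / n;
    lbar[t] = sl / n;
    tser[t] = e.total_traits;
    tcol[t] = t + 1;
    if (detail) {
      for (int i = 0; i < n; ++i) {
        snap_budget(t, i) = e.budget[i];
        snap_z(t, i) = e.zsum[i];
        snap_level(t, i) = e.level[i];
        snap_ns(t, i) = e.n_social[i];
        snap_nr(t, i) = e.n_rec[i];
        snap_ni(t, i) = e.n_innov[i];
      }
    }
  }

  DataFrame metrics = DataFrame::create(
      _["t"] = tcol, _["mean_payoff"] = zbar, _["mean_level"] = lbar,
      _["distinct_traits"] = tser);

  DataFrame agents = DataFrame::create(
      _["node"] = seq_len(n),
      _["budget"] = NumericVector(e.budget.begin(), e.budget.end()),
      _["max_level"] = IntegerVector(e.level.begin(), e.level.end()),
      _["cumulative_payoff"] = NumericVector(e.zsum.begin(), e.zsum.end()),
      _["n_social"] = IntegerVector(e.n_social.begin(), e.n_social.end()),
      _["n_rec"] = IntegerVector(e.n_rec.begin(), e.n_rec.end()),
      _["n_innov"] = IntegerVector(e.n_innov.begin(), e.n_innov.end()));

  List out = List::create(
      _["metrics"] = metrics, _["agents"] = agents,
      _["replacements"] = static_cast<double>(e.replacements),
      _["n_mediated"] = static_cast<double>(e.n_mediated),
      _["n_social_dispatch"] = static_cast<double>(e.n_social_dispatch),
      _["archive_count"] = e.total_traits);

  if (detail) {
    List reps(n);
    for (int i = 0; i < n; ++i) {
      int L = e.level[i];
      IntegerMatrix m(L, 2);
      for (int l = 0; l < L; ++l) {
        m(l, 0) = e.rep_branch[i][l];
        m(l, 1) = e.rep_payoff[i][l];
      }
      colnames(m) = CharacterVector::create("branch", "payoff");
      reps[i] = m;
    }
    int np = static_cast<int>(e.payoffs.size());
    IntegerVector pb(np), pl(np), pz(np);
    int idx = 0;
    for (const auto& kv : e.payoffs) {
      pb[idx] = static_cast<int>(kv.first >> 32);
      pl[idx] = static_cast<int>(kv.first & 0xffffffffLL);
      pz[idx] = kv.second;
      ++idx;
    }
    out["repertoires"] = reps;
    out["payoff_map"] = DataFrame::create(_["branch"] = pb, _["level"] = pl,
                                          _["payoff"] = pz);
    out["snapshots"] = List::create(
        _["budget"] = snap_budget, _["cumulative_payoff"] = snap_z,
        _["max_level"] = snap_level, _["n_social"] = snap_ns,
        _["n_rec"] = snap_nr, _["n_innov"] = snap_ni);
  }
  return out;
}
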