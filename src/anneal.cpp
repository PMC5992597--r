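// Simulated-annealing structure search core.  The BDeu family scores and
// the Metropolis/cooling/reannealing/restart loop live here; the R level
// owns validation, seeding (R's RNG is used throughout, so
// set.seed()/withr::with_seed() give bit-reproducible searches) and the
// independent scoring route used by the tests.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

namespace {

struct FamilyScorer {
  const IntegerMatrix& obs;  // samples x nodes, states 0..2
  int n_nodes;
  double ess;
  std::unordered_map<uint64_t, double> cache;

  FamilyScorer(const IntegerMatrix& obs_, double ess_)
    : obs(obs_), n_nodes(obs_.ncol()), ess(ess_) {}

  // parents given as bitmask over nodes (node ids < 57)
  double score(int v, uint64_t mask) {
    uint64_t key = (static_cast<uint64_t>(v) << 57) | mask;
    auto hit = cache.find(key);
    if (hit != cache.end()) return hit->second;

    std::vector<int> parents;
    for (int p = 0; p < n_nodes; ++p)
      if (mask & (1ULL << p)) parents.push_back(p);
    int k = static_cast<int>(parents.size());
    long q = 1;
    for (int i = 0; i < k; ++i) q *= 3;
    int n_samples = obs.nrow();
    std::vector<int> counts(static_cast<size_t>(q) * 3, 0);
    for (int s = 0; s < n_samples; ++s) {
      long cfg = 0, mult = 1;
      for (int i = 0; i < k; ++i) {
        cfg += obs(s, parents[i]) * mult;
        mult *= 3;
      }
      counts[cfg * 3 + obs(s, v)]++;
    }
    double a_jk = ess / (q * 3.0);
    double a_j = ess / q;
    double sc = 0.0;
    for (long j = 0; j < q; ++j) {
      int nj = counts[j * 3] + counts[j * 3 + 1] + counts[j * 3 + 2];
      sc += R::lgammafn(a_j) - R::lgammafn(a_j + nj);
      for (int st = 0; st < 3; ++st)
        sc += R::lgammafn(a_jk + counts[j * 3 + st]) - R::lgammafn(a_jk);
    }
    cache[key] = sc;
    return sc;
  }
};

// directed path from -> to in adjacency (row-major vector adj[u*n+v])
bool has_path_cpp(const std::vector<uint8_t>& adj, int n, int from, int to) {
  if (from == to) return true;
  std::vector<uint8_t> seen(n, 0);
  std::vector<int> stack{from};
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    if (u == to) return true;
    if (seen[u]) continue;
    seen[u] = 1;
    for (int w = 0; w < n; ++w)
      if (adj[u * n + w] && !seen[w]) stack.push_back(w);
  }
  return false;
}

struct Ensemble {
  int capacity;
  std::vector<std::string> keys;
  std::vector<double> scores;
  std::vector<std::vector<uint8_t>> adjs;

  explicit Ensemble(int cap) : capacity(cap) {}

  static std::string key_of(const std::vector<uint8_t>& adj) {
    return std::string(adj.begin(), adj.end());
  }

  void offer(const std::vector<uint8_t>& adj, double score) {
    std::string key = key_of(adj);
    for (size_t i = 0; i < keys.size(); ++i)
      if (keys[i] == key) return;
    if (static_cast<int>(keys.size()) >= capacity) {
      size_t worst = 0;
      for (size_t i = 1; i < scores.size(); ++i)
        if (scores[i] < scores[worst]) worst = i;
      if (score <= scores[worst]) return;
      keys.erase(keys.begin() + worst);
      scores.erase(scores.begin() + worst);
      adjs.erase(adjs.begin() + worst);
    }
    keys.push_back(key);
    scores.push_back(score);
    adjs.push_back(adj);
  }
};

}  // namespace

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(IntegerMatrix obs, List schedule, double ess,
                std::string collect) {
  const int n = obs.ncol();
  FamilyScorer scorer(obs, ess);

  const double t0 = schedule["t0"];
  const double cooling = schedule["cooling"];
  const double t_reanneal = schedule["t_reanneal"];
  const int max_accepted = schedule["max_accepted"];
  const int max_proposed = schedule["max_proposed"];
  const int min_accepted = schedule["min_accepted"];
  const int restarts = schedule["restarts"];
  const int maxp = schedule["max_parents"];
  const double budget = schedule["budget"];
  const int ensemble_size = schedule["ensemble_size"];
  const bool all_visited = (collect == "all_visited");

  Ensemble ens(ensemble_size);
  std::vector<uint64_t> parent_mask(n, 0);
  std::vector<int> indegree(n, 0);

  auto total_score = [&](const std::vector<uint8_t>& adj) {
    double s = 0.0;
    for (int v = 0; v < n; ++v) s += scorer.score(v, parent_mask[v]);
    (void)adj;
    return s;
  };

  double proposals_left = budget;
  for (int restart = 0; restart < restarts && proposals_left > 0; ++restart) {
    // random initial DAG: random topological order + Bernoulli(0.1) edges
    std::vector<uint8_t> adj(n * n, 0);
    std::fill(parent_mask.begin(), parent_mask.end(), 0ULL);
    std::fill(indegree.begin(), indegree.end(), 0);
    if (maxp > 0) {
      std::vector<int> ord(n);
      for (int i = 0; i < n; ++i) ord[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = static_cast<int>(R::unif_rand() * (i + 1));
        std::swap(ord[i], ord[j]);
      }
      for (int pos = 1; pos < n; ++pos) {
        int v = ord[pos];
        for (int k = 0; k < pos && indegree[v] < maxp; ++k) {
          int u = ord[k];
          if (R::unif_rand() < 0.1) {
            adj[u * n + v] = 1;
            parent_mask[v] |= (1ULL << u);
            indegree[v]++;
          }
        }
      }
    }
    double score = 0.0;
    for (int v = 0; v < n; ++v) score += scorer.score(v, parent_mask[v]);
    std::vector<uint8_t> best_adj = adj;
    double best_score = score;
    if (all_visited) ens.offer(adj, score);

    double temp = t0;
    int acc_cool = 0, prop_cool = 0, acc_reanneal = 0;
    double budget_this = std::min(proposals_left,
                                  std::ceil(budget / restarts));
    proposals_left -= budget_this;

    while (budget_this > 0) {
      budget_this -= 1;
      prop_cool += 1;
      int u = static_cast<int>(R::unif_rand() * n);
      int v = static_cast<int>(R::unif_rand() * (n - 1));
      if (v >= u) v += 1;
      double delta = NA_REAL;
      int move = -1;  // 0 delete, 1 reverse, 2 add
      if (adj[u * n + v]) {
        if (R::unif_rand() < 0.5) {  // delete u -> v
          delta = scorer.score(v, parent_mask[v] & ~(1ULL << u)) -
                  scorer.score(v, parent_mask[v]);
          move = 0;
        } else {  // reverse u -> v
          adj[u * n + v] = 0;
          bool ok = indegree[u] < maxp && !has_path_cpp(adj, n, u, v);
          adj[u * n + v] = 1;
          if (ok) {
            delta = (scorer.score(v, parent_mask[v] & ~(1ULL << u)) -
                     scorer.score(v, parent_mask[v])) +
                    (scorer.score(u, parent_mask[u] | (1ULL << v)) -
                     scorer.score(u, parent_mask[u]));
            move = 1;
          }
        }
      } else if (!adj[v * n + u]) {  // add u -> v
        if (indegree[v] < maxp && !has_path_cpp(adj, n, v, u)) {
          delta = scorer.score(v, parent_mask[v] | (1ULL << u)) -
                  scorer.score(v, parent_mask[v]);
          move = 2;
        }
      }
      if (move >= 0 && !ISNA(delta) &&
          (delta >= 0 || R::unif_rand() < std::exp(delta / temp))) {
        if (move == 0) {
          adj[u * n + v] = 0;
          parent_mask[v] &= ~(1ULL << u);
          indegree[v]--;
        } else if (move == 1) {
          adj[u * n + v] = 0;
          adj[v * n + u] = 1;
          parent_mask[v] &= ~(1ULL << u);
          parent_mask[u] |= (1ULL << v);
          indegree[v]--;
          indegree[u]++;
        } else {
          adj[u * n + v] = 1;
          parent_mask[v] |= (1ULL << u);
          indegree[v]++;
        }
        score += delta;
        acc_cool += 1;
        acc_reanneal += 1;
        if (all_visited) {
          ens.offer(adj, score);
        } else if (score > best_score) {
          best_score = score;
          best_adj = adj;
        }
      }
      if (acc_cool >= max_accepted || prop_cool >= max_proposed) {
        if (acc_reanneal < min_accepted) {
          temp = t_reanneal;
        } else {
          temp *= cooling;
        }
        acc_reanneal = 0;
        acc_cool = 0;
        prop_cool = 0;
      }
    }
    if (!all_visited) ens.offer(best_adj, best_score);
  }

  // sort by score descending
  std::vector<size_t> idx(ens.scores.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    return ens.scores[a] > ens.scores[b];
  });
  List networks(idx.size());
  for (size_t r = 0; r < idx.size(); ++r) {
    const std::vector<uint8_t>& a = ens.adjs[idx[r]];
    IntegerMatrix am(n, n);
    for (int u = 0; u < n; ++u)
      for (int v = 0; v < n; ++v) am(u, v) = a[u * n + v];
    networks[r] = List::create(Named("adjacency") = am,
                               Named("score") = ens.scores[idx[r]]);
  }
  return networks;
}
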