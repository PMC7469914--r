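// Compiled cores for the Trader optimizer, the generic baselines and the
// exhaustive oracle. All randomness flows through R's RNG (unif_rand), so
// set.seed() on the R side makes every engine deterministic. Coverage is
// encoded as bitmasks over the instance's main targets (<= 30 bits);
// adverse pairs as 0-based index pairs.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Instance {
  int m;                       // number of candidate drugs
  std::vector<unsigned> cov;   // coverage bitmask per candidate
  std::vector<double> se;      // side-effect count per candidate
  std::vector<std::vector<int>> adj;  // adverse adjacency lists
  bool hard;                   // hard DDAR mode vs additive penalty
  double lambda;               // penalty per violating pair
  double sentinel;             // finite infeasibility sentinel (hard mode)
};

inline int popcount(unsigned x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

Instance make_instance(const IntegerVector& cov, const NumericVector& se,
                       const IntegerMatrix& pairs, int n_main,
                       bool hard, double lambda) {
  Instance ins;
  ins.m = cov.size();
  ins.cov.assign(cov.begin(), cov.end());
  ins.se.assign(se.begin(), se.end());
  ins.adj.assign(ins.m, {});
  for (int k = 0; k < pairs.nrow(); ++k) {
    int a = pairs(k, 0), b = pairs(k, 1);
    ins.adj[a].push_back(b);
    ins.adj[b].push_back(a);
  }
  ins.hard = hard;
  ins.lambda = lambda;
  double tot = 0; for (double s : ins.se) tot += s;
  ins.sentinel = -(tot + n_main + 1.0);
  return ins;
}

// score of a 0/1 solution; x must contain at least one 1
double score_x(const Instance& ins, const std::vector<int>& x) {
  unsigned mask = 0; double sesum = 0; int k = 0, viol = 0;
  for (int i = 0; i < ins.m; ++i) {
    if (x[i]) {
      mask |= ins.cov[i];
      sesum += ins.se[i];
      ++k;
      for (int j : ins.adj[i]) if (j > i && x[j]) ++viol;
    }
  }
  double base = popcount(mask) - sesum / k;
  if (viol == 0) return base;
  return ins.hard ? ins.sentinel : base - ins.lambda * viol;
}

inline int runif_int(int n) {  // uniform on 0..n-1
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

void repair_zero(std::vector<int>& x) {
  for (int v : x) if (v) return;
  x[runif_int((int)x.size())] = 1;
}

// sample r distinct positions from 0..m-1 (partial Fisher-Yates)
void sample_positions(int m, int r, std::vector<int>& pool,
                      std::vector<int>& out) {
  for (int i = 0; i < m; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < r; ++i) {
    int j = i + runif_int(m - i);
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

struct BestTracker {
  std::vector<int> vec;
  double score;
  bool feasible_seen = false;
  void consider(const std::vector<int>& x, double s, double sentinel) {
    if (vec.empty() || s > score) { vec = x; score = s; }
    if (s > sentinel) feasible_seen = true;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_trader(IntegerVector cov, NumericVector se, IntegerMatrix pairs,
                int n_main, int C, int T, int M, int max_eval,
                double retail_frac, bool hard, double lambda,
                bool record_groups) {
  Instance ins = make_instance(cov, se, pairs, n_main, hard, lambda);
  const int m = ins.m;

  std::vector<std::vector<int>> pop(C, std::vector<int>(m));
  std::vector<double> scores(C);
  std::vector<int> group(C);
  long long evals = 0;

  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < m; ++i) pop[c][i] = unif_rand() < 0.5 ? 1 : 0;
    repair_zero(pop[c]);
    group[c] = c % T;
    scores[c] = score_x(ins, pop[c]);
    ++evals;
  }

  BestTracker best;
  for (int c = 0; c < C; ++c) best.consider(pop[c], scores[c], ins.sentinel);

  std::vector<double> trace;
  trace.push_back(-best.score);
  std::vector<int> pool(m), pos;
  std::vector<int> sizes_hist;

  int rmax = (int)std::ceil(m * retail_frac);
  if (rmax < 1) rmax = 1;

  std::vector<int> master(T);
  std::vector<double> prop(T);

  while (evals < max_eval) {
    // masters: best score per group, lowest index on ties
    std::fill(master.begin(), master.end(), -1);
    for (int c = 0; c < C; ++c) {
      int g = group[c];
      if (master[g] < 0 || scores[c] > scores[master[g]]) master[g] = c;
    }

    // distributing: master -> each slave of its group
    for (int c = 0; c < C; ++c) {
      int g = group[c];
      if (c == master[g]) continue;
      int r = 1 + runif_int(m);
      sample_positions(m, r, pool, pos);
      std::vector<int> trial = pop[c];
      for (int p : pos) trial[p] = pop[master[g]][p];
      repair_zero(trial);
      double s = score_x(ins, trial);
      ++evals;
      if (s > scores[c]) { pop[c] = trial; scores[c] = s; }
      best.consider(pop[c], scores[c], ins.sentinel);
    }

    // retailing: small random flips on each slave
    for (int c = 0; c < C; ++c) {
      if (c == master[group[c]]) continue;
      int r = 1 + runif_int(rmax);
      sample_positions(m, r, pool, pos);
      std::vector<int> trial = pop[c];
      for (int p : pos) trial[p] = 1 - trial[p];
      repair_zero(trial);
      double s = score_x(ins, trial);
      ++evals;
      if (s > scores[c]) { pop[c] = trial; scores[c] = s; }
      best.consider(pop[c], scores[c], ins.sentinel);
    }

    // group properties = sum of member scores
    std::fill(prop.begin(), prop.end(), 0.0);
    for (int c = 0; c < C; ++c) prop[group[c]] += scores[c];

    // one importing-exporting event: importer uniform among masters,
    // exporter drawn from the rest with probability ~ shifted property
    {
      int gi = runif_int(T);
      double mn = R_PosInf;
      for (int g = 0; g < T; ++g) if (g != gi && prop[g] < mn) mn = prop[g];
      double tot = 0;
      std::vector<double> w(T, 0.0);
      for (int g = 0; g < T; ++g) if (g != gi) {
        w[g] = prop[g] - mn + 1.0;
        tot += w[g];
      }
      double u = unif_rand() * tot, acc = 0;
      int ge = -1;
      for (int g = 0; g < T; ++g) if (g != gi) {
        acc += w[g];
        if (u <= acc) { ge = g; break; }
      }
      if (ge < 0) for (int g = T - 1; g >= 0; --g) if (g != gi) { ge = g; break; }

      int imp = master[gi], exp = master[ge];
      int r = 1 + runif_int(m);
      sample_positions(m, r, pool, pos);
      std::vector<int> trial = pop[imp];
      for (int p : pos) trial[p] = pop[exp][p];
      repair_zero(trial);
      double s = score_x(ins, trial);
      ++evals;
      if (s > scores[imp]) { pop[imp] = trial; scores[imp] = s; }
      best.consider(pop[imp], scores[imp], ins.sentinel);
    }

    // regrouping (proportional quotas, largest remainder); masters stay
    {
      std::fill(prop.begin(), prop.end(), 0.0);
      for (int c = 0; c < C; ++c) prop[group[c]] += scores[c];
      int poolsize = C - M * T;
      std::vector<int> quota(T, M);
      if (poolsize > 0) {
        double mn = *std::min_element(prop.begin(), prop.end());
        std::vector<double> p(T);
        double tot = 0;
        for (int g = 0; g < T; ++g) {
          p[g] = mn <= 0 ? prop[g] - mn + 1.0 : prop[g];
          tot += p[g];
        }
        std::vector<double> raw(T);
        std::vector<int> base(T);
        int used = 0;
        for (int g = 0; g < T; ++g) {
          raw[g] = p[g] / tot * poolsize;
          base[g] = (int)std::floor(raw[g]);
          used += base[g];
        }
        int rem = poolsize - used;
        std::vector<int> ord(T);
        for (int g = 0; g < T; ++g) ord[g] = g;
        std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
          return raw[a] - base[a] > raw[b] - base[b];
        });
        for (int i = 0; i < rem; ++i) base[ord[i]] += 1;
        for (int g = 0; g < T; ++g) quota[g] += base[g];
      }

      // migrate worst-first from over-quota to under-quota groups
      std::vector<int> size(T, 0);
      for (int c = 0; c < C; ++c) size[group[c]]++;
      bool moved = true;
      while (moved) {
        moved = false;
        int donor = -1;
        for (int g = 0; g < T; ++g) if (size[g] > quota[g]) { donor = g; break; }
        if (donor < 0) break;
        // worst non-master member of donor
        int worst = -1;
        for (int c = 0; c < C; ++c) {
          if (group[c] != donor || c == master[donor]) continue;
          if (worst < 0 || scores[c] < scores[worst]) worst = c;
        }
        // recipient with largest deficit (lowest index on ties)
        int recip = -1, deficit = 0;
        for (int g = 0; g < T; ++g) {
          int d = quota[g] - size[g];
          if (d > deficit) { deficit = d; recip = g; }
        }
        if (worst < 0 || recip < 0) break;
        group[worst] = recip;
        size[donor]--; size[recip]++;
        moved = true;
      }
      if (record_groups) {
        for (int g = 0; g < T; ++g) sizes_hist.push_back(size[g]);
      }
    }

    trace.push_back(-best.score);
  }

  IntegerVector bestv(best.vec.begin(), best.vec.end());
  List out = List::create(
    _["best"] = bestv,
    _["best_score"] = best.score,
    _["objective"] = -best.score,
    _["feasible"] = best.score > ins.sentinel,
    _["evaluations"] = (double)evals,
    _["trace"] = NumericVector(trace.begin(), trace.end()));
  if (record_groups) {
    IntegerMatrix gs((int)sizes_hist.size() / T, T);
    for (int i = 0, k = 0; i < gs.nrow(); ++i)
      for (int g = 0; g < T; ++g) gs(i, g) = sizes_hist[k++];
    out["group_sizes"] = gs;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_random_search(IntegerVector cov, NumericVector se,
                       IntegerMatrix pairs, int n_main, int budget,
                       bool hard, double lambda, int trace_every) {
  Instance ins = make_instance(cov, se, pairs, n_main, hard, lambda);
  const int m = ins.m;
  BestTracker best;
  std::vector<double> trace;
  std::vector<int> x(m);
  for (int e = 1; e <= budget; ++e) {
    for (int i = 0; i < m; ++i) x[i] = unif_rand() < 0.5 ? 1 : 0;
    repair_zero(x);
    best.consider(x, score_x(ins, x), ins.sentinel);
    if (e % trace_every == 0 || e == budget) trace.push_back(-best.score);
  }
  IntegerVector bestv(best.vec.begin(), best.vec.end());
  return List::create(
    _["best"] = bestv, _["best_score"] = best.score,
    _["objective"] = -best.score,
    _["feasible"] = best.score > ins.sentinel,
    _["evaluations"] = (double)budget,
    _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export]]
List cpp_hill_climb(IntegerVector cov, NumericVector se, IntegerMatrix pairs,
                    int n_main, int budget, bool hard, double lambda,
                    int trace_every) {
  Instance ins = make_instance(cov, se, pairs, n_main, hard, lambda);
  const int m = ins.m;
  BestTracker best;
  std::vector<double> trace;
  std::vector<int> x(m), order(m), pool(m);
  long long evals = 0;
  auto log_trace = [&]() {
    if (evals % trace_every == 0 || evals == budget)
      trace.push_back(-best.score);
  };

  while (evals < budget) {
    for (int i = 0; i < m; ++i) x[i] = unif_rand() < 0.5 ? 1 : 0;
    repair_zero(x);
    double sc = score_x(ins, x);
    ++evals;
    best.consider(x, sc, ins.sentinel);
    log_trace();
    bool improved = true;
    while (improved && evals < budget) {
      improved = false;
      sample_positions(m, m, pool, order);  // random scan order
      for (int idx = 0; idx < m && evals < budget; ++idx) {
        int p = order[idx];
        x[p] = 1 - x[p];
        bool zero = true;
        for (int v : x) if (v) { zero = false; break; }
        if (zero) { x[p] = 1 - x[p]; continue; }  // skip empty neighbor
        double s = score_x(ins, x);
        ++evals;
        if (s > sc) {
          sc = s;
          improved = true;
          best.consider(x, sc, ins.sentinel);
          log_trace();
          break;  // first improvement: rescan from a fresh random order
        }
        x[p] = 1 - x[p];
        log_trace();
      }
    }
  }
  IntegerVector bestv(best.vec.begin(), best.vec.end());
  return List::create(
    _["best"] = bestv, _["best_score"] = best.score,
    _["objective"] = -best.score,
    _["feasible"] = best.score > ins.sentinel,
    _["evaluations"] = (double)evals,
    _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export]]
List cpp_oracle(IntegerVector cov, NumericVector se, IntegerMatrix pairs,
                int n_main, bool hard, double lambda) {
  Instance ins = make_instance(cov, se, pairs, n_main, hard, lambda);
  const int m = ins.m;
  if (m > 20) stop("exhaustive oracle supports at most 20 candidates");
  const unsigned N = 1u << m;

  // adverse pair masks for fast feasibility
  std::vector<unsigned> pairmask;
  for (int k = 0; k < pairs.nrow(); ++k)
    pairmask.push_back((1u << pairs(k, 0)) | (1u << pairs(k, 1)));

  double best = R_NegInf;
  unsigned best_mask = 0;
  long long feasible = 0;
  for (unsigned msk = 1; msk < N; ++msk) {
    int viol = 0;
    for (unsigned pm : pairmask) if ((msk & pm) == pm) ++viol;
    if (ins.hard && viol > 0) continue;
    unsigned covm = 0; double sesum = 0; int k = 0;
    for (int i = 0; i < m; ++i) if (msk & (1u << i)) {
      covm |= ins.cov[i];
      sesum += ins.se[i];
      ++k;
    }
    double s = popcount(covm) - sesum / k - (ins.hard ? 0.0 : ins.lambda * viol);
    ++feasible;
    if (s > best) { best = s; best_mask = msk; }
  }
  IntegerVector sel(m);
  for (int i = 0; i < m; ++i) sel[i] = (best_mask >> i) & 1u;
  return List::create(
    _["optimal_selection"] = sel,
    _["optimal_score"] = best,
    _["optimal_objective"] = -best,
    _["enumerated"] = (double)feasible);
}
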