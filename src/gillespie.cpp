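#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Continuous-time multi-type birth-death-mutation simulator.
//
// Cells are stored per clone as a flat vector of integer labels, where a
// cell's label is the id of its most recent passenger mutation (0 = none).
// Every event picks a uniformly random cell, so each step is O(1); the law
// is exactly that of the per-cell Gillespie algorithm. The global ancestor
// vector anc maps each mutation id to the label the mutated cell carried
// beforehand, so anc[i] < i always and carrier sets are subtree sums.
//
// Clones are independent branching processes and are simulated sequentially
// in order of origin time. While simulating clone j, the origin of each
// child clone and the two observation checkpoints are pending actions,
// applied at the first event time that crosses them (state recorded
// immediately before that event). Founding a child removes one uniformly
// chosen cell from the parent and records the number of passengers in that
// founder cell.
//
// Conditioning on survival: extinction of clone 0 while founding events or
// (when there are no drivers) checkpoints remain pending restarts the whole
// run; extinction of clone j >= 1 restarts clone j from its single founder
// cell at its origin time. All restarts consume the same RNG stream.

namespace {

struct Pending {
  double time;
  int type;   // 0 = found child, 1 = checkpoint 1, 2 = checkpoint 2
  int child;  // child clone index for type 0
};

int chain_length(const std::vector<int>& anc, int label) {
  int n = 0;
  while (label > 0) {
    label = anc[label];
    ++n;
  }
  return n;
}

}  // namespace

// [[Rcpp::export(name = ".sim_gillespie_cpp")]]
List sim_gillespie_cpp(IntegerVector parent, NumericVector b, NumericVector d,
                       NumericVector t_origin, double u, double t_obs1,
                       double t_obs2, double max_events) {
  const int K = parent.size();  // number of clones (k + 1)
  for (int j = 0; j < K; ++j) {
    if (!R_finite(b[j]) || !R_finite(d[j]) || b[j] < 0 || d[j] < 0)
      stop("non-finite or negative birth/death rate");
  }
  if (!(u >= 0) || !R_finite(u)) stop("invalid mutation rate");

  // simulation order: by origin time, parents before children
  std::vector<int> order(K);
  for (int j = 0; j < K; ++j) order[j] = j;
  std::stable_sort(order.begin(), order.end(), [&](int a, int c) {
    return t_origin[a] < t_origin[c];
  });

  std::vector<int> anc(1, 0);  // anc[0] unused
  std::vector<int> founder_label(K, 0), founder_chain(K, 0), m_true(K, 0);
  std::vector<int> restart_clone(K, 0);
  int restart_whole = 0;
  double events = 0.0;
  long interrupt_tick = 0;
  std::vector<std::vector<int>> snap1(K), snap2(K);
  std::vector<int> labels;

  bool done = false;
  while (!done) {
    anc.assign(1, 0);
    std::fill(founder_label.begin(), founder_label.end(), 0);
    std::fill(founder_chain.begin(), founder_chain.end(), 0);
    std::fill(m_true.begin(), m_true.end(), 0);
    for (int j = 0; j < K; ++j) {
      snap1[j].clear();
      snap2[j].clear();
    }
    bool failed = false;

    for (int oj = 0; oj < K && !failed; ++oj) {
      const int j = order[oj];
      const double bj = b[j], dj = d[j];
      const double per_cell = bj + dj + u;

      std::vector<Pending> pend;
      for (int c = 0; c < K; ++c)
        if (parent[c] == j) pend.push_back({t_origin[c], 0, c});
      pend.push_back({t_obs1, 1, -1});
      pend.push_back({t_obs2, 2, -1});
      std::stable_sort(pend.begin(), pend.end(),
                       [](const Pending& a, const Pending& c) {
                         return a.time < c.time;
                       });

      labels.assign(1, founder_label[j]);
      double t = t_origin[j];
      size_t pi = 0;

      while (true) {
        if (labels.empty()) {
          bool founding_left = false;
          for (size_t q = pi; q < pend.size(); ++q)
            if (pend[q].type == 0) founding_left = true;
          if (j == 0 && (founding_left || K == 1)) {
            failed = true;  // whole-run restart
            break;
          }
          if (j == 0) {
            // allowed to die once all children are founded; remaining
            // checkpoints record an empty clone
            break;
          }
          ++restart_clone[j];
          labels.assign(1, founder_label[j]);
          t = t_origin[j];
          pi = 0;
          snap1[j].clear();
          snap2[j].clear();
          continue;
        }
        if (pi >= pend.size()) break;

        const double N = static_cast<double>(labels.size());
        const double tnext = t + exp_rand() / (N * per_cell);

        bool crossed_last = false;
        while (pi < pend.size() && pend[pi].time <= tnext) {
          const Pending& p = pend[pi];
          if (p.type == 1) {
            snap1[j] = labels;
          } else if (p.type == 2) {
            snap2[j] = labels;
            crossed_last = true;
          } else {
            const int c = p.child;
            int idx = static_cast<int>(unif_rand() * labels.size());
            if (idx >= static_cast<int>(labels.size()))
              idx = static_cast<int>(labels.size()) - 1;
            founder_label[c] = labels[idx];
            founder_chain[c] = chain_length(anc, labels[idx]);
            m_true[c] = founder_chain[c] - founder_chain[j];
            labels[idx] = labels.back();
            labels.pop_back();
          }
          ++pi;
        }
        if (crossed_last) break;
        t = tnext;
        if (labels.empty()) continue;

        // execute the event at tnext
        int idx = static_cast<int>(unif_rand() * labels.size());
        if (idx >= static_cast<int>(labels.size()))
          idx = static_cast<int>(labels.size()) - 1;
        const double y = unif_rand() * per_cell;
        if (y < bj) {
          labels.push_back(labels[idx]);
        } else if (y < bj + dj) {
          labels[idx] = labels.back();
          labels.pop_back();
        } else {
          anc.push_back(labels[idx]);
          labels[idx] = static_cast<int>(anc.size()) - 1;
        }
        events += 1.0;
        if (events > max_events)
          stop("event budget exceeded (%.0f events); raise max_events or "
               "shorten the schedule",
               events);
        if ((++interrupt_tick & 0xFFFFF) == 0) checkUserInterrupt();
      }
    }

    if (failed) {
      ++restart_whole;
      continue;
    }
    // keep the run only if the tumor is extant at the end of the schedule
    double total2 = 0.0;
    for (int j = 0; j < K; ++j) total2 += snap2[j].size();
    if (total2 == 0.0) {
      ++restart_whole;
      continue;
    }
    done = true;
  }

  List s1(K), s2(K);
  for (int j = 0; j < K; ++j) {
    s1[j] = IntegerVector(snap1[j].begin(), snap1[j].end());
    s2[j] = IntegerVector(snap2[j].begin(), snap2[j].end());
  }
  IntegerVector anc_out(anc.begin() + 1, anc.end());
  return List::create(
      _["snapshot1"] = s1, _["snapshot2"] = s2, _["ancestor"] = anc_out,
      _["founder_label"] = IntegerVector(founder_label.begin(), founder_label.end()),
      _["m_true"] = IntegerVector(m_true.begin(), m_true.end()),
      _["restart_whole"] = restart_whole,
      _["restart_clone"] = IntegerVector(restart_clone.begin(), restart_clone.end()),
      _["n_events"] = events);
}

// Carrier counts per clone for every mutation with at least one extant
// carrier. labels_list holds, per clone, the per-cell label vector of one
// checkpoint. A cell carries mutation n iff n lies on the ancestor chain of
// its label, so counts are accumulated bottom-up (anc[id] < id).
// [[Rcpp::export(name = ".tally_carriers_cpp")]]
List tally_carriers_cpp(IntegerVector ancestor, List labels_list) {
  const int P = ancestor.size();
  const int K = labels_list.size();
  for (int i = 0; i < P; ++i) {
    if (ancestor[i] < 0 || ancestor[i] > i)
      stop("invalid ancestor vector: ancestor of mutation %d is %d", i + 1,
           (int)ancestor[i]);
  }
  std::vector<std::vector<double>> cnt(K, std::vector<double>(P + 1, 0.0));
  for (int c = 0; c < K; ++c) {
    IntegerVector lab = labels_list[c];
    for (int i = 0; i < lab.size(); ++i) {
      const int l = lab[i];
      if (l < 0 || l > P) stop("label %d outside mutation id range", l);
      cnt[c][l] += 1.0;
    }
  }
  for (int id = P; id >= 1; --id) {
    const int a = ancestor[id - 1];
    for (int c = 0; c < K; ++c)
      if (cnt[c][id] > 0) cnt[c][a] += cnt[c][id];
  }
  std::vector<int> keep;
  keep.reserve(P / 4 + 1);
  for (int id = 1; id <= P; ++id) {
    double tot = 0.0;
    for (int c = 0; c < K; ++c) tot += cnt[c][id];
    if (tot > 0) keep.push_back(id);
  }
  const int n = keep.size();
  IntegerVector ids(n), anc_out(n);
  IntegerMatrix counts(n, K);
  for (int i = 0; i < n; ++i) {
    ids[i] = keep[i];
    anc_out[i] = ancestor[keep[i] - 1];
    for (int c = 0; c < K; ++c)
      counts(i, c) = static_cast<int>(cnt[c][keep[i]]);
  }
  return List::create(_["id"] = ids, _["ancestor"] = anc_out,
                      _["carriers"] = counts);
}

// First time a single-type birth-death process started from one cell
// reaches target_n cells, conditioned on survival (extinct runs restart and
// consume the same RNG stream).
// [[Rcpp::export(name = ".first_passage_cpp")]]
double first_passage_cpp(double b, double d, int target_n) {
  if (b <= 0 || d < 0 || target_n < 1) stop("invalid first-passage setup");
  while (true) {
    double t = 0.0;
    long n = 1;
    while (n > 0 && n < target_n) {
      t += exp_rand() / (n * (b + d));
      if (unif_rand() * (b + d) < b)
        ++n;
      else
        --n;
    }
    if (n >= target_n) return t;
  }
}
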