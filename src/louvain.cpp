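#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Greedy Louvain for a generic (signed) modularity matrix B:
// maximize Q = sum_{u != v, sigma_u == sigma_v} B(u, v).
// Diagonal entries carry self-loops created by aggregation; they never
// enter move gains (a node's self-loop follows it into any community).

namespace {

// Fisher-Yates shuffle driven by R's RNG so set.seed() controls sweeps.
void shuffle_order(std::vector<int>& ord) {
  const int n = static_cast<int>(ord.size());
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// One greedy level: move nodes between communities until no move improves Q
// by more than tol. labels in/out are 0-based. Returns true if any move made.
bool greedy_level(const NumericMatrix& B, std::vector<int>& labels,
                  const double tol, const bool rand_moves) {
  const int n = B.nrow();
  std::vector<int> size(n, 0);
  for (int i = 0; i < n; ++i) size[labels[i]]++;
  std::vector<double> w(n);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  bool any_move = false, improved = true;
  int guard = 0;
  while (improved && ++guard <= 1000) {
    improved = false;
    shuffle_order(ord);
    for (int oi = 0; oi < n; ++oi) {
      const int i = ord[oi];
      const int cur = labels[i];
      std::fill(w.begin(), w.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        w[labels[j]] += B(i, j);
      }
      // candidate gains are 2 * w[c] (symmetric matrix, both ordered pairs);
      // an empty community has gain 0; ties broken by lowest community id.
      size[cur]--;
      int best = -1;          // -1 encodes "fresh empty community"
      double best_gain = 0.0; // gain of isolating i
      const double base = 2.0 * w[cur]; // gain of staying put
      if (rand_moves) {
        // uniform choice among strictly improving moves (incl. isolation)
        std::vector<int> cand;
        for (int c = 0; c < n; ++c) {
          if (size[c] == 0 || c == cur) continue;
          if (2.0 * w[c] - base > tol) cand.push_back(c);
        }
        if (0.0 - base > tol) cand.push_back(-1);
        if (!cand.empty()) {
          int pick = cand[static_cast<int>(unif_rand() * cand.size()) %
                          static_cast<int>(cand.size())];
          best = pick;
        } else {
          best = cur;
        }
      } else {
        // ascending scan + strict improvement = lowest-id tie-break
        for (int c = 0; c < n; ++c) {
          if (size[c] == 0) continue;
          const double g = 2.0 * w[c];
          if (g > best_gain + 1e-15) {
            best_gain = g;
            best = c;
          }
        }
        const double delta = best_gain - base;
        if (delta <= tol) best = cur;
      }
      if (best == -1) {
        // lowest-id empty community for isolation
        for (int c = 0; c < n; ++c) {
          if (size[c] == 0) { best = c; break; }
        }
      }
      if (best != cur) {
        labels[i] = best;
        size[best]++;
        improved = true;
        any_move = true;
      } else {
        labels[i] = cur;
        size[cur]++;
      }
    }
  }
  return any_move;
}

// Relabel to contiguous 0..K-1 in order of first appearance.
int canonicalize(std::vector<int>& labels) {
  std::vector<int> map(labels.size(), -1);
  int next = 0;
  for (size_t i = 0; i < labels.size(); ++i) {
    if (map[labels[i]] < 0) map[labels[i]] = next++;
    labels[i] = map[labels[i]];
  }
  return next;
}

} // namespace

// [[Rcpp::export]]
double evaluate_q_cpp(const NumericMatrix& B, const IntegerVector& labels1) {
  const int n = B.nrow();
  if (labels1.size() != n) stop("labels length does not match matrix size");
  double q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && labels1[i] == labels1[j]) q += B(i, j);
  return q;
}

namespace {

double q_of(const NumericMatrix& B, const std::vector<int>& labels) {
  const int n = B.nrow();
  double q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && labels[i] == labels[j]) q += B(i, j);
  return q;
}

NumericMatrix aggregate(const NumericMatrix& B, const std::vector<int>& lab,
                        const int k) {
  const int n = B.nrow();
  NumericMatrix B2(k, k);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      B2(lab[i], lab[j]) += B(i, j); // diagonal keeps self-loops
  return B2;
}

} // namespace

// [[Rcpp::export]]
List louvain_cpp(const NumericMatrix& B0, const double tol,
                 const bool rand_moves = true,
                 const IntegerVector& init = IntegerVector(),
                 const IntegerVector& groups = IntegerVector()) {
  const int n0 = B0.nrow();
  if (B0.ncol() != n0) stop("modularity matrix must be square");

  std::vector<int> assign(n0);
  if (init.size() == n0) {
    for (int i = 0; i < n0; ++i) assign[i] = init[i] - 1;
    canonicalize(assign);
  } else {
    for (int i = 0; i < n0; ++i) assign[i] = i;
  }
  double best_q = q_of(B0, assign);
  const bool has_groups = groups.size() == n0;
  int n_groups = 0;
  if (has_groups) {
    for (int i = 0; i < n0; ++i)
      n_groups = std::max(n_groups, static_cast<int>(groups[i]) + 1);
  }

  // iterated Louvain: refine at the original scale, then aggregate, until
  // a full cycle no longer improves Q
  for (int outer = 0; outer < 25; ++outer) {
    std::vector<int> labels(assign);
    greedy_level(B0, labels, tol, rand_moves);
    const int k0 = canonicalize(labels);
    assign = labels;
    NumericMatrix B = aggregate(B0, labels, k0);
    while (B.nrow() > 1) {
      const int n = B.nrow();
      std::vector<int> lab2(n);
      for (int i = 0; i < n; ++i) lab2[i] = i;
      const bool moved = greedy_level(B, lab2, tol, rand_moves);
      if (!moved) break;
      const int k = canonicalize(lab2);
      for (int i = 0; i < n0; ++i) assign[i] = lab2[assign[i]];
      if (k == n || k == 1) break;
      B = aggregate(B, lab2, k);
    }

    if (has_groups) {
      // chunk refinement: super-nodes are (community x group) chunks, so a
      // single layer's share of a community can switch multilayer
      // communities (plain aggregation moves whole communities only and
      // cannot repair a bad cross-layer matching)
      int kc = 0;
      std::vector<int> chunk(n0);
      {
        std::vector<int> map(static_cast<size_t>(n0) * n_groups, -1);
        for (int i = 0; i < n0; ++i) {
          const size_t key = static_cast<size_t>(assign[i]) * n_groups +
            groups[i];
          if (map[key] < 0) map[key] = kc++;
          chunk[i] = map[key];
        }
      }
      if (kc > 1 && kc < n0) {
        NumericMatrix Bc = aggregate(B0, chunk, kc);
        std::vector<int> clab(kc);
        for (int i = 0; i < n0; ++i) clab[chunk[i]] = assign[i];
        greedy_level(Bc, clab, tol, false); // deterministic cleanup
        for (int i = 0; i < n0; ++i) assign[i] = clab[chunk[i]];
        canonicalize(assign);
      }
    }

    const double q = q_of(B0, assign);
    if (q <= best_q + tol) break;
    best_q = q;
  }

  std::vector<int> final_labels(assign);
  canonicalize(final_labels);
  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = final_labels[i] + 1;
  return List::create(_["labels"] = out,
                      _["q"] = evaluate_q_cpp(B0, out));
}

// Exhaustive maximum of Q over all partitions of n items into at most max_k
// blocks (restricted-growth enumeration with incremental gains).
// [[Rcpp::export]]
List brute_force_max_q_cpp(const NumericMatrix& B, const int max_k) {
  const int n = B.nrow();
  if (n > 16) stop("exhaustive search limited to n <= 16");
  std::vector<int> a(n, 0), best_a(n, 0);
  std::vector<double> gain(n, 0.0); // Q contribution of item i at its level
  double best_q = -std::numeric_limits<double>::infinity();

  // iterative restricted-growth enumeration
  std::vector<int> maxb(n, 0); // max block id used among items < i
  int i = 1;
  a[0] = 0; maxb[0] = 0;
  double q = 0.0;
  std::vector<int> choice(n, -1);
  choice[0] = 0;
  if (n == 1) {
    best_q = 0.0;
  } else {
    while (i >= 1) {
      if (i == n) {
        if (q > best_q) { best_q = q; best_a = a; }
        --i;
        q -= gain[i];
        continue;
      }
      const int limit = std::min(maxb[i - 1] + 1, max_k - 1);
      int next = choice[i] + 1;
      if (next > limit) {
        choice[i] = -1;
        --i;
        if (i >= 1) q -= gain[i];
        continue;
      }
      choice[i] = next;
      a[i] = next;
      maxb[i] = std::max(maxb[i - 1], next);
      double g = 0.0;
      for (int j = 0; j < i; ++j)
        if (a[j] == next) g += B(i, j) + B(j, i);
      gain[i] = g;
      q += g;
      ++i;
      if (i < n) choice[i] = -1;
    }
  }
  IntegerVector lab(n);
  for (int j = 0; j < n; ++j) lab[j] = best_a[j] + 1;
  return List::create(_["q"] = best_q, _["labels"] = lab);
}

// Co-assignment frequency over partitions: labels is units x partitions.
// [[Rcpp::export]]
NumericMatrix agreement_cpp(const IntegerMatrix& labels) {
  const int n = labels.nrow(), p = labels.ncol();
  NumericMatrix A(n, n);
  for (int c = 0; c < p; ++c)
    for (int i = 0; i < n; ++i)
      for (int j = i; j < n; ++j)
        if (labels(i, c) == labels(j, c)) { A(i, j) += 1.0; A(j, i) += (i == j ? 0.0 : 1.0); }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) A(i, j) /= p;
  for (int i = 0; i < n; ++i) A(i, i) = 1.0;
  return A;
}

// Layer-switch permutation null. labels_list: per-partition node x layer
// integer matrices. obs: observed L x L proportion matrix (averaged across
// partitions). Returns counts of null proportions >= observed per layer pair.
// [[Rcpp::export]]
IntegerMatrix layer_switch_null_cpp(const List& labels_list,
                                    const NumericMatrix& obs,
                                    const int n_perm) {
  const int P = labels_list.size();
  IntegerMatrix first = labels_list[0];
  const int n = first.nrow(), L = first.ncol();
  IntegerMatrix counts(L, L);
  std::vector<int> row(L);
  NumericMatrix prop(L, L);
  for (int t = 0; t < n_perm; ++t) {
    std::fill(prop.begin(), prop.end(), 0.0);
    for (int p = 0; p < P; ++p) {
      IntegerMatrix lab = labels_list[p];
      for (int i = 0; i < n; ++i) {
        for (int r = 0; r < L; ++r) row[r] = lab(i, r);
        shuffle_order(row);
        for (int r = 0; r < L; ++r)
          for (int s = r + 1; s < L; ++s)
            if (row[r] != row[s]) prop(r, s) += 1.0;
      }
    }
    const double denom = static_cast<double>(n) * P;
    for (int r = 0; r < L; ++r)
      for (int s = r + 1; s < L; ++s)
        if (prop(r, s) / denom >= obs(r, s) - 1e-12) {
          counts(r, s)++;
          counts(s, r)++;
        }
  }
  return counts;
}
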