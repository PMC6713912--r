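#include <Rcpp.h>
using namespace Rcpp;

// Maximum base-pairing dynamic program (Nussinov-style) with deterministic
// traceback. Bases are passed as integers 0..3 (A,C,G,U); `pairable` is the
// 4x4 admissible-pair matrix; `min_loop` is the minimum number of unpaired
// bases enclosed by any pair.
//
// Recurrence over [i, j]:
//   N(i, j) = max( N(i, j-1),
//                  max_{k : pairable(k, j), j-k > min_loop}
//                      N(i, k-1) + N(k+1, j-1) + 1 )
// Traceback ties resolve in favour of leaving j unpaired, then pairing j
// with the smallest admissible k (the split point is implicit at k).

// [[Rcpp::export]]
List nussinov_fold(IntegerVector bases, int min_loop, LogicalMatrix pairable) {
  int n = bases.size();
  std::string structure(n, '.');
  if (n < min_loop + 2) {
    return List::create(_["structure"] = structure, _["pairs"] = 0);
  }

  // N stored as a flat n x n matrix, N[i + n*j] for i <= j.
  std::vector<int> N((size_t)n * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[i + (size_t)n * (j - 1)];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!pairable(bases[k], bases[j])) continue;
        int val = 1;
        if (k > i) val += N[i + (size_t)n * (k - 1)];
        if (k + 1 <= j - 1) val += N[(k + 1) + (size_t)n * (j - 1)];
        if (val > best) best = val;
      }
      N[i + (size_t)n * j] = best;
    }
  }

  // Iterative traceback over an explicit interval stack.
  int pairs = 0;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int target = N[i + (size_t)n * j];
    if (target == N[i + (size_t)n * (j - 1)]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!pairable(bases[k], bases[j])) continue;
      int val = 1;
      if (k > i) val += N[i + (size_t)n * (k - 1)];
      if (k + 1 <= j - 1) val += N[(k + 1) + (size_t)n * (j - 1)];
      if (val == target) {
        structure[k] = '(';
        structure[j] = ')';
        ++pairs;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }

  return List::create(_["structure"] = structure, _["pairs"] = pairs);
}
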