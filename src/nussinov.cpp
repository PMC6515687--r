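#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Canonical RNA pairs (AU, GC, GU and reverses); T treated as U, anything
// else (N, gaps) unpairable.
static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'U' || b == 'T';
  case 'U': case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'U' || b == 'T';
  case 'C': return b == 'G';
  default: return false;
  }
}

//' Maximum base-pairing secondary structure (Nussinov dynamic program)
//'
//' Computes one maximum-cardinality set of nested canonical base pairs
//' (AU/GC/GU wobble) subject to a minimum hairpin loop length. Ties are
//' broken toward pairing each base with its most distant optimal partner
//' (favoring long-range stems), which makes the traceback deterministic.
//'
//' @param seq character scalar, sequence over ACGUT (case-insensitive).
//' @param min_loop integer, minimum number of unpaired bases enclosed by
//'   any pair (default 3).
//' @return integer vector of length \code{nchar(seq)}: 1-based index of the
//'   pairing partner of each position, or 0 if unpaired.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector nussinov_partners(std::string seq, int min_loop = 3) {
  int n = seq.size();
  IntegerVector partner(n, 0);
  if (n < 2) return partner;
  for (int i = 0; i < n; ++i) seq[i] = std::toupper(seq[i]);

  // M[i][j] = max pairs in seq[i..j], stored in a flat vector
  std::vector<int> M((size_t)n * n, 0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[idx(i + 1, j)];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1 + (k > i + 1 ? M[idx(i + 1, k - 1)] : 0)
                  + (k < j ? M[idx(k + 1, j)] : 0);
        if (v > best) best = v;
      }
      M[idx(i, j)] = best;
    }
  }

  // traceback; prefer pairing i when it attains the optimum, and among
  // optimal partners take the most distant (rightmost) one — this favors
  // the long-range stem over equal-score pairings into the enclosed loop,
  // mimicking the stacking preference of real duplexes
  std::stack<std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (j - i < min_loop + 1) continue;
    int target = M[idx(i, j)];
    if (target == 0) continue;
    bool paired = false;
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1 + (k > i + 1 ? M[idx(i + 1, k - 1)] : 0)
                + (k < j ? M[idx(k + 1, j)] : 0);
      if (v == target) {
        partner[i] = k + 1;
        partner[k] = i + 1;
        if (k > i + 1) todo.push(std::make_pair(i + 1, k - 1));
        if (k < j) todo.push(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push(std::make_pair(i + 1, j));
  }
  return partner;
}
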