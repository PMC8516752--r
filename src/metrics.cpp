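#include <Rcpp.h>
using namespace Rcpp;

// Strings arrive as integer code-point vectors (utf8ToInt on the R side), so
// every routine here is Unicode-correct by construction: a "character" is one
// code point, and spaces are ordinary characters.

// [[Rcpp::export(name = ".lev_cpp")]]
int lev_cpp(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Greedy within-window character matching: scan the response left to right;
// each character matches the leftmost unmatched identical character of the
// target no further away (by position) than the window. Transpositions are
// half the number of matched positions whose order differs between the two
// matched sequences, rounded down.
// Returns (s, n, window).
// [[Rcpp::export(name = ".jaro_cpp")]]
IntegerVector jaro_cpp(IntegerVector a, IntegerVector b) {
  int A = a.size(), B = b.size();
  int window = std::max(0, std::max(A, B) / 2 - 1);
  std::vector<bool> a_used(A, false);
  std::vector<int> b_match;   // matched chars in response order
  std::vector<int> a_idx;     // their positions in the target
  for (int j = 0; j < B; ++j) {
    int lo = std::max(0, j - window), hi = std::min(A - 1, j + window);
    for (int i = lo; i <= hi; ++i) {
      if (!a_used[i] && a[i] == b[j]) {
        a_used[i] = true;
        b_match.push_back(b[j]);
        a_idx.push_back(i);
        break;
      }
    }
  }
  int s = (int)b_match.size();
  std::vector<int> a_sorted(a_idx);
  std::sort(a_sorted.begin(), a_sorted.end());
  int mismatches = 0;
  for (int k = 0; k < s; ++k)
    if (a[a_sorted[k]] != b_match[k]) ++mismatches;
  return IntegerVector::create(s, mismatches / 2, window);
}

// Longest common substring of a[lo_a, hi_a) x b[lo_b, hi_b); ties broken by
// smallest start in a, then smallest start in b (first strictly-longer hit
// while scanning forward).
static void lcs_block(const IntegerVector& a, const IntegerVector& b,
                      int lo_a, int hi_a, int lo_b, int hi_b,
                      int& best_a, int& best_b, int& best_len) {
  int m = hi_b - lo_b;
  best_len = 0; best_a = lo_a; best_b = lo_b;
  if (m <= 0 || hi_a - lo_a <= 0) return;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = lo_a; i < hi_a; ++i) {
    cur[0] = 0;
    for (int j = lo_b; j < hi_b; ++j) {
      int c = (a[i] == b[j]) ? prev[j - lo_b] + 1 : 0;
      cur[j - lo_b + 1] = c;
      if (c > best_len) {
        best_len = c;
        best_a = i - c + 1;
        best_b = j - c + 1;
      }
    }
    std::swap(prev, cur);
  }
}

static void match_rec(const IntegerVector& a, const IntegerVector& b,
                      int lo_a, int hi_a, int lo_b, int hi_b,
                      std::vector<int>& out) {
  int ba, bb, len;
  lcs_block(a, b, lo_a, hi_a, lo_b, hi_b, ba, bb, len);
  if (len == 0) return;
  match_rec(a, b, lo_a, ba, lo_b, bb, out);
  out.push_back(ba); out.push_back(bb); out.push_back(len);
  match_rec(a, b, ba + len, hi_a, bb + len, hi_b, out);
}

// Recursive longest-matching-block decomposition (find the longest common
// contiguous substring, recurse on unmatched prefixes and suffixes).
// Returns a 3-column matrix: 0-based a start, 0-based b start, length.
// [[Rcpp::export(name = ".blocks_cpp")]]
IntegerMatrix blocks_cpp(IntegerVector a, IntegerVector b) {
  std::vector<int> out;
  match_rec(a, b, 0, a.size(), 0, b.size(), out);
  int k = (int)out.size() / 3;
  IntegerMatrix res(k, 3);
  for (int r = 0; r < k; ++r) {
    res(r, 0) = out[3 * r];
    res(r, 1) = out[3 * r + 1];
    res(r, 2) = out[3 * r + 2];
  }
  return res;
}
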