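#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// 4-bit nucleotide masks over the IUPAC alphabet; 0 = invalid symbol.
static int iupac_mask_of(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return 1 | 2 | 4 | 8;
    default: return 0;
  }
}

static inline bool bases_compatible(char a, char b) {
  return (iupac_mask_of(a) & iupac_mask_of(b)) != 0;
}

// [[Rcpp::export(name = ".cpp_iupac_compatible")]]
LogicalVector cpp_iupac_compatible(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i]);
    std::string sb = as<std::string>(b[i % b.size()]);
    bool ok = sa.size() == sb.size();
    for (size_t j = 0; ok && j < sa.size(); ++j)
      ok = bases_compatible(sa[j], sb[j]);
    out[i] = ok;
  }
  return out;
}

// Banded Levenshtein distance with early exit: exact whenever the true
// distance is <= cap, otherwise returns cap + 1 as a sentinel.
static int banded_lv(const std::string &a, const std::string &b, int cap) {
  int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > cap) return cap + 1;
  int band = cap;
  std::vector<int> prev(m + 1, cap + 1), cur(m + 1, cap + 1);
  for (int j = 0; j <= std::min(m, band); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - band), hi = std::min(m, i + band);
    std::fill(cur.begin(), cur.end(), cap + 1);
    if (lo == 1 && i <= band) cur[0] = i;
    int rowmin = cur[0];
    for (int j = lo; j <= hi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = (prev[j] <= cap ? prev[j] + 1 : cap + 1);
      int ins = (cur[j - 1] <= cap ? cur[j - 1] + 1 : cap + 1);
      int v = std::min(sub, std::min(del, ins));
      cur[j] = std::min(v, cap + 1);
      rowmin = std::min(rowmin, cur[j]);
    }
    if (rowmin > cap) return cap + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[m], cap + 1);
}

// [[Rcpp::export(name = ".cpp_edit_distance")]]
IntegerVector cpp_edit_distance(CharacterVector a, CharacterVector b, int cap) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i % a.size()]);
    std::string sb = as<std::string>(b[i % b.size()]);
    out[i] = banded_lv(sa, sb, cap);
  }
  return out;
}

// Semi-global ("infix") edit distance: the needle must align end to end,
// the haystack contributes a free-floating window. Returns the minimal
// distance together with the 1-based start/end of the matched window.
// With iupac = true a needle symbol matches any compatible haystack base
// at zero cost (primer search); plain equality otherwise (index search).
static void infix_align(const std::string &needle, const std::string &hay,
                        bool iupac, int &best, int &best_start, int &best_end) {
  int n = (int)needle.size(), m = (int)hay.size();
  // dp over needle rows; start[j] tracks the window origin column.
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<int> sprev(m + 1), scur(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = 0; sprev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i; scur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      bool match = iupac ? bases_compatible(needle[i - 1], hay[j - 1])
                         : (needle[i - 1] == hay[j - 1]);
      int sub = prev[j - 1] + (match ? 0 : 1);
      int del = prev[j] + 1;      // consume needle base, no haystack base
      int ins = cur[j - 1] + 1;   // consume haystack base
      int v = sub, s = sprev[j - 1];
      if (del < v) { v = del; s = sprev[j]; }
      if (ins < v) { v = ins; s = scur[j - 1]; }
      cur[j] = v; scur[j] = s;
    }
    std::swap(prev, cur);
    std::swap(sprev, scur);
  }
  best = INT_MAX; best_start = 0; best_end = 0;
  for (int j = 0; j <= m; ++j) {
    if (prev[j] < best) { best = prev[j]; best_start = sprev[j] + 1; best_end = j; }
  }
}

// [[Rcpp::export(name = ".cpp_infix_search")]]
List cpp_infix_search(CharacterVector needles, std::string haystack, bool iupac) {
  R_xlen_t n = needles.size();
  IntegerVector dist(n), start(n), end(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string nd = as<std::string>(needles[i]);
    int d, s, e;
    infix_align(nd, haystack, iupac, d, s, e);
    dist[i] = d; start[i] = s; end[i] = e;
  }
  return List::create(_["dist"] = dist, _["start"] = start, _["end"] = end);
}

// Distance matrix of every index against every read window: the workhorse
// behind demultiplexing. Rows = reads (windows), columns = indexes.
// Also returns matched window end (for left windows) and start (for right
// windows) so trimming can cut at the observed index boundary.
// [[Rcpp::export(name = ".cpp_index_scan")]]
List cpp_index_scan(CharacterVector windows, CharacterVector indexes) {
  int nr = (int)windows.size(), nc = (int)indexes.size();
  IntegerMatrix dist(nr, nc), start(nr, nc), end(nr, nc);
  std::vector<std::string> idx(nc);
  for (int j = 0; j < nc; ++j) idx[j] = as<std::string>(indexes[j]);
  for (int i = 0; i < nr; ++i) {
    std::string w = as<std::string>(windows[i]);
    for (int j = 0; j < nc; ++j) {
      int d, s, e;
      infix_align(idx[j], w, false, d, s, e);
      dist(i, j) = d; start(i, j) = s; end(i, j) = e;
    }
  }
  return List::create(_["dist"] = dist, _["start"] = start, _["end"] = end);
}
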