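#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static int mask_of(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 5;  case 'Y': case 'y': return 10;
    case 'S': case 's': return 6;  case 'W': case 'w': return 9;
    case 'K': case 'k': return 12; case 'M': case 'm': return 3;
    case 'B': case 'b': return 14; case 'D': case 'd': return 13;
    case 'H': case 'h': return 11; case 'V': case 'v': return 7;
    case 'N': case 'n': return 15;
    default: return 0;
  }
}

// Affine-gap pairwise alignment (Gotoh) with match +2, mismatch -3, and a
// gap of length L costing open + ext*L (default 5 + 2L). IUPAC-compatible
// symbol pairs score as matches. local=true: Smith-Waterman, else global
// (Needleman-Wunsch, end gaps penalised). Traceback prefers diagonal, then
// gap-in-subject, then gap-in-query (deterministic).
// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(std::string a, std::string b, bool local,
                    double match = 2.0, double mismatch = -3.0,
                    double gap_open = 5.0, double gap_ext = 2.0) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> H((n + 1) * (m + 1), 0.0), E(H), F(H);
  // traceback codes: 0 stop, 1 diag, 2 up(E: gap in b), 3 left(F: gap in a)
  std::vector<unsigned char> TB((n + 1) * (m + 1), 0);
  std::vector<unsigned char> TE((n + 1) * (m + 1), 0), TF((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) {
    E[at(0, j)] = NEG;
    if (!local && j > 0) { H[at(0, j)] = -(gap_open + gap_ext * j); TB[at(0, j)] = 3; }
    F[at(0, j)] = local ? NEG : H[at(0, j)];
  }
  for (int i = 0; i <= n; ++i) {
    F[at(i, 0)] = NEG;
    if (!local && i > 0) { H[at(i, 0)] = -(gap_open + gap_ext * i); TB[at(i, 0)] = 2; }
    E[at(i, 0)] = local ? NEG : H[at(i, 0)];
  }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int ma = mask_of(a[i - 1]);
    for (int j = 1; j <= m; ++j) {
      double e_open = H[at(i - 1, j)] - (gap_open + gap_ext);
      double e_ext = E[at(i - 1, j)] - gap_ext;
      if (e_open >= e_ext) { E[at(i, j)] = e_open; TE[at(i, j)] = 0; }
      else { E[at(i, j)] = e_ext; TE[at(i, j)] = 1; }
      double f_open = H[at(i, j - 1)] - (gap_open + gap_ext);
      double f_ext = F[at(i, j - 1)] - gap_ext;
      if (f_open >= f_ext) { F[at(i, j)] = f_open; TF[at(i, j)] = 0; }
      else { F[at(i, j)] = f_ext; TF[at(i, j)] = 1; }
      double s = (ma & mask_of(b[j - 1])) ? match : mismatch;
      double diag = H[at(i - 1, j - 1)] + s;
      double h = diag; unsigned char tb = 1;
      if (E[at(i, j)] > h) { h = E[at(i, j)]; tb = 2; }
      if (F[at(i, j)] > h) { h = F[at(i, j)]; tb = 3; }
      if (local && h <= 0) { h = 0; tb = 0; }
      H[at(i, j)] = h; TB[at(i, j)] = tb;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i, j;
  double score;
  if (local) { i = bi; j = bj; score = best; }
  else { i = n; j = m; score = H[at(n, m)]; }
  std::string aa, bb;
  int qi_end = i, sj_end = j;
  // follow gap-state runs so extensions are traced correctly
  int state = 0;  // 0 = in H, 2 = in E run, 3 = in F run
  while (i > 0 || j > 0) {
    if (local && TB[at(i, j)] == 0 && state == 0) break;
    unsigned char tb = state == 0 ? TB[at(i, j)] : (unsigned char)state;
    if (tb == 1) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j; state = 0;
    } else if (tb == 2) {
      bool ext = TE[at(i, j)] == 1;
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
      state = ext ? 2 : 0;
    } else if (tb == 3) {
      bool ext = TF[at(i, j)] == 1;
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
      state = ext ? 3 : 0;
    } else break;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  int matches = 0;
  for (size_t k = 0; k < aa.size(); ++k)
    if ((mask_of(aa[k]) & mask_of(bb[k])) != 0) ++matches;
  return List::create(_["score"] = score,
                      _["aligned_query"] = aa, _["aligned_subject"] = bb,
                      _["alignment_length"] = (int)aa.size(),
                      _["matches"] = matches,
                      _["query_start"] = i + 1, _["query_end"] = qi_end,
                      _["subject_start"] = j + 1, _["subject_end"] = sj_end);
}
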