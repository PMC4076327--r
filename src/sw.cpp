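#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 2-bit base code; -1 for N or anything else (never matches, never seeds).
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// All w-mer codes of a sequence; -1 where the window contains a non-ACGT base.
// [[Rcpp::export]]
IntegerVector cpp_word_codes(std::string s, int w) {
  int n = (int)s.size() - w + 1;
  if (n <= 0) return IntegerVector(0);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    long code = 0; bool ok = true;
    for (int j = 0; j < w; ++j) {
      int b = base_code(s[i + j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | b;
    }
    out[i] = ok ? (int)code : -1;
  }
  return out;
}

// Ungapped x-drop extension of an exact word seed at (qpos, spos), 0-based.
// Returns best score and the extended 0-based half-open extents.
static void ungapped_extend(const std::string &a, const std::string &b,
                            int qpos, int spos, int w,
                            int match, int mismatch, int xdrop,
                            int &best, int &q0, int &q1, int &s0, int &s1) {
  best = w * match;
  int score = best;
  int i = qpos + w, j = spos + w;
  q1 = i; s1 = j;
  while (i < (int)a.size() && j < (int)b.size()) {
    int ca = base_code(a[i]), cb = base_code(b[j]);
    score += (ca >= 0 && ca == cb) ? match : mismatch;
    ++i; ++j;
    if (score > best) { best = score; q1 = i; s1 = j; }
    if (best - score > xdrop) break;
  }
  int right_best = best;
  score = right_best;
  i = qpos - 1; j = spos - 1;
  q0 = qpos; s0 = spos;
  while (i >= 0 && j >= 0) {
    int ca = base_code(a[i]), cb = base_code(b[j]);
    score += (ca >= 0 && ca == cb) ? match : mismatch;
    if (score > best) { best = score; q0 = i; s0 = j; }
    if (best - score > xdrop) break;
    --i; --j;
  }
}

// Best ungapped seed extension between two sequences: exact w-mer seeds via a
// word table of b, one extension per diagonal (first seed wins).
// [[Rcpp::export]]
List cpp_best_ungapped(std::string a, std::string b, int w,
                       int match, int mismatch, int xdrop) {
  int na = (int)a.size() - w + 1, nb = (int)b.size() - w + 1;
  List out = List::create(_["score"] = 0, _["q_start"] = -1, _["q_end"] = -1,
                          _["s_start"] = -1, _["s_end"] = -1,
                          _["n_seeds"] = 0);
  if (na <= 0 || nb <= 0) return out;
  IntegerVector wa = cpp_word_codes(a, w), wb = cpp_word_codes(b, w);
  std::unordered_map<int, std::vector<int> > tab;
  tab.reserve(nb * 2);
  for (int j = 0; j < nb; ++j) if (wb[j] >= 0) tab[wb[j]].push_back(j);
  std::unordered_set<long> diag_seen;
  int best = 0, bq0 = -1, bq1 = -1, bs0 = -1, bs1 = -1, nseeds = 0;
  for (int i = 0; i < na; ++i) {
    if (wa[i] < 0) continue;
    std::unordered_map<int, std::vector<int> >::iterator it = tab.find(wa[i]);
    if (it == tab.end()) continue;
    for (size_t k = 0; k < it->second.size(); ++k) {
      int j = it->second[k];
      long d = (long)i - j + (long)b.size();
      if (diag_seen.count(d)) continue;
      diag_seen.insert(d);
      ++nseeds;
      int sc, q0, q1, s0, s1;
      ungapped_extend(a, b, i, j, w, match, mismatch, xdrop,
                      sc, q0, q1, s0, s1);
      if (sc > best) { best = sc; bq0 = q0; bq1 = q1; bs0 = s0; bs1 = s1; }
    }
  }
  out["score"] = best; out["q_start"] = bq0; out["q_end"] = bq1;
  out["s_start"] = bs0; out["s_end"] = bs1; out["n_seeds"] = nseeds;
  return out;
}

// Full affine-gap Smith-Waterman with traceback. Gap of length L costs
// gap_open + L * gap_extend (NCBI blastn flag convention). N never matches.
// Returns the single optimal local alignment (ties: smallest end i, then j).
// [[Rcpp::export]]
List cpp_sw_affine(std::string a, std::string b,
                   int match, int mismatch, int gap_open, int gap_extend) {
  int n = a.size(), m = b.size();
  const int NEG = -1000000000;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG); // gap in b (vertical)
  // trace codes: 0 stop, 1 diag, 2 up(E: consume a), 3 left(F: consume b)
  // plus separate matrices for E/F continuation
  std::vector<unsigned char> trH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> trE((size_t)(n + 1) * (m + 1), 0); // 1 = open
  std::vector<unsigned char> trF((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  std::vector<int> acode(n), bcode(m);
  for (int i = 0; i < n; ++i) acode[i] = base_code(a[i]);
  for (int j = 0; j < m; ++j) bcode[j] = base_code(b[j]);
  int gopen1 = gap_open + gap_extend; // cost of a length-1 gap
  for (int i = 1; i <= n; ++i) {
    int Fj = NEG; // gap in a (horizontal), current row
    Hcur[0] = 0; Ecur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      // E: gap in b, coming from row i-1
      int e_open = Hprev[j] - gopen1;
      int e_ext = Eprev[j] - gap_extend;
      int E = e_open >= e_ext ? e_open : e_ext;
      trE[idx] = e_open >= e_ext ? 1 : 0;
      // F: gap in a, coming from column j-1 in this row
      int f_open = Hcur[j - 1] - gopen1;
      int f_ext = Fj - gap_extend;
      int F = f_open >= f_ext ? f_open : f_ext;
      trF[idx] = f_open >= f_ext ? 1 : 0;
      int s = (acode[i - 1] >= 0 && acode[i - 1] == bcode[j - 1])
                ? match : mismatch;
      int diag = Hprev[j - 1] + s;
      int H = 0; unsigned char t = 0;
      if (diag > H) { H = diag; t = 1; }
      if (E > H) { H = E; t = 2; }
      if (F > H) { H = F; t = 3; }
      Hcur[j] = H; Ecur[j] = E; Fj = F; trH[idx] = t;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
  }
  // traceback
  std::string edit;
  int i = bi, j = bj;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 || j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = trH[idx];
      if (t == 0) break;
      if (t == 1) {
        edit.push_back((acode[i - 1] >= 0 && acode[i - 1] == bcode[j - 1])
                         ? '=' : 'X');
        --i; --j;
      } else if (t == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // E: gap in b, consume a
      edit.push_back('D');
      state = trE[idx] ? 0 : 1;
      --i;
    } else { // F: gap in a, consume b
      edit.push_back('I');
      state = trF[idx] ? 0 : 2;
      --j;
    }
  }
  std::reverse(edit.begin(), edit.end());
  return List::create(
    _["score"] = best,
    _["q_start"] = i, _["q_end"] = bi,   // 0-based half-open on a
    _["s_start"] = j, _["s_end"] = bj,   // 0-based half-open on b
    _["edit"] = edit);
}
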