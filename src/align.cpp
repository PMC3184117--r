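#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of two DNA strings with linear gap
// penalties. Beyond the optimal score we need, for the homology screen,
// a "nucleotide difference" style summary: the mismatch count covers the
// full end-to-end overlap implied by the alignment, i.e. core mismatch
// columns (substitutions, plus gap columns when count_indels is true)
// plus the differences found when the core is extended diagonally
// through the flanks the score-maximizing alignment trimmed away.
// Overhang is only the genuine end offset (the absolute difference of
// the two unaligned counts), the part of a sequence extending past the
// other. Ties among equal-scoring alignments are resolved
// deterministically: fewest mismatches, then smallest total overhang,
// then leftmost start.

namespace {

struct Cell {
  double score;
  int mm;    // mismatches along the best path into this cell
  char dir;  // 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
};

struct AlnResult {
  int mismatches, oh_left, oh_right, aligned_length;
  double score;
};

AlnResult sw_one(const std::string& a, const std::string& b,
                 double match, double mismatch, double gap,
                 bool count_indels) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<Cell> H((size_t)(n + 1) * (m + 1));
  auto at = [&](int i, int j) -> Cell& { return H[(size_t)i * (m + 1) + j]; };
  for (int j = 0; j <= m; ++j) at(0, j) = {0.0, 0, 0};
  for (int i = 0; i <= n; ++i) at(i, 0) = {0.0, 0, 0};

  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool is_match = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      double sdiag = at(i - 1, j - 1).score + (is_match ? match : mismatch);
      int mdiag = at(i - 1, j - 1).mm + (is_match ? 0 : 1);
      double sup = at(i - 1, j).score + gap;
      int mup = at(i - 1, j).mm + (count_indels ? 1 : 0);
      double sleft = at(i, j - 1).score + gap;
      int mleft = at(i, j - 1).mm + (count_indels ? 1 : 0);

      // start from the restart option (empty alignment, score 0);
      // prefer higher score, then fewer mismatches; remaining ties go
      // to the earlier candidate in the order restart, diag, up, left
      Cell c = {0.0, 0, 0};
      const double cs[3] = {sdiag, sup, sleft};
      const int cm[3] = {mdiag, mup, mleft};
      for (int k = 0; k < 3; ++k) {
        if (cs[k] > c.score || (cs[k] == c.score && cm[k] < c.mm))
          c = {cs[k], cm[k], (char)(k + 1)};
      }
      at(i, j) = c;
      if (c.score > best) best = c.score;
    }
  }

  AlnResult out;
  if (best <= 0.0) {
    // no positive-scoring local alignment at all (no common base):
    // treat as full offset-0 overlap, entirely mismatched
    int mn = n < m ? n : m;
    out = {mn, 0, n > m ? n - m : m - n, mn, 0.0};
    return out;
  }

  bool have = false;
  int b_mm = INT_MAX, b_oh = INT_MAX, b_as = INT_MAX, b_bs = INT_MAX;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (at(i, j).score != best) continue;
      // traceback to the start of this candidate alignment
      int ci = i, cj = j, cols = 0;
      while (at(ci, cj).dir != 0) {
        char d = at(ci, cj).dir;
        ++cols;
        if (d == 1) { --ci; --cj; }
        else if (d == 2) --ci;
        else --cj;
      }
      int a_start = ci + 1, b_start = cj + 1;  // 1-based first aligned base
      int la = a_start - 1, lb = b_start - 1;  // unaligned prefixes
      int ra = n - i, rb = m - j;              // unaligned suffixes
      int trim_l = la < lb ? la : lb;
      int trim_r = ra < rb ? ra : rb;
      // extend the core diagonally through the trimmed flanks and
      // count the actual differences there
      int flank_mm = 0;
      for (int t = 1; t <= trim_l; ++t) {
        char ca = a[a_start - 1 - t], cb = b[b_start - 1 - t];
        if (!(ca == cb && ca != 'N')) ++flank_mm;
      }
      for (int t = 1; t <= trim_r; ++t) {
        char ca = a[i - 1 + t], cb = b[j - 1 + t];
        if (!(ca == cb && ca != 'N')) ++flank_mm;
      }
      int mm = at(i, j).mm + flank_mm;
      int ohl = la > lb ? la - lb : lb - la;
      int ohr = ra > rb ? ra - rb : rb - ra;
      int oh = ohl + ohr;
      if (mm < b_mm || (mm == b_mm && (oh < b_oh ||
          (oh == b_oh && (a_start < b_as ||
           (a_start == b_as && b_start < b_bs)))))) {
        b_mm = mm; b_oh = oh; b_as = a_start; b_bs = b_start;
        out = {mm, ohl, ohr, cols + trim_l + trim_r, best};
        have = true;
      }
    }
  }
  if (!have) {
    int mn = n < m ? n : m;
    out = {mn, 0, n > m ? n - m : m - n, mn, 0.0};
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, double match_score,
                  double mismatch_score, double gap_score,
                  bool count_indels) {
  AlnResult r = sw_one(a, b, match_score, mismatch_score, gap_score,
                       count_indels);
  return List::create(_["mismatches"] = r.mismatches,
                      _["overhang_left"] = r.oh_left,
                      _["overhang_right"] = r.oh_right,
                      _["aligned_length"] = r.aligned_length,
                      _["score"] = r.score);
}

// All-vs-all summaries for a catalog of assay targets against a panel;
// returns one integer matrix per summary field, assays in rows.
// [[Rcpp::export]]
List sw_align_many_cpp(CharacterVector a_seqs, CharacterVector b_seqs,
                       double match_score, double mismatch_score,
                       double gap_score, bool count_indels) {
  const int na = a_seqs.size(), nb = b_seqs.size();
  IntegerMatrix mm(na, nb), ohl(na, nb), ohr(na, nb), alen(na, nb);
  for (int i = 0; i < na; ++i) {
    std::string a = as<std::string>(a_seqs[i]);
    for (int j = 0; j < nb; ++j) {
      std::string b = as<std::string>(b_seqs[j]);
      AlnResult r = sw_one(a, b, match_score, mismatch_score, gap_score,
                           count_indels);
      mm(i, j) = r.mismatches;
      ohl(i, j) = r.oh_left;
      ohr(i, j) = r.oh_right;
      alen(i, j) = r.aligned_length;
    }
  }
  return List::create(_["mismatches"] = mm, _["overhang_left"] = ohl,
                      _["overhang_right"] = ohr,
                      _["aligned_length"] = alen);
}
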