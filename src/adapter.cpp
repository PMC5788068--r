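#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// Ungapped 3'-adapter scan. For each read, every 0-based start offset
// o in [0, len - min_overlap] is tried; the adapter prefix is compared
// column by column (the alignment may overhang the read's 3' end, so
// aligned_len = min(adapter_len, read_len - o)). 'N' (either side) is a
// mismatch. A candidate is valid when mismatches <= floor(rate * aligned_len)
// and aligned_len >= min_overlap. Among valid candidates the one with the
// smallest mismatch rate wins; ties go to the smallest offset. Rates are
// compared by cross-multiplication to stay in integer arithmetic.
//
// Returns an integer matrix with one row per read and columns
// offset (0-based, NA if no hit), aligned_len, mismatches.
// [[Rcpp::export]]
IntegerMatrix cpp_align_adapter(CharacterVector seqs, std::string adapter,
                                double max_mismatch_rate, int min_overlap) {
  int n = seqs.size();
  int alen = adapter.size();
  for (int i = 0; i < alen; ++i) adapter[i] = std::toupper(adapter[i]);
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = LENGTH(STRING_ELT(seqs, i));
    int best_off = NA_INTEGER, best_len = NA_INTEGER, best_mm = NA_INTEGER;
    for (int o = 0; o + min_overlap <= len; ++o) {
      int cols = std::min(alen, len - o);
      int budget = (int)std::floor(max_mismatch_rate * cols);
      int mm = 0;
      for (int j = 0; j < cols; ++j) {
        char c = std::toupper(s[o + j]);
        if (c != adapter[j] || c == 'N') {
          if (++mm > budget) break;
        }
      }
      if (mm > budget) continue;
      // valid candidate; better if strictly smaller rate mm/cols
      if (best_off == NA_INTEGER ||
          (long long)mm * best_len < (long long)best_mm * cols) {
        best_off = o; best_len = cols; best_mm = mm;
      }
    }
    out(i, 0) = best_off;
    out(i, 1) = best_len;
    out(i, 2) = best_mm;
  }
  colnames(out) = CharacterVector::create("offset", "aligned_len", "mismatches");
  return out;
}

// First/last retained index (1-based) after trimming low-quality bases from
// both ends: bases with quality < threshold are removed from the 5' end, then
// from the 3' end. Returns n x 2 matrix (from, to); from > to means the whole
// read is trimmed away. Qualities are Phred+33 characters.
// [[Rcpp::export]]
IntegerMatrix cpp_qual_trim_bounds(CharacterVector quals, int threshold) {
  int n = quals.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(quals, i));
    int len = LENGTH(STRING_ELT(quals, i));
    int from = 0, to = len - 1;
    while (from <= to && (q[from] - 33) < threshold) ++from;
    while (to >= from && (q[to] - 33) < threshold) --to;
    out(i, 0) = from + 1;
    out(i, 1) = to + 1;
  }
  return out;
}
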