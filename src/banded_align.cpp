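#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Banded Smith-Waterman (linear gap penalty) restricted to the diagonal band
//   j - i in [diag0 - band, diag0 + band]
// where i indexes the pattern (1..m) and j the subject (1..n), and diag0 is
// the expected 0-based offset of the pattern start within the subject.
// Candidate placements come from k-mer seeding, so the band only has to absorb
// indel drift across one repeat unit, not the whole read.
//
// Returns integer vector:
//   score, p_start, p_end, s_start, s_end (0-based half-open), n_match, n_cols
// A score of 0 means no positive-scoring local alignment inside the band.
// [[Rcpp::export(name = ".banded_local_align")]]
IntegerVector banded_local_align(const std::string& pattern,
                                 const std::string& subject,
                                 int diag0, int band,
                                 int match, int mismatch, int gap) {
  const int m = (int) pattern.size();
  const int n = (int) subject.size();
  const int B = 2 * band + 1;          // band columns per pattern row

  if (m == 0 || n == 0) {
    return IntegerVector::create(0, 0, 0, 0, 0, 0, 0);
  }

  // H rows: previous and current, each of width B + 2 (sentinels at ends).
  std::vector<int> prev(B + 2, 0), curr(B + 2, 0);
  // traceback: 0 = stop, 1 = diagonal, 2 = up (gap in subject), 3 = left (gap in pattern)
  std::vector<unsigned char> tb((size_t)(m + 1) * (B + 2), 0);

  int best = 0, best_i = 0, best_j = 0;

  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(1, i + diag0 - band);
    const int jhi = std::min(n, i + diag0 + band);
    std::fill(curr.begin(), curr.end(), 0);
    unsigned char* tbrow = &tb[(size_t)i * (B + 2)];
    if (jlo > jhi) continue;
    for (int j = jlo; j <= jhi; ++j) {
      // band column index (1-based within row, sentinel at 0 and B+1)
      const int b = j - i - diag0 + band + 1;
      // moving from row i-1 to i shifts the same j by +1 in band coordinates
      const int diag_prev = b;        // (i-1, j-1)
      const int up_prev   = b + 1;    // (i-1, j)
      const int left_curr = b - 1;    // (i,   j-1)

      const int s = (pattern[i - 1] == subject[j - 1]) ? match : mismatch;
      int v = 0; unsigned char dir = 0;

      const int vd = prev[diag_prev] + s;
      if (vd > v) { v = vd; dir = 1; }
      if (up_prev <= B) {
        const int vu = prev[up_prev] - gap;
        if (vu > v) { v = vu; dir = 2; }
      }
      if (left_curr >= 1) {
        const int vl = curr[left_curr] - gap;
        if (vl > v) { v = vl; dir = 3; }
      }
      curr[b] = v;
      tbrow[b] = (v > 0) ? dir : 0;
      if (v > best) { best = v; best_i = i; best_j = j; }
    }
    std::swap(prev, curr);
  }

  if (best <= 0) {
    return IntegerVector::create(0, 0, 0, 0, 0, 0, 0);
  }

  // traceback from (best_i, best_j)
  int i = best_i, j = best_j;
  int n_match = 0, n_cols = 0;
  while (i > 0 && j > 0) {
    const int b = j - i - diag0 + band + 1;
    if (b < 1 || b > B) break;
    const unsigned char dir = tb[(size_t)i * (B + 2) + b];
    if (dir == 0) break;
    ++n_cols;
    if (dir == 1) {
      if (pattern[i - 1] == subject[j - 1]) ++n_match;
      --i; --j;
    } else if (dir == 2) {
      --i;
    } else {
      --j;
    }
  }

  return IntegerVector::create(best, i, best_i, j, best_j, n_match, n_cols);
}
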