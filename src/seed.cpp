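#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Exact-match diagonals of the query's sampled k-mers in the subject.
// K-mers are taken from the query every `step` bases; each exact occurrence
// at subject position p of the k-mer starting at query position q yields the
// diagonal p - q (0-based offset of the query start implied by the match).
// [[Rcpp::export(name = ".seed_diags")]]
IntegerVector seed_diags_cpp(const std::string& query,
                             const std::string& subject,
                             int k, int step) {
  const int qn = (int) query.size(), sn = (int) subject.size();
  std::vector<int> out;
  if (qn < k || sn < k || k < 1 || k > 31) return IntegerVector(0);

  std::unordered_map<uint64_t, std::vector<int> > kmers;
  for (int q = 0; q + k <= qn; q += step) {
    uint64_t key = 0; bool ok = true;
    for (int t = 0; t < k; ++t) {
      int b = base2bits(query[q + t]);
      if (b < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t) b;
    }
    if (ok) kmers[key].push_back(q);
  }
  if (kmers.empty()) return IntegerVector(0);

  const uint64_t mask = (k == 31) ? 0x3FFFFFFFFFFFFFFFULL
                                  : ((1ULL << (2 * k)) - 1ULL);
  uint64_t key = 0; int run = 0;
  for (int p = 0; p < sn; ++p) {
    int b = base2bits(subject[p]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t) b) & mask;
    if (++run < k) continue;
    auto it = kmers.find(key);
    if (it != kmers.end()) {
      const int pos = p - k + 1;
      for (int q : it->second) out.push_back(pos - q);
    }
  }
  return IntegerVector(out.begin(), out.end());
}

// All exact occurrence start positions (0-based) of `query` in `subject`.
// [[Rcpp::export(name = ".exact_occurrences")]]
IntegerVector exact_occurrences(const std::string& query,
                                const std::string& subject) {
  std::vector<int> out;
  if (query.empty() || subject.size() < query.size())
    return IntegerVector(0);
  size_t p = subject.find(query, 0);
  while (p != std::string::npos) {
    out.push_back((int) p);
    p = subject.find(query, p + 1);
  }
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
std::string revcomp_cpp(const std::string& seq) {
  std::string out(seq.size(), 'N');
  const size_t n = seq.size();
  for (size_t i = 0; i < n; ++i) {
    char c = seq[n - 1 - i], r;
    switch (c) {
      case 'A': r = 'T'; break; case 'a': r = 't'; break;
      case 'C': r = 'G'; break; case 'c': r = 'g'; break;
      case 'G': r = 'C'; break; case 'g': r = 'c'; break;
      case 'T': r = 'A'; break; case 't': r = 'a'; break;
      default: r = 'N';
    }
    out[i] = r;
  }
  return out;
}
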