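#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// All strings within Hamming distance `remaining` of s, substitutions at
// positions >= start (avoids revisiting edited positions).
static void enumerate_neighbors(std::string &s, int start, int remaining,
                                std::unordered_set<std::string> &out) {
  out.insert(s);
  if (remaining == 0) return;
  const int k = (int)s.size();
  for (int i = start; i < k; ++i) {
    const char orig = s[i];
    for (int b = 0; b < 4; ++b) {
      if (BASES[b] == orig) continue;
      s[i] = BASES[b];
      enumerate_neighbors(s, i + 1, remaining - 1, out);
    }
    s[i] = orig;
  }
}

// Per-position mapability codes.
//   fwd: forward-strand k-mer windows over all sequences (NA where the window
//        contains N), rc: their reverse complements, margin: mismatch margin.
// Codes: 0 AMBIGUOUS, 1 REPETITIVE, 2 UNIQUE_STRICT, 3 UNIQUE_D1.
// A window is exact-unique when its k-mer occurs at exactly one physical site
// counting both strands; it is margin-unique when additionally no other site
// matches it (on either strand) within <= margin substitutions.
// [[Rcpp::export]]
IntegerVector cpp_classify_kmers(CharacterVector fwd, CharacterVector rc,
                                 int margin) {
  const int n = fwd.size();
  std::unordered_map<std::string, int> counts;
  counts.reserve((size_t)n * 2);
  for (int i = 0; i < n; ++i) {
    if (fwd[i] == NA_STRING) continue;
    counts[std::string(fwd[i])]++;
  }
  IntegerVector code(n);
  for (int i = 0; i < n; ++i) {
    if (fwd[i] == NA_STRING) {
      code[i] = 0;
      continue;
    }
    std::string w(fwd[i]);
    std::string r(rc[i]);
    int e = counts[w];
    if (w != r) {
      auto it = counts.find(r);
      if (it != counts.end()) e += it->second;
    }
    if (e > 1) {
      code[i] = 1;
      continue;
    }
    if (margin <= 0) {
      code[i] = 3;
      continue;
    }
    std::unordered_set<std::string> nb;
    enumerate_neighbors(w, 0, margin, nb);
    if (w != r) enumerate_neighbors(r, 0, margin, nb);
    long m = 0;
    for (const auto &u : nb) {
      auto it = counts.find(u);
      if (it != counts.end()) {
        m += it->second;
        if (m > 1) break;
      }
    }
    code[i] = (m > 1) ? 2 : 3;
  }
  return code;
}
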