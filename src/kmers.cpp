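#include <Rcpp.h>
#include <string>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static inline bool valid_base(char b) {
  return b == 'A' || b == 'C' || b == 'G' || b == 'T';
}

// lexicographic min of a window and its reverse complement
static std::string canonical_window(const char *s, int k) {
  std::string fwd(s, s + k);
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) rc[k - 1 - i] = comp_base(s[i]);
  return (rc < fwd) ? rc : fwd;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(CharacterVector seqs, int k) {
  if (k < 1) stop("k must be >= 1");
  std::unordered_set<std::string> out;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    std::string s = Rcpp::as<std::string>(seqs[i]);
    for (char &c : s) c = (char) toupper((unsigned char) c);
    int n = (int) s.size();
    if (n < k) continue;
    // track rightmost invalid base so windows containing non-ACGT are skipped
    int last_bad = -1;
    for (int j = 0; j < n; ++j) {
      if (!valid_base(s[j])) last_bad = j;
      int start = j - k + 1;
      if (start >= 0 && last_bad < start)
        out.insert(canonical_window(s.c_str() + start, k));
    }
  }
  CharacterVector res(out.size());
  R_xlen_t i = 0;
  for (const std::string &s : out) res[i++] = s;
  return res;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// FNV-1a over the k-mer bytes, salted per (seed, rep), splitmix-finalised.
// Returned as a double holding the top 53 bits, so R can order the values.
// [[Rcpp::export]]
NumericVector cpp_hash_kmers(CharacterVector kmers, double seed, int rep) {
  uint64_t salt = splitmix64(((uint64_t) seed) * 0x9E3779B97F4A7C15ULL +
                             (uint64_t) rep);
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    uint64_t h = 0xCBF29CE484222325ULL ^ salt;
    for (const char *p = s; *p; ++p) {
      h ^= (uint64_t) (unsigned char) (*p);
      h *= 0x100000001B3ULL;
    }
    out[i] = (double) (splitmix64(h) >> 11);
  }
  return out;
}

// n distinct random canonical k-mers, driven by R's RNG (so set.seed applies)
// [[Rcpp::export]]
CharacterVector cpp_random_kmer_universe(int n, int k) {
  if (n < 0) stop("n must be >= 0");
  if (k < 1) stop("k must be >= 1");
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::unordered_set<std::string> seen;
  std::vector<std::string> out;
  out.reserve(n);
  std::string buf(k, 'A');
  RNGScope scope;
  // distinct draws: collision rate is negligible for k >= 16 but loop anyway
  int guard = 0;
  while ((int) out.size() < n) {
    for (int j = 0; j < k; ++j) {
      int b = (int) (unif_rand() * 4.0);
      if (b > 3) b = 3;
      buf[j] = bases[b];
    }
    std::string canon = canonical_window(buf.c_str(), k);
    if (seen.insert(canon).second) {
      out.push_back(canon);
      guard = 0;
    } else if (++guard > 1000000) {
      stop("could not generate %d distinct canonical %d-mers", n, k);
    }
  }
  return CharacterVector(out.begin(), out.end());
}
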