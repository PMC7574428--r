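// 2-bit packed k-mer machinery: counting, set membership scans and a
// unitig-only de Bruijn assembler. k is capped at 31 so a k-mer fits in a
// 64-bit word (Jellyfish-style rolling encoding).

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

inline uint64_t canonical_code(uint64_t code, int k) {
  uint64_t rc = revcomp_code(code, k);
  return code < rc ? code : rc;
}

std::string decode_code(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

void check_k(int k) {
  if (k < 1) stop("k must be a positive integer");
  if (k > 31) stop("k must be <= 31 (2-bit packed representation)");
}

// Call fn(pos, code) for every length-k window made only of A/C/G/T.
// pos is the 0-based window start; windows touching any other symbol are
// silently skipped (the caller decides whether they count for anything).
template <typename F>
void scan_windows(const char *s, int n, int k, F fn) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t code = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) fn(i - k + 1, code);
  }
}

// Encode a full string as one k-mer; returns false on non-ACGT or length
// mismatch.
bool encode_kmer(const char *s, int n, int k, uint64_t &out) {
  if (n != k) return false;
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

std::unordered_set<uint64_t> encode_set(const CharacterVector &kmers, int k,
                                        bool canonical) {
  std::unordered_set<uint64_t> set;
  set.reserve((size_t)kmers.size() * 2 + 1);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t code;
    if (!encode_kmer(CHAR(STRING_ELT(kmers, i)),
                     (int)LENGTH(STRING_ELT(kmers, i)), k, code))
      stop("k-mer %d is not a length-%d A/C/G/T string", (int)(i + 1), k);
    set.insert(canonical ? canonical_code(code, k) : code);
  }
  return set;
}

} // namespace

// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector reads, int k, bool canonical) {
  check_k(k);
  std::unordered_map<uint64_t, int> tab;
  bool any_long_enough = false;
  double total = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int n = (int)LENGTH(STRING_ELT(reads, r));
    if (n >= k) any_long_enough = true;
    scan_windows(s, n, k, [&](int, uint64_t code) {
      tab[canonical ? canonical_code(code, k) : code] += 1;
      total += 1;
    });
  }
  if (!any_long_enough)
    stop("no countable k-mers: k exceeds every read length");
  std::vector<std::pair<uint64_t, int>> v(tab.begin(), tab.end());
  std::sort(v.begin(), v.end());
  CharacterVector keys(v.size());
  IntegerVector counts(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    keys[i] = decode_code(v[i].first, k);
    counts[i] = v[i].second;
  }
  return List::create(_["kmer"] = keys, _["count"] = counts,
                      _["total_instances"] = total);
}

// Per-read window statistics against a k-mer set. q counts every window
// (L - k + 1, including windows with non-ACGT symbols, which can never hit);
// first_in / last_in report the terminal windows s_1 and s_q.
// [[Rcpp::export]]
List kmer_classify_cpp(CharacterVector reads, CharacterVector members, int k,
                       bool canonical) {
  check_k(k);
  std::unordered_set<uint64_t> set = encode_set(members, k, canonical);
  R_xlen_t n = reads.size();
  IntegerVector q(n), n_high(n);
  LogicalVector first_in(n), last_in(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    int qq = len >= k ? len - k + 1 : 0;
    int hits = 0;
    bool fin = false, lin = false;
    scan_windows(s, len, k, [&](int pos, uint64_t code) {
      uint64_t key = canonical ? canonical_code(code, k) : code;
      if (set.count(key)) {
        ++hits;
        if (pos == 0) fin = true;
        if (pos == qq - 1) lin = true;
      }
    });
    q[r] = qq; n_high[r] = hits; first_in[r] = fin; last_in[r] = lin;
  }
  return List::create(_["q"] = q, _["n_high"] = n_high,
                      _["first_in"] = first_in, _["last_in"] = last_in);
}

// Per-window counts of one sequence against a (k-mer, count) table; windows
// absent from the table (or containing non-ACGT) get 0.
// [[Rcpp::export]]
NumericVector kmer_window_counts_cpp(std::string seq, CharacterVector kmers,
                                     NumericVector counts, int k,
                                     bool canonical) {
  check_k(k);
  if (kmers.size() != counts.size()) stop("kmers and counts differ in length");
  std::unordered_map<uint64_t, double> tab;
  tab.reserve((size_t)kmers.size() * 2 + 1);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t code;
    if (!encode_kmer(CHAR(STRING_ELT(kmers, i)),
                     (int)LENGTH(STRING_ELT(kmers, i)), k, code))
      stop("k-mer %d is not a length-%d A/C/G/T string", (int)(i + 1), k);
    tab[canonical ? canonical_code(code, k) : code] = counts[i];
  }
  int n = (int)seq.size();
  int q = n >= k ? n - k + 1 : 0;
  NumericVector out(q, 0.0);
  scan_windows(seq.c_str(), n, k, [&](int pos, uint64_t code) {
    uint64_t key = canonical ? canonical_code(code, k) : code;
    auto it = tab.find(key);
    if (it != tab.end()) out[pos] = it->second;
  });
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  static unsigned char comp[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) comp[i] = (unsigned char)i;
    comp['A'] = 'T'; comp['T'] = 'A'; comp['C'] = 'G'; comp['G'] = 'C';
    comp['a'] = 't'; comp['t'] = 'a'; comp['c'] = 'g'; comp['g'] = 'c';
    init = true;
  }
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(STRING_ELT(x, i));
    int n = (int)LENGTH(STRING_ELT(x, i));
    std::string r((size_t)n, ' ');
    for (int j = 0; j < n; ++j)
      r[(size_t)(n - 1 - j)] = (char)comp[(unsigned char)s[j]];
    out[i] = r;
  }
  return out;
}

// Maximal unbranched paths (unitigs) of the bidirected de Bruijn graph whose
// edges are the supplied canonical k-mers. Nodes are (k-1)-mers; a path is
// extended through a node only if it has exactly one in- and one out-edge
// and is not its own reverse complement. k must be odd so no edge is a
// palindrome. Returns unitig sequences (as traversed) and the mean edge
// multiplicity along each path.
// [[Rcpp::export]]
List dbg_unitigs_cpp(CharacterVector kmers, NumericVector counts, int k) {
  check_k(k);
  if (k % 2 == 0) stop("assembly k must be odd");
  if (kmers.size() != counts.size()) stop("kmers and counts differ in length");
  std::unordered_map<uint64_t, double> cov;
  cov.reserve((size_t)kmers.size() * 2 + 1);
  std::vector<uint64_t> keys;
  keys.reserve((size_t)kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t code;
    if (!encode_kmer(CHAR(STRING_ELT(kmers, i)),
                     (int)LENGTH(STRING_ELT(kmers, i)), k, code))
      stop("k-mer %d is not a length-%d A/C/G/T string", (int)(i + 1), k);
    uint64_t c = canonical_code(code, k);
    if (cov.count(c)) stop("duplicate k-mer in graph edge list");
    cov[c] = counts[i];
    keys.push_back(c);
  }
  std::sort(keys.begin(), keys.end());

  const int km1 = k - 1;
  const uint64_t nodemask = (1ULL << (2 * km1)) - 1;
  auto exists = [&](uint64_t w) { return cov.count(canonical_code(w, k)) > 0; };
  auto out_edges = [&](uint64_t v, std::vector<uint64_t> &res) {
    res.clear();
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t w = (v << 2) | b;
      if (exists(w)) res.push_back(w);
    }
  };
  auto in_count = [&](uint64_t v) {
    int c = 0;
    for (uint64_t b = 0; b < 4; ++b)
      if (exists((b << (2 * km1)) | v)) ++c;
    return c;
  };

  std::unordered_set<uint64_t> visited;
  visited.reserve(keys.size() * 2 + 1);

  // Walk forward from oriented k-mer w while the junction node is simple,
  // marking canonical forms visited and appending oriented codes.
  auto extend = [&](std::vector<uint64_t> &path) {
    for (;;) {
      uint64_t w = path.back();
      uint64_t v = w & nodemask;
      if (v == revcomp_code(v, km1)) break;
      std::vector<uint64_t> outs;
      out_edges(v, outs);
      if (outs.size() != 1 || in_count(v) != 1) break;
      uint64_t c2 = canonical_code(outs[0], k);
      if (visited.count(c2)) break;
      visited.insert(c2);
      path.push_back(outs[0]);
    }
  };

  std::vector<std::string> seqs;
  std::vector<double> covs;
  for (uint64_t seed : keys) {
    if (visited.count(seed)) continue;
    visited.insert(seed);
    std::vector<uint64_t> fwd{seed};
    extend(fwd);
    std::vector<uint64_t> bwd{revcomp_code(seed, k)};
    extend(bwd);
    // full oriented path: reversed complements of bwd[1..] then fwd
    std::vector<uint64_t> path;
    path.reserve(bwd.size() - 1 + fwd.size());
    for (size_t i = bwd.size() - 1; i >= 1; --i)
      path.push_back(revcomp_code(bwd[i], k));
    for (uint64_t w : fwd) path.push_back(w);

    std::string s = decode_code(path[0], k);
    double c = cov[canonical_code(path[0], k)];
    static const char bases[] = "ACGT";
    for (size_t i = 1; i < path.size(); ++i) {
      s.push_back(bases[path[i] & 3ULL]);
      c += cov[canonical_code(path[i], k)];
    }
    seqs.push_back(s);
    covs.push_back(c / (double)path.size());
  }
  return List::create(_["seq"] = wrap(seqs), _["mean_cov"] = wrap(covs));
}
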