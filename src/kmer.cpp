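#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit encoding A=0, C=1, G=2, T=3 preserves lexicographic order, so the
// numeric minimum of a k-mer code and its reverse-complement code is the
// canonical (lexicographically smaller) k-mer. k is capped at 32 (64-bit code).

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char alpha[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = alpha[code & 3ULL];
    code >>= 2;
  }
  return s;
}

static inline uint64_t encode_kmer(const char *s, int k, bool &ok) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { ok = false; return 0; }
    code = (code << 2) | (uint64_t)c;
  }
  ok = true;
  return code;
}

// Scan one sequence, calling f(canonical_code) for every ACGT-only window.
template <typename F>
static void scan_canonical(const std::string &seq, int k, F f) {
  const int n = (int)seq.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0; // number of consecutive valid bases ending here
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) f(fwd < rc ? fwd : rc);
  }
}

// [[Rcpp::export]]
List cpp_count_canonical(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_map<uint64_t, int> counts;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    scan_canonical(seq, k, [&](uint64_t code) { ++counts[code]; });
  }
  const R_xlen_t m = (R_xlen_t)counts.size();
  CharacterVector kmer(m);
  IntegerVector count(m);
  R_xlen_t i = 0;
  for (const auto &kv : counts) {
    kmer[i] = decode_kmer(kv.first, k);
    count[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

static std::unordered_set<uint64_t> encode_set(const CharacterVector &kmers, int k) {
  std::unordered_set<uint64_t> out;
  out.reserve((size_t)kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k)
      stop("k-mer of wrong length in set");
    bool ok;
    uint64_t code = encode_kmer(s, k, ok);
    if (!ok) stop("non-ACGT character in k-mer set");
    out.insert(code);
  }
  return out;
}

// Occurrence counts of members of two disjoint canonical k-mer sets in each
// sequence (every window occurrence counts once).
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_hits(CharacterVector seqs, int k,
                            CharacterVector set1, CharacterVector set2) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_set<uint64_t> s1 = encode_set(set1, k);
  std::unordered_set<uint64_t> s2 = encode_set(set2, k);
  IntegerMatrix hits(seqs.size(), 2);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string seq = as<std::string>(seqs[i]);
    int h1 = 0, h2 = 0;
    scan_canonical(seq, k, [&](uint64_t code) {
      if (s1.count(code)) ++h1;
      else if (s2.count(code)) ++h2;
    });
    hits(i, 0) = h1;
    hits(i, 1) = h2;
  }
  return hits;
}

// Per-position k-mer coverage track: position p gets the source-multiset count
// of the canonical k-mer starting at p; positions with no valid window start
// (trailing k-1 bases, bases before an N run) inherit the last valid start's
// count; N positions themselves get 0.
// [[Rcpp::export]]
List cpp_position_coverage(CharacterVector targets, int k,
                           CharacterVector src_kmers, IntegerVector src_counts) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  if (src_kmers.size() != src_counts.size()) stop("k-mer/count length mismatch");
  std::unordered_map<uint64_t, int> src;
  src.reserve((size_t)src_kmers.size() * 2);
  for (R_xlen_t i = 0; i < src_kmers.size(); ++i) {
    bool ok;
    uint64_t code = encode_kmer(CHAR(STRING_ELT(src_kmers, i)), k, ok);
    if (!ok) stop("non-ACGT character in source k-mer");
    src[code] = src_counts[i];
  }
  List out(targets.size());
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < targets.size(); ++s) {
    std::string seq = as<std::string>(targets[s]);
    const int n = (int)seq.size();
    IntegerVector cov(n, 0);
    // start_count[p] = count for window starting at p, or -1 if invalid
    std::vector<int> start_count(n, -1);
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        auto it = src.find(canon);
        start_count[i - k + 1] = (it == src.end()) ? 0 : it->second;
      }
    }
    int carry = 0;
    for (int p = 0; p < n; ++p) {
      if (base_code(seq[p]) < 0) { cov[p] = 0; carry = 0; continue; }
      if (start_count[p] >= 0) carry = start_count[p];
      cov[p] = carry;
    }
    out[s] = cov;
  }
  out.attr("names") = targets.attr("names");
  return out;
}

// Greedy alignment-free diff walk between two haplotype sequences. Returns
// VCF-style anchored records (1-based positions on `a`). Events are assumed
// separated by more than `probe` matching bases (true for rejection-sampled
// non-overlapping variants).
// [[Rcpp::export]]
DataFrame cpp_diff_sequences(std::string a, std::string b,
                             int probe = 20, int max_event = 100000) {
  std::vector<int> pos;
  std::vector<std::string> ref, alt;
  const int na = (int)a.size(), nb = (int)b.size();
  int i = 0, j = 0;
  auto agree = [&](int ia, int jb) {
    // fractional forward agreement over the probe window (truncated at the
    // sequence ends): a correct offset agrees except at nearby substitutions
    // (~1 - snv_rate per base); a wrong offset agrees at random (~25%)
    int compared = 0, matched = 0;
    for (int t = 0; t < probe; ++t) {
      if (ia + t >= na || jb + t >= nb) break;
      ++compared;
      if (a[ia + t] == b[jb + t]) ++matched;
    }
    if (compared == 0) return true;
    return matched >= (int)(0.75 * compared + 0.5);
  };
  // stricter variant for the indel-length scan: a window truncated by the
  // sequence end is only accepted when the remainders align exactly
  // (otherwise scanning thousands of offsets finds spurious tail matches)
  auto agree_scan = [&](int ia, int jb) {
    if (na - ia < probe || nb - jb < probe) {
      if (na - ia != nb - jb) return false;
      for (int t = 0; ia + t < na; ++t)
        if (a[ia + t] != b[jb + t]) return false;
      return true;
    }
    return agree(ia, jb);
  };
  while (i < na && j < nb) {
    if (a[i] == b[j]) { ++i; ++j; continue; }
    if (agree(i + 1, j + 1)) { // substitution
      pos.push_back(i + 1);
      ref.push_back(std::string(1, a[i]));
      alt.push_back(std::string(1, b[j]));
      ++i; ++j;
      continue;
    }
    bool found = false;
    for (int d = 1; d <= max_event && !found; ++d) {
      if (j + d <= nb && agree_scan(i, j + d)) { // insertion in b
        if (i == 0) stop("unanchored event at sequence start");
        pos.push_back(i); // anchor base a[i-1], 1-based position i
        ref.push_back(std::string(1, a[i - 1]));
        alt.push_back(std::string(1, a[i - 1]) + b.substr(j, d));
        j += d;
        found = true;
      } else if (i + d <= na && agree_scan(i + d, j)) { // deletion in b
        if (i == 0) stop("unanchored event at sequence start");
        pos.push_back(i);
        ref.push_back(std::string(1, a[i - 1]) + a.substr(i, d));
        alt.push_back(std::string(1, a[i - 1]));
        i += d;
        found = true;
      }
    }
    if (!found) stop("sequences failed to resynchronize at position %d", i + 1);
  }
  if (i < na) { // trailing deletion in b
    pos.push_back(i);
    ref.push_back(std::string(1, a[i - 1]) + a.substr(i));
    alt.push_back(std::string(1, a[i - 1]));
  } else if (j < nb) { // trailing insertion in b
    pos.push_back(i);
    ref.push_back(std::string(1, a[i - 1]));
    alt.push_back(std::string(1, a[i - 1]) + b.substr(j));
  }
  return DataFrame::create(_["pos"] = pos, _["ref"] = ref, _["alt"] = alt,
                           _["stringsAsFactors"] = false);
}
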