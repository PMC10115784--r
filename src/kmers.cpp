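#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit DNA encoding; canonical k-mer = min(forward, reverse-complement).
// Ambiguous bases invalidate every k-mer window overlapping them.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string decode_kmer(uint64_t key, int k) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = B[key & 3ULL];
    key >>= 2;
  }
  return s;
}

static inline uint64_t encode_string(const char* s, int k, bool* ok) {
  uint64_t key = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { *ok = false; return 0; }
    key = (key << 2) | (uint64_t)c;
  }
  *ok = true;
  return key;
}

// Rolling scan over one sequence calling f(pos, canonical_key) for each
// valid k-mer start position pos (0-based).
template <typename F>
static void scan_kmers(const char* s, R_xlen_t n, int k, F f) {
  if (n < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0; // number of consecutive valid bases ending at i
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - c)) << shift);
    if (++run >= k) {
      uint64_t canon = std::min(fwd, rev);
      f(i - k + 1, canon);
    }
  }
}

// [[Rcpp::export]]
List cpp_kmer_matrix(CharacterVector seqs, int k, int min_total) {
  int nseq = seqs.size();
  std::unordered_map<uint64_t, int> global;
  std::vector<double> valid(nseq, 0.0);
  for (int j = 0; j < nseq; ++j) {
    const char* s = CHAR(STRING_ELT(seqs, j));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, j));
    scan_kmers(s, n, k, [&](R_xlen_t, uint64_t key) {
      ++global[key];
      valid[j] += 1.0;
    });
  }
  std::vector<uint64_t> keep;
  keep.reserve(1024);
  for (auto& kv : global)
    if (kv.second >= min_total) keep.push_back(kv.first);
  std::sort(keep.begin(), keep.end());
  global.clear();
  std::unordered_map<uint64_t, int> col;
  col.reserve(keep.size() * 2);
  for (size_t i = 0; i < keep.size(); ++i) col[keep[i]] = (int)i;
  IntegerMatrix counts(nseq, (int)keep.size());
  for (int j = 0; j < nseq; ++j) {
    const char* s = CHAR(STRING_ELT(seqs, j));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, j));
    scan_kmers(s, n, k, [&](R_xlen_t, uint64_t key) {
      auto it = col.find(key);
      if (it != col.end()) counts(j, it->second) += 1;
    });
  }
  CharacterVector kmers((int)keep.size());
  for (size_t i = 0; i < keep.size(); ++i)
    kmers[(int)i] = decode_kmer(keep[i], k);
  return List::create(_["kmers"] = kmers, _["counts"] = counts,
                      _["valid"] = NumericVector(valid.begin(), valid.end()));
}

// Exhaustive per-sequence canonical k-mer tabulation (no count filter).
// Intended for small sequences (oracles, toy inputs).
// [[Rcpp::export]]
List cpp_kmer_table(CharacterVector seq, int k) {
  const char* s = CHAR(STRING_ELT(seq, 0));
  R_xlen_t n = LENGTH(STRING_ELT(seq, 0));
  std::unordered_map<uint64_t, int> tab;
  scan_kmers(s, n, k, [&](R_xlen_t, uint64_t key) { ++tab[key]; });
  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmers((int)keys.size());
  IntegerVector counts((int)keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[(int)i] = decode_kmer(keys[i], k);
    counts[(int)i] = tab[keys[i]];
  }
  return List::create(_["kmers"] = kmers, _["counts"] = counts);
}

static std::vector<std::unordered_set<uint64_t>> build_sets(List sets, int k) {
  std::vector<std::unordered_set<uint64_t>> out(sets.size());
  for (int m = 0; m < sets.size(); ++m) {
    CharacterVector sv = sets[m];
    for (int i = 0; i < sv.size(); ++i) {
      const char* s = CHAR(STRING_ELT(sv, i));
      if ((int)LENGTH(STRING_ELT(sv, i)) != k)
        stop("k-mer set %d contains a string whose length is not k", m + 1);
      bool ok = false;
      uint64_t fwd = encode_string(s, k, &ok);
      if (!ok) stop("k-mer set %d contains ambiguous bases", m + 1);
      uint64_t rev = 0, tmp = fwd;
      for (int j = 0; j < k; ++j) {
        rev = (rev << 2) | (3ULL - (tmp & 3ULL));
        tmp >>= 2;
      }
      out[m].insert(std::min(fwd, rev));
    }
  }
  return out;
}

// Per-window hit counts of each k-mer set along one sequence.
// Window of a k-mer is determined by its start position (0-based),
// tiling windows of window_size bp.
// [[Rcpp::export]]
List cpp_window_set_hits(CharacterVector seq, int k, List sets,
                         double window_size) {
  const char* s = CHAR(STRING_ELT(seq, 0));
  R_xlen_t n = LENGTH(STRING_ELT(seq, 0));
  int nwin = (int)((n + window_size - 1) / window_size);
  if (nwin < 1) nwin = 1;
  int nsets = sets.size();
  auto S = build_sets(sets, k);
  IntegerMatrix hits(nwin, nsets);
  IntegerVector totals(nwin);
  scan_kmers(s, n, k, [&](R_xlen_t pos, uint64_t key) {
    int w = (int)(pos / window_size);
    totals[w] += 1;
    for (int m = 0; m < nsets; ++m)
      if (S[m].count(key)) { hits(w, m) += 1; }
  });
  return List::create(_["hits"] = hits, _["totals"] = totals);
}

// Per-read hit counts of each k-mer set.
// [[Rcpp::export]]
IntegerMatrix cpp_classify_reads(CharacterVector reads, int k, List sets) {
  int nr = reads.size(), nsets = sets.size();
  auto S = build_sets(sets, k);
  IntegerMatrix hits(nr, nsets);
  for (int r = 0; r < nr; ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    R_xlen_t n = LENGTH(STRING_ELT(reads, r));
    scan_kmers(s, n, k, [&](R_xlen_t, uint64_t key) {
      for (int m = 0; m < nsets; ++m)
        if (S[m].count(key)) hits(r, m) += 1;
    });
  }
  return hits;
}

// Place each read on the genome by its first k-mer that occurs at a
// unique position genome-wide (exact canonical match). Returns a matrix
// with columns: sequence index (1-based, NA if unplaced) and 0-based
// position of the read start estimate.
// [[Rcpp::export]]
IntegerMatrix cpp_locate_reads(CharacterVector genome, CharacterVector reads,
                               int k) {
  struct Loc { int seq; double pos; bool unique; };
  std::unordered_map<uint64_t, Loc> index;
  for (int j = 0; j < genome.size(); ++j) {
    const char* s = CHAR(STRING_ELT(genome, j));
    R_xlen_t n = LENGTH(STRING_ELT(genome, j));
    scan_kmers(s, n, k, [&](R_xlen_t pos, uint64_t key) {
      auto it = index.find(key);
      if (it == index.end())
        index[key] = {j, (double)pos, true};
      else
        it->second.unique = false;
    });
  }
  int nr = reads.size();
  IntegerMatrix out(nr, 2);
  for (int r = 0; r < nr; ++r) {
    out(r, 0) = NA_INTEGER;
    out(r, 1) = NA_INTEGER;
    const char* s = CHAR(STRING_ELT(reads, r));
    R_xlen_t n = LENGTH(STRING_ELT(reads, r));
    bool placed = false;
    scan_kmers(s, n, k, [&](R_xlen_t off, uint64_t key) {
      if (placed) return;
      auto it = index.find(key);
      if (it != index.end() && it->second.unique) {
        double start = it->second.pos - (double)off;
        if (start < 0) start = 0;
        out(r, 0) = it->second.seq + 1;
        out(r, 1) = (int)start;
        placed = true;
      }
    });
  }
  return out;
}
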