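#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline char complement_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Count k-mers across a set of sequences. Windows containing any
// non-ACGT character are skipped (and tallied). When canonical = true
// each window is stored as the lexicographic minimum of the window and
// its reverse complement.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
  if (k < 1) stop("k must be positive");
  std::unordered_map<std::string, double> tab;
  double total = 0.0, skipped = 0.0, bases = 0.0;
  std::string kmer(k, 'N'), rc(k, 'N');

  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) stop("NA sequence at index %d", (int)(i + 1));
    const char *s = CHAR(STRING_ELT(seqs, i));
    const int n = LENGTH(STRING_ELT(seqs, i));
    bases += n;
    if (n < k) continue;
    // next_valid[j]: windows starting before a non-ACGT char are skipped
    int bad_until = -1;  // last index (0-based) of a non-ACGT char seen
    for (int j = 0; j < k - 1; ++j)
      if (!is_acgt(s[j])) bad_until = j;
    for (int j = 0; j + k <= n; ++j) {
      const char last = s[j + k - 1];
      if (!is_acgt(last)) bad_until = j + k - 1;
      if (bad_until >= j) { skipped += 1.0; continue; }
      for (int t = 0; t < k; ++t) kmer[t] = s[j + t];
      if (canonical) {
        for (int t = 0; t < k; ++t) rc[t] = complement_base(kmer[k - 1 - t]);
        if (rc < kmer) tab[rc] += 1.0; else tab[kmer] += 1.0;
      } else {
        tab[kmer] += 1.0;
      }
      total += 1.0;
    }
  }

  const R_xlen_t m = (R_xlen_t)tab.size();
  CharacterVector keys(m);
  NumericVector counts(m);
  R_xlen_t idx = 0;
  for (const auto &kv : tab) {
    keys[idx] = kv.first;
    counts[idx] = kv.second;
    ++idx;
  }
  return List::create(_["kmer"] = keys, _["count"] = counts,
                      _["total_kmers"] = total, _["skipped"] = skipped,
                      _["total_bases"] = bases);
}

// Ungapped scan of each read against a consensus tile: for starts
// 1..n_pos, count mismatches of the read against tile[start..]; report
// the minimum and its leftmost start. The tile must be at least
// n_pos + read length - 1 characters.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_reads(CharacterVector reads, std::string tile, int n_pos) {
  const R_xlen_t n = reads.size();
  const int tlen = (int)tile.size();
  IntegerMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    const int r = LENGTH(STRING_ELT(reads, i));
    if (n_pos + r - 1 > tlen) stop("tile too short for read length");
    int best = r + 1, best_pos = 1;
    for (int p = 0; p < n_pos; ++p) {
      int d = 0;
      const char *w = tile.data() + p;
      for (int t = 0; t < r && d < best; ++t) d += (s[t] != w[t]);
      if (d < best) { best = d; best_pos = p + 1; }
    }
    out(i, 0) = best;
    out(i, 1) = best_pos;
  }
  return out;
}

// Hamming distances between each query k-mer (rows) and each window
// (columns). All strings must share one length.
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(CharacterVector queries, CharacterVector windows) {
  const R_xlen_t n = queries.size(), m = windows.size();
  int k = -1;
  std::vector<const char *> qs(n), ws(m);
  for (R_xlen_t i = 0; i < n; ++i) {
    qs[i] = CHAR(STRING_ELT(queries, i));
    int len = LENGTH(STRING_ELT(queries, i));
    if (k < 0) k = len;
    if (len != k) stop("all strings must have equal length");
  }
  for (R_xlen_t j = 0; j < m; ++j) {
    ws[j] = CHAR(STRING_ELT(windows, j));
    if (LENGTH(STRING_ELT(windows, j)) != k)
      stop("all strings must have equal length");
  }
  IntegerMatrix out(n, m);
  for (R_xlen_t j = 0; j < m; ++j) {
    const char *w = ws[j];
    for (R_xlen_t i = 0; i < n; ++i) {
      const char *q = qs[i];
      int d = 0;
      for (int t = 0; t < k; ++t) d += (q[t] != w[t]);
      out(i, j) = d;
    }
  }
  return out;
}
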