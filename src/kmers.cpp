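#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// k-mers are handled internally as 2-bit-packed 128-bit integers (A=0, C=1,
// G=2, T=3; first base in the most significant position), so numeric
// comparison and sorting coincide with byte-lexicographic order on the
// corresponding ACGT strings. The canonical form is min(forward, revcomp).
// Rolling updates make window scans O(1) per base.

typedef __uint128_t u128;

struct U128Hash {
  size_t operator()(const u128 &x) const {
    uint64_t lo = (uint64_t) x, hi = (uint64_t) (x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL;
    h ^= hi + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
    return (size_t) h;
  }
};

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static inline bool valid_base(char c) { return base_code(c) >= 0; }

static std::string decode_kmer(u128 x, int k) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string out(k, 'A');
  for (int j = k - 1; j >= 0; --j) {
    out[j] = B[(int) (x & 3)];
    x >>= 2;
  }
  return out;
}

// encode an exact-k ACGT string; returns false on any other character
static bool encode_kmer(const char *s, int k, u128 &out) {
  u128 v = 0;
  for (int j = 0; j < k; ++j) {
    int c = base_code(s[j]);
    if (c < 0) return false;
    v = (v << 2) | (u128) c;
  }
  out = v;
  return true;
}

static bool encode_canonical(const char *s, int k, u128 &out) {
  u128 f = 0, r = 0;
  for (int j = 0; j < k; ++j) {
    int c = base_code(s[j]);
    if (c < 0) return false;
    f = (f << 2) | (u128) c;
    r |= ((u128) (3 - c)) << (2 * j);
  }
  out = f < r ? f : r;
  return true;
}

// Rolling scanner over one sequence; calls fn(canonical, fwd) per valid
// window.
template <typename F>
static void scan_windows(const char *s, long long L, int k, F fn,
                         long long *skipped = nullptr) {
  u128 mask = (((u128) 1) << (2 * k)) - 1;
  u128 fwd = 0, rc = 0;
  int run = 0;  // valid bases accumulated
  int shift = 2 * (k - 1);
  long long emitted = 0;
  for (long long p = 0; p < L; ++p) {
    int c = base_code(s[p]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (u128) c) & mask;
    rc = (rc >> 2) | (((u128) (3 - c)) << shift);
    if (++run >= k) { fn(fwd < rc ? fwd : rc, fwd); ++emitted; }
  }
  if (skipped && L >= k) *skipped += (L - k + 1) - emitted;
}

// [[Rcpp::export]]
List canonicalize_cpp(CharacterVector kmers, int k) {
  int n = kmers.size(), skipped = 0;
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_STRING; ++skipped; continue; }
    if ((int) LENGTH(STRING_ELT(kmers, i)) != k)
      stop("k-mer %d has length %d, expected k = %d", i + 1,
           (int) LENGTH(STRING_ELT(kmers, i)), k);
    u128 can;
    if (encode_canonical(CHAR(STRING_ELT(kmers, i)), k, can))
      out[i] = decode_kmer(can, k);
    else { out[i] = NA_STRING; ++skipped; }
  }
  return List::create(_["kmers"] = out, _["n_skipped"] = skipped);
}

// collect all canonical windows into a sorted vector; counting is then a
// run-length scan (faster and more memory-predictable than hashing)
static void collect_canonical(CharacterVector seqs, int k,
                              std::vector<u128> &wins,
                              long long *skipped = nullptr) {
  long long total = 0;
  for (int i = 0; i < seqs.size(); ++i)
    if (seqs[i] != NA_STRING) total += LENGTH(STRING_ELT(seqs, i));
  wins.clear();
  wins.reserve((size_t) total);
  for (int i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    scan_windows(CHAR(STRING_ELT(seqs, i)), LENGTH(STRING_ELT(seqs, i)), k,
                 [&](u128 can, u128) { wins.push_back(can); }, skipped);
  }
  std::sort(wins.begin(), wins.end());
}

// decode a sorted vector of encodings into an R character vector
static CharacterVector decode_all(const std::vector<u128> &v, int k) {
  CharacterVector out(v.size());
  std::vector<char> buf(k);
  static const char B[4] = {'A', 'C', 'G', 'T'};
  for (size_t i = 0; i < v.size(); ++i) {
    u128 x = v[i];
    for (int j = k - 1; j >= 0; --j) { buf[j] = B[(int) (x & 3)]; x >>= 2; }
    SET_STRING_ELT(out, i, Rf_mkCharLen(buf.data(), k));
  }
  return out;
}

// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector seqs, int k, int min_count) {
  std::vector<u128> wins;
  long long skipped = 0;
  collect_canonical(seqs, k, wins, &skipped);
  std::vector<u128> keep;
  long long distinct = 0;
  size_t i = 0, n = wins.size();
  while (i < n) {
    size_t j = i;
    while (j < n && wins[j] == wins[i]) ++j;
    ++distinct;
    if ((long long) (j - i) >= min_count) keep.push_back(wins[i]);
    i = j;
  }
  return List::create(_["kmers"] = decode_all(keep, k),
                      _["n_skipped"] = (double) skipped,
                      _["n_distinct"] = (double) distinct);
}

// Presence/absence matrix straight from per-accession sequence sets, with
// the within-accession multiplicity filter and the cross-panel occupancy
// filter 2 <= c <= n - 2.
// [[Rcpp::export]]
List kmer_matrix_cpp(List seq_sets, int k, int min_count) {
  int n_acc = seq_sets.size();
  // per-accession sorted distinct member lists, then a k-way merge that
  // computes occupancy and applies the 2 <= c <= n - 2 filter on the fly
  std::vector<std::vector<u128> > members(n_acc);
  std::vector<u128> wins;
  for (int a = 0; a < n_acc; ++a) {
    collect_canonical(seq_sets[a], k, wins);
    std::vector<u128> &mem = members[a];
    size_t i = 0, n = wins.size();
    while (i < n) {
      size_t j = i;
      while (j < n && wins[j] == wins[i]) ++j;
      if ((long long) (j - i) >= min_count) mem.push_back(wins[i]);
      i = j;
    }
    mem.shrink_to_fit();
    Rcpp::checkUserInterrupt();
  }
  wins.clear(); wins.shrink_to_fit();
  std::vector<size_t> cursor(n_acc, 0);
  std::vector<u128> out_keys;
  std::vector<uint8_t> out_bits;
  std::vector<int> holders(n_acc);
  long long n_unfiltered = 0;
  const u128 NONE = ~(u128) 0;
  for (;;) {
    u128 cur = NONE;
    for (int a = 0; a < n_acc; ++a)
      if (cursor[a] < members[a].size() && members[a][cursor[a]] < cur)
        cur = members[a][cursor[a]];
    if (cur == NONE) break;
    int occ = 0;
    for (int a = 0; a < n_acc; ++a) {
      if (cursor[a] < members[a].size() && members[a][cursor[a]] == cur) {
        holders[occ++] = a;
        ++cursor[a];
      }
    }
    ++n_unfiltered;
    if (occ >= 2 && occ <= n_acc - 2) {
      out_keys.push_back(cur);
      size_t base = out_bits.size();
      out_bits.resize(base + n_acc, 0);
      for (int h = 0; h < occ; ++h) out_bits[base + holders[h]] = 1;
    }
  }
  size_t nr = out_keys.size();
  RawMatrix out_pres(nr, n_acc);
  for (size_t r = 0; r < nr; ++r)
    for (int a = 0; a < n_acc; ++a)
      out_pres(r, a) = out_bits[r * n_acc + a];
  return List::create(_["kmers"] = decode_all(out_keys, k),
                      _["presence"] = out_pres,
                      _["n_unfiltered"] = (double) n_unfiltered);
}

// [[Rcpp::export]]
IntegerVector row_occupancy_cpp(RawMatrix pres) {
  int nr = pres.nrow(), nc = pres.ncol();
  IntegerVector out(nr);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out[i] += pres(i, j);
  return out;
}

// Pearson correlation of each 0/1 row with a numeric vector y.
// [[Rcpp::export]]
NumericVector row_pearson_cpp(RawMatrix pres, NumericVector y) {
  int nr = pres.nrow(), n = pres.ncol();
  if (y.size() != n) stop("phenotype length does not match column count");
  double sy = 0, syy = 0;
  for (int j = 0; j < n; ++j) { sy += y[j]; syy += y[j] * y[j]; }
  double vy = n * syy - sy * sy;
  NumericVector out(nr);
  for (int i = 0; i < nr; ++i) {
    double sx = 0, sxy = 0;
    for (int j = 0; j < n; ++j)
      if (pres(i, j)) { sx += 1.0; sxy += y[j]; }
    double vx = n * sx - sx * sx;  // x binary: sum(x^2) == sum(x)
    if (vx <= 0 || vy <= 0) { out[i] = NA_REAL; continue; }
    out[i] = (n * sxy - sx * sy) / std::sqrt(vx * vy);
  }
  return out;
}

// X %*% M for a raw 0/1 matrix X (nr x n) and numeric M (n x p).
// [[Rcpp::export]]
NumericMatrix raw_crossprod_cpp(RawMatrix pres, NumericMatrix M) {
  int nr = pres.nrow(), n = pres.ncol(), p = M.ncol();
  if (M.nrow() != n) stop("dimension mismatch");
  NumericMatrix out(nr, p);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < n; ++j)
      if (pres(i, j))
        for (int c = 0; c < p; ++c) out(i, c) += M(j, c);
  return out;
}

// Row-wise any() over a column subset (0-based indices).
// [[Rcpp::export]]
LogicalVector rows_any_cpp(RawMatrix pres, IntegerVector cols) {
  int nr = pres.nrow();
  LogicalVector out(nr, false);
  for (int c = 0; c < cols.size(); ++c) {
    int j = cols[c];
    if (j < 0 || j >= pres.ncol()) stop("column index out of range");
    for (int i = 0; i < nr; ++i)
      if (pres(i, j)) out[i] = true;
  }
  return out;
}

// Pairwise Hamming proportion between accession columns.
// [[Rcpp::export]]
NumericMatrix column_hamming_cpp(RawMatrix pres) {
  int nr = pres.nrow(), n = pres.ncol();
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      long long diff = 0;
      for (int i = 0; i < nr; ++i)
        if (pres(i, a) != pres(i, b)) ++diff;
      double d = (double) diff / nr;
      out(a, b) = d; out(b, a) = d;
    }
  return out;
}

// Pairwise Jaccard distance between accession columns.
// [[Rcpp::export]]
NumericMatrix column_jaccard_cpp(RawMatrix pres) {
  int nr = pres.nrow(), n = pres.ncol();
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      long long inter = 0, uni = 0;
      for (int i = 0; i < nr; ++i) {
        bool x = pres(i, a), y = pres(i, b);
        if (x && y) ++inter;
        if (x || y) ++uni;
      }
      double d = uni == 0 ? 0.0 : 1.0 - (double) inter / uni;
      out(a, b) = d; out(b, a) = d;
    }
  return out;
}

// Exact placement of query k-mers on target sequences, both strands.
// [[Rcpp::export]]
DataFrame place_kmers_cpp(CharacterVector kmers, CharacterVector targets,
                          CharacterVector target_names, int k) {
  std::unordered_map<u128, std::vector<int>, U128Hash> lut;
  std::vector<u128> raw_enc(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    if ((int) LENGTH(STRING_ELT(kmers, i)) != k) stop("query length != k");
    const char *s = CHAR(STRING_ELT(kmers, i));
    u128 can, raw;
    if (!encode_canonical(s, k, can) || !encode_kmer(s, k, raw))
      stop("query k-mer %d not over ACGT", i + 1);
    raw_enc[i] = raw;
    lut[can].push_back(i);
  }
  std::vector<int> hit_kmer, hit_target, hit_pos;
  std::vector<bool> hit_fwd;
  for (int t = 0; t < targets.size(); ++t) {
    const char *s = CHAR(STRING_ELT(targets, t));
    long long L = LENGTH(STRING_ELT(targets, t));
    // position-aware rolling scan
    u128 mask = (((u128) 1) << (2 * k)) - 1;
    u128 fwd = 0, rc = 0;
    int run = 0, shift = 2 * (k - 1);
    for (long long q = 0; q < L; ++q) {
      int c = base_code(s[q]);
      if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (u128) c) & mask;
      rc = (rc >> 2) | (((u128) (3 - c)) << shift);
      if (++run < k) continue;
      u128 can = fwd < rc ? fwd : rc;
      auto it = lut.find(can);
      if (it == lut.end()) continue;
      for (int qi : it->second) {
        hit_kmer.push_back(qi);
        hit_target.push_back(t);
        hit_pos.push_back((int) (q - k + 2));  // 1-based forward-strand start
        hit_fwd.push_back(raw_enc[qi] == fwd);
      }
    }
  }
  int nh = hit_kmer.size();
  CharacterVector kq(nh), tg(nh), st(nh);
  IntegerVector ps(nh);
  for (int i = 0; i < nh; ++i) {
    kq[i] = kmers[hit_kmer[i]];
    tg[i] = target_names[hit_target[i]];
    ps[i] = hit_pos[i];
    st[i] = hit_fwd[i] ? "+" : "-";
  }
  return DataFrame::create(_["kmer"] = kq, _["target"] = tg,
                           _["position"] = ps, _["strand"] = st,
                           _["stringsAsFactors"] = false);
}

// Canonical k-mer occurrence counts over target sequences.
// [[Rcpp::export]]
List occurrence_count_cpp(CharacterVector targets, int k) {
  std::vector<u128> wins;
  collect_canonical(targets, k, wins);
  std::vector<u128> keys;
  std::vector<int> cnts;
  size_t i = 0, n = wins.size();
  while (i < n) {
    size_t j = i;
    while (j < n && wins[j] == wins[i]) ++j;
    keys.push_back(wins[i]);
    cnts.push_back((int) (j - i));
    i = j;
  }
  return List::create(_["kmers"] = decode_all(keys, k),
                      _["counts"] = wrap(cnts));
}

// Per-segment window bookkeeping for chromosome painting. A window belongs
// to the segment containing its forward-strand start (0-based half-open).
// Flag bits: 1 = usable, 2 = present in panel, 4.. = lineage-specific sets.
// [[Rcpp::export]]
IntegerMatrix paint_counts_cpp(CharacterVector chrom_seq, int k, double segment,
                               CharacterVector usable, CharacterVector present,
                               List spec_sets) {
  std::unordered_map<u128, uint32_t, U128Hash> flags;
  flags.reserve((size_t) usable.size() + present.size());
  auto add_set = [&](CharacterVector v, uint32_t bit) {
    for (int i = 0; i < v.size(); ++i) {
      u128 enc;
      if ((int) LENGTH(STRING_ELT(v, i)) != k)
        stop("set member length != k");
      if (!encode_kmer(CHAR(STRING_ELT(v, i)), k, enc))
        stop("set member not over ACGT");
      flags[enc] |= bit;
    }
  };
  add_set(usable, 1u);
  add_set(present, 2u);
  int ns = spec_sets.size();
  for (int s = 0; s < ns; ++s)
    add_set(as<CharacterVector>(spec_sets[s]), 4u << s);
  const char *seq = CHAR(STRING_ELT(chrom_seq, 0));
  long long L = LENGTH(STRING_ELT(chrom_seq, 0));
  long long n_seg = (L + (long long) segment - 1) / (long long) segment;
  IntegerMatrix out(n_seg, 3 + ns);  // n_windows, n_usable, n_usable_present, spec..
  u128 mask = (((u128) 1) << (2 * k)) - 1;
  u128 fwd = 0, rc = 0;
  int run = 0, shift = 2 * (k - 1);
  for (long long q = 0; q < L; ++q) {
    int c = base_code(seq[q]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (u128) c) & mask;
    rc = (rc >> 2) | (((u128) (3 - c)) << shift);
    if (++run < k) continue;
    long long seg = (q - k + 1) / (long long) segment;
    out(seg, 0) += 1;
    auto it = flags.find(fwd < rc ? fwd : rc);
    if (it == flags.end()) continue;
    uint32_t f = it->second;
    if (!(f & 1u)) continue;
    out(seg, 1) += 1;
    if (f & 2u) out(seg, 2) += 1;
    for (int s = 0; s < ns; ++s)
      if (f & (4u << s)) out(seg, 3 + s) += 1;
  }
  return out;
}

// Exact-match seed-and-extend alignment: all maximal exact matches >=
// seed_len between scaffolds and reference sequences, both strands,
// PAF-style rows (0-based half-open intervals). Desk-scale substitute for
// an external aligner.
// [[Rcpp::export]]
DataFrame mem_align_cpp(CharacterVector scaffolds, CharacterVector ref_seqs,
                        int seed_len) {
  std::unordered_map<std::string, std::vector<std::pair<int, long long> > > idx;
  for (int t = 0; t < ref_seqs.size(); ++t) {
    const char *r = CHAR(STRING_ELT(ref_seqs, t));
    long long L = LENGTH(STRING_ELT(ref_seqs, t));
    if (L < seed_len) stop("reference sequence shorter than seed length");
    std::string w(seed_len, 'A');
    for (long long p = 0; p + seed_len <= L; ++p) {
      bool ok = true;
      for (int j = 0; j < seed_len; ++j) {
        char c = r[p + j];
        if (!valid_base(c)) { ok = false; break; }
        w[j] = c;
      }
      if (ok) idx[w].push_back(std::make_pair(t, p));
    }
  }
  std::vector<int> q_id, t_id;
  std::vector<long long> qs, qe, ts, te, blk;
  std::vector<std::string> strand;
  for (int q = 0; q < scaffolds.size(); ++q) {
    std::string fwd(CHAR(STRING_ELT(scaffolds, q)));
    long long qlen = (long long) fwd.size();
    std::string rc(fwd.rbegin(), fwd.rend());
    for (auto &c : rc) c = comp_base(c);
    for (int strand_i = 0; strand_i < 2; ++strand_i) {
      const std::string &query = strand_i == 0 ? fwd : rc;
      std::string w(seed_len, 'A');
      for (long long p = 0; p + seed_len <= qlen; ++p) {
        bool ok = true;
        for (int j = 0; j < seed_len; ++j) {
          if (!valid_base(query[p + j])) { ok = false; break; }
          w[j] = query[p + j];
        }
        if (!ok) continue;
        auto it = idx.find(w);
        if (it == idx.end()) continue;
        for (const auto &hit : it->second) {
          int t = hit.first;
          long long tp = hit.second;
          const char *r = CHAR(STRING_ELT(ref_seqs, t));
          long long Lr = LENGTH(STRING_ELT(ref_seqs, t));
          if (p > 0 && tp > 0 && query[p - 1] == r[tp - 1] &&
              valid_base(query[p - 1])) continue;  // not leftmost seed
          long long len = seed_len;
          while (p + len < qlen && tp + len < Lr &&
                 query[p + len] == r[tp + len] && valid_base(query[p + len]))
            ++len;
          q_id.push_back(q); t_id.push_back(t);
          if (strand_i == 0) { qs.push_back(p); qe.push_back(p + len); }
          else { qs.push_back(qlen - (p + len)); qe.push_back(qlen - p); }
          ts.push_back(tp); te.push_back(tp + len); blk.push_back(len);
          strand.push_back(strand_i == 0 ? "+" : "-");
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  int nh = q_id.size();
  IntegerVector qcol(nh), tcol(nh);
  NumericVector qsv(nh), qev(nh), tsv(nh), tev(nh), blkv(nh);
  CharacterVector stv(nh);
  for (int i = 0; i < nh; ++i) {
    qcol[i] = q_id[i] + 1; tcol[i] = t_id[i] + 1;
    qsv[i] = qs[i]; qev[i] = qe[i]; tsv[i] = ts[i]; tev[i] = te[i];
    blkv[i] = blk[i]; stv[i] = strand[i];
  }
  return DataFrame::create(_["query_i"] = qcol, _["target_i"] = tcol,
                           _["qstart"] = qsv, _["qend"] = qev,
                           _["tstart"] = tsv, _["tend"] = tev,
                           _["block_len"] = blkv, _["strand"] = stv,
                           _["stringsAsFactors"] = false);
}
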