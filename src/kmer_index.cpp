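#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// 2-bit DNA k-mer index shared by the SD detector, the gene-copy mapper and
// the transcript screen. k is capped at 31 so a k-mer fits in 62 bits.

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Sorted-array k-mer index: parallel arrays (keys sorted ascending, with
// sequence/position payloads) queried by binary search.  Far more compact
// than a hash map, which matters when one index per haplotype assembly is
// built in a cohort loop.
struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<int> lens;
  std::vector<uint64_t> keys;
  std::vector<int32_t> seq;
  std::vector<int32_t> pos;
};

// mark k-mer start positions overlapping a masked interval
static std::vector<char> mask_starts(int len, int k, SEXP mask_sexp) {
  std::vector<char> skip((size_t)std::max(len - k + 1, 0), 0);
  if (Rf_isNull(mask_sexp)) return skip;
  IntegerMatrix m(mask_sexp);
  for (int i = 0; i < m.nrow(); ++i) {
    int s = m(i, 0), e = m(i, 1);  // 0-based half-open
    int lo = std::max(0, s - k + 1);
    int hi = std::min((int)skip.size(), e);
    for (int p = lo; p < hi; ++p) skip[p] = 1;
  }
  return skip;
}

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector seqs, int k, List mask) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  size_t total = 0;
  for (int si = 0; si < seqs.size(); ++si) total += LENGTH(STRING_ELT(seqs, si));
  uint64_t kmask = (k == 31) ? ((~0ULL) >> 2) : ((1ULL << (2 * k)) - 1);
  std::vector<std::pair<uint64_t, uint64_t>> ents;  // (key, seq<<32 | pos)
  ents.reserve(total);
  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    idx->names.push_back(seqs.hasAttribute("names")
                             ? as<std::string>(as<CharacterVector>(seqs.names())[si])
                             : std::to_string(si + 1));
    idx->lens.push_back((int)s.size());
    std::vector<char> skip = mask_starts((int)s.size(), k,
                                         mask.size() > si ? (SEXP)mask[si] : R_NilValue);
    uint64_t val = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)b) & kmask;
      if (++run >= k) {
        int start = i - k + 1;
        if (!skip.empty() && skip[start]) continue;
        ents.emplace_back(val, ((uint64_t)si << 32) | (uint64_t)start);
      }
    }
  }
  std::sort(ents.begin(), ents.end());
  idx->keys.resize(ents.size());
  idx->seq.resize(ents.size());
  idx->pos.resize(ents.size());
  for (size_t i = 0; i < ents.size(); ++i) {
    idx->keys[i] = ents[i].first;
    idx->seq[i] = (int32_t)(ents[i].second >> 32);
    idx->pos[i] = (int32_t)(ents[i].second & 0xFFFFFFFFULL);
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export(name = ".kmer_index_info")]]
List kmer_index_info(SEXP xp) {
  XPtr<KmerIndex> p(xp);
  return List::create(_["k"] = p->k,
                      _["names"] = wrap(p->names),
                      _["lengths"] = wrap(p->lens),
                      _["n_kmers"] = (double)p->keys.size());
}

// Query sequences against the index. Positions are 0-based k-mer starts.
// strand +1: query window matches target window directly;
// strand -1: reverse complement of the query window matches the target window.
// In self mode the query set is assumed identical to the indexed set and each
// unordered locus pair is emitted once, with self and near-diagonal hits
// suppressed.
// [[Rcpp::export(name = ".kmer_index_query")]]
DataFrame kmer_index_query(SEXP xp, CharacterVector qseqs, bool self_mode,
                           int min_sep, int max_occ, double max_hits) {
  XPtr<KmerIndex> p(xp);
  const int k = p->k;
  uint64_t kmask = (k == 31) ? ((~0ULL) >> 2) : ((1ULL << (2 * k)) - 1);
  std::vector<int> Q, QP, T, TP, S;
  for (int qi = 0; qi < qseqs.size(); ++qi) {
    std::string s = as<std::string>(qseqs[qi]);
    uint64_t fval = 0, rval = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; fval = 0; rval = 0; continue; }
      fval = ((fval << 2) | (uint64_t)b) & kmask;
      rval = (rval >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      if (++run < k) continue;
      int qpos = i - k + 1;
      for (int strand = 0; strand < 2; ++strand) {
        uint64_t key = strand == 0 ? fval : rval;
        auto lo = std::lower_bound(p->keys.begin(), p->keys.end(), key);
        if (lo == p->keys.end() || *lo != key) continue;
        size_t i0 = (size_t)(lo - p->keys.begin());
        size_t i1 = i0;
        while (i1 < p->keys.size() && p->keys[i1] == key) ++i1;
        if ((int)(i1 - i0) > max_occ) continue;
        for (size_t hi2 = i0; hi2 < i1; ++hi2) {
          int ti = p->seq[hi2], tpos = p->pos[hi2];
          if (self_mode) {
            if (ti < qi) continue;
            if (ti == qi) {
              if (strand == 0 && tpos - qpos < min_sep) continue;
              if (strand == 1 && tpos <= qpos) continue;
            }
          }
          Q.push_back(qi + 1); QP.push_back(qpos);
          T.push_back(ti + 1); TP.push_back(tpos);
          S.push_back(strand == 0 ? 1 : -1);
        }
      }
      if ((double)Q.size() > max_hits)
        stop("seed match count exceeded max_hits (%g); raise kmer_size or mask repeats",
             max_hits);
    }
  }
  return DataFrame::create(_["qseq"] = Q, _["qpos"] = QP, _["tseq"] = T,
                           _["tpos"] = TP, _["strand"] = S);
}

// Self-alignment seed pass: canonical k-mers (min of forward and reverse
// complement) are collected for every unmasked position, sorted, and
// duplicate groups emit locus pairs.  Matching strand-bit means a direct
// match, differing bits an inverted one, so one sort yields both
// orientations without a hash table.
struct CanonEntry {
  uint64_t canon;
  int32_t seq;   // (seq index << 1) | strand bit
  int32_t pos;
};

// [[Rcpp::export(name = ".self_seed_pairs")]]
DataFrame self_seed_pairs(CharacterVector seqs, int k, List mask, int min_sep,
                          int max_occ, double max_hits) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  uint64_t kmask = (k == 31) ? ((~0ULL) >> 2) : ((1ULL << (2 * k)) - 1);
  std::vector<CanonEntry> ents;
  size_t total = 0;
  for (int si = 0; si < seqs.size(); ++si) total += LENGTH(STRING_ELT(seqs, si));
  ents.reserve(total);
  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    std::vector<char> skip = mask_starts((int)s.size(), k,
                                         mask.size() > si ? (SEXP)mask[si] : R_NilValue);
    uint64_t fval = 0, rval = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; fval = 0; rval = 0; continue; }
      fval = ((fval << 2) | (uint64_t)b) & kmask;
      rval = (rval >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      if (++run < k) continue;
      int start = i - k + 1;
      if (!skip.empty() && skip[start]) continue;
      bool fwd_min = fval <= rval;
      CanonEntry e;
      e.canon = fwd_min ? fval : rval;
      e.seq = (si << 1) | (fwd_min ? 0 : 1);
      e.pos = start;
      ents.push_back(e);
    }
  }
  std::sort(ents.begin(), ents.end(), [](const CanonEntry& a, const CanonEntry& b) {
    if (a.canon != b.canon) return a.canon < b.canon;
    if ((a.seq >> 1) != (b.seq >> 1)) return (a.seq >> 1) < (b.seq >> 1);
    return a.pos < b.pos;
  });
  std::vector<int> Q, QP, T, TP, S;
  size_t n = ents.size();
  size_t g0 = 0;
  while (g0 < n) {
    size_t g1 = g0 + 1;
    while (g1 < n && ents[g1].canon == ents[g0].canon) ++g1;
    if ((int)(g1 - g0) <= max_occ) {
      for (size_t i = g0; i < g1; ++i) {
        for (size_t j = i + 1; j < g1; ++j) {
          int si = ents[i].seq >> 1, sj = ents[j].seq >> 1;
          int strand = ((ents[i].seq ^ ents[j].seq) & 1) ? -1 : 1;
          if (si == sj) {
            if (strand == 1 && ents[j].pos - ents[i].pos < min_sep) continue;
            if (strand == -1 && ents[j].pos <= ents[i].pos) continue;
          }
          Q.push_back(si + 1); QP.push_back(ents[i].pos);
          T.push_back(sj + 1); TP.push_back(ents[j].pos);
          S.push_back(strand);
        }
      }
      if ((double)Q.size() > max_hits)
        stop("seed match count exceeded max_hits (%g); raise kmer_size or mask repeats",
             max_hits);
    }
    g0 = g1;
  }
  return DataFrame::create(_["qseq"] = Q, _["qpos"] = QP, _["tseq"] = T,
                           _["tpos"] = TP, _["strand"] = S);
}

// Genome-wide occurrence count of the k-mer starting at every position
// (0 marks positions whose k-mer contains a non-ACGT base or runs off the
// end).  Uses a 64-bit polynomial rolling hash so k may exceed 32; hash
// collisions are vanishingly rare at genome scales well beyond this
// package's use.
static const uint64_t HM = 0x9E3779B97F4A7C15ULL;  // odd multiplier

// [[Rcpp::export(name = ".kmer_multiplicity")]]
List kmer_multiplicity(CharacterVector seqs, int k) {
  if (k < 4 || k > 1000) stop("k must be in [4, 1000]");
  uint64_t mpow = 1;  // HM^(k-1): coefficient of the window's leading base
  for (int i = 0; i < k - 1; ++i) mpow *= HM;
  std::unordered_map<uint64_t, int> counts;
  std::vector<std::string> ss(seqs.size());
  for (int si = 0; si < seqs.size(); ++si) {
    ss[si] = as<std::string>(seqs[si]);
    const std::string& s = ss[si];
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      if (run >= k) h -= (uint64_t)(base2bit(s[i - k]) + 1) * mpow;
      h = h * HM + (uint64_t)(b + 1);
      if (++run >= k) counts[h]++;
    }
  }
  List out(seqs.size());
  for (int si = 0; si < seqs.size(); ++si) {
    const std::string& s = ss[si];
    int n = std::max((int)s.size() - k + 1, 0);
    IntegerVector cv(n, 0);
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      if (run >= k) h -= (uint64_t)(base2bit(s[i - k]) + 1) * mpow;
      h = h * HM + (uint64_t)(b + 1);
      if (++run >= k) cv[i - k + 1] = counts[h];
    }
    out[si] = cv;
  }
  out.names() = seqs.hasAttribute("names") ? (SEXP)seqs.names() : R_NilValue;
  return out;
}
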