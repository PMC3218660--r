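#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Exact matcher for tiled fusion-junction libraries.
//
// An element of the library is tileX ++ tileY (tile length L), X upstream.
// A read of length rl (> L) aligned to an element at offset o always crosses
// the junction, splitting into a prefix of s = L - o bases that must match a
// window ending at the tileX right edge and a suffix of rl - s bases that
// must match a window starting at the tileY left edge, with a total mismatch
// budget mm. Enumerating the split s in [rl - L, L] and matching prefix and
// suffix independently against the two regions is therefore exhaustive: it
// reports exactly the hits a brute-force scan over all materialised elements
// would.
//
// A read with <= mm mismatches against some element must contain an exact
// run of seed_len bases lying wholly within one region window (seed_len is
// the worst-case guaranteed run length, computed in R), so reads sharing no
// seed_len-mer with either region are screened out up front.

static inline uint64_t encode_kmer(const int *x, int k, bool &ok) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    if (x[i] < 0 || x[i] > 3) { ok = false; return 0; }
    v = (v << 2) | (uint64_t)x[i];
  }
  ok = true;
  return v;
}

static void add_region_kmers(const IntegerVector &reg, int k,
                             std::unordered_set<uint64_t> &set) {
  int n = reg.size();
  for (int i = 0; i + k <= n; ++i) {
    bool ok;
    uint64_t v = encode_kmer(&reg[i], k, ok);
    if (ok) set.insert(v);
  }
}

static bool read_passes_screen(const int *read, int rl, int k,
                               const std::unordered_set<uint64_t> &set) {
  for (int i = 0; i + k <= rl; ++i) {
    bool ok;
    uint64_t v = encode_kmer(read + i, k, ok);
    if (ok && set.count(v)) return true;
  }
  return false;
}

struct PartHit { int pos; int mm; }; // pos: tile index (0-based)

// prefix hits: for split s, windows of region ending at e with <= mm
// mismatches against read[0..s-1]; tile index a = e - L + 1
static void prefix_hits(const int *read, const int *reg, int nreg, int L,
                        int rl, int mm, int smin, int smax,
                        std::vector<std::vector<PartHit> > &out) {
  // out indexed by s - smin
  for (int d = 0; d <= nreg - smin; ++d) {
    int cum = 0;
    int jmax = std::min(smax, nreg - d);
    for (int j = 0; j < jmax; ++j) {
      int rb = read[j], gb = reg[d + j];
      if (rb < 0 || gb < 0 || rb != gb) ++cum;
      if (cum > mm) break;
      int s = j + 1;
      if (s >= smin) {
        int a = d + s - L; // 0-based tile start
        if (a >= 0 && a + L <= nreg)
          out[s - smin].push_back(PartHit{a, cum});
      }
    }
  }
}

// suffix hits: for split s, windows of region starting at b with <= mm
// mismatches against read[s..rl-1]; b is the tile index directly.
// Scans each diagonal d = b - s backwards from the read's last base,
// accumulating mismatches; the count is monotone as the window grows
// leftwards, so the walk stops once the budget is exhausted.
static void suffix_hits(const int *read, const int *reg, int nreg, int L,
                        int rl, int mm, int smin, int smax,
                        std::vector<std::vector<PartHit> > &out) {
  int dmin = -smax;              // b = d + s >= 0 for some s <= smax
  int dmax = nreg - rl;          // suffix always ends at read[rl-1] -> reg[d+rl-1]
  for (int d = dmin; d <= dmax; ++d) {
    int cum = 0;
    int jstop = std::max(smin, -d);
    for (int j = rl - 1; j >= jstop; --j) {
      int rb = read[j], gb = reg[d + j];
      if (rb < 0 || gb < 0 || rb != gb) {
        if (++cum > mm) break;
      }
      if (j >= smin && j <= smax) {
        int b = d + j; // suffix starts at read[j] aligned to reg[b]
        if (b >= 0 && b + L <= nreg)
          out[j - smin].push_back(PartHit{b, cum});
      }
    }
  }
}

// Ungapped local-similarity: for each read, the maximum number of matching
// nucleotides over all ungapped alignments (diagonals, partial overlaps
// included) against the subject, on either strand. A read is similar when
// this count reaches the identity fraction of its length.
// [[Rcpp::export]]
IntegerVector cpp_local_match_count(IntegerVector subject,
                                    IntegerMatrix reads_fwd,
                                    IntegerMatrix reads_rc) {
  int n = reads_fwd.nrow(), rl = reads_fwd.ncol(), ns = subject.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    int best = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const IntegerMatrix &m = strand == 0 ? reads_fwd : reads_rc;
      for (int d = -(rl - 1); d < ns; ++d) {
        int jlo = d < 0 ? -d : 0;
        int jhi = std::min(rl, ns - d);
        if (jhi - jlo <= best) continue; // cannot beat the current best
        int c = 0;
        for (int j = jlo; j < jhi; ++j) {
          int rb = m(r, j), gb = subject[d + j];
          if (rb >= 0 && rb == gb) ++c;
        }
        if (c > best) best = c;
      }
    }
    out[r] = best;
  }
  return out;
}

// Does each read (or its given reverse complement) match anywhere in the
// subject end-to-end with at most max_mm substitutions? Exhaustive diagonal
// scan with early exit; same contract as a brute-force window comparison.
// [[Rcpp::export]]
LogicalVector cpp_kmismatch_any(IntegerVector subject, IntegerMatrix reads_fwd,
                                IntegerMatrix reads_rc, int max_mm) {
  int n = reads_fwd.nrow(), rl = reads_fwd.ncol(), ns = subject.size();
  LogicalVector out(n);
  for (int r = 0; r < n; ++r) {
    bool hit = false;
    for (int strand = 0; strand < 2 && !hit; ++strand) {
      const IntegerMatrix &m = strand == 0 ? reads_fwd : reads_rc;
      for (int d = 0; d + rl <= ns && !hit; ++d) {
        int c = 0;
        int j = 0;
        for (; j < rl; ++j) {
          int rb = m(r, j), gb = subject[d + j];
          if (rb < 0 || gb < 0 || rb != gb) {
            if (++c > max_mm) break;
          }
        }
        if (j == rl) hit = true;
      }
    }
    out[r] = hit;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_junction_align(IntegerVector region_a, IntegerVector region_b,
                             IntegerMatrix reads_fwd, IntegerMatrix reads_rc,
                             int tile_len, int max_mismatches, int seed_len) {
  int rl = reads_fwd.ncol();
  int n_reads = reads_fwd.nrow();
  int L = tile_len;
  int smin = rl - L, smax = L;
  if (smin < 1) smin = 1;
  if (smax > rl - 1) smax = rl - 1;
  int ns = smax - smin + 1;

  std::unordered_set<uint64_t> kmers;
  add_region_kmers(region_a, seed_len, kmers);
  add_region_kmers(region_b, seed_len, kmers);

  std::vector<int> o_read, o_orient, o_tile_a, o_tile_b, o_offset, o_mm, o_strand;

  std::vector<std::vector<PartHit> > preA(ns), preB(ns), sufA(ns), sufB(ns);
  std::vector<int> rbuf(rl);

  for (int r = 0; r < n_reads; ++r) {
    for (int strand = 0; strand < 2; ++strand) {
      const IntegerMatrix &m = strand == 0 ? reads_fwd : reads_rc;
      for (int j = 0; j < rl; ++j) rbuf[j] = m(r, j);
      if (!read_passes_screen(rbuf.data(), rl, seed_len, kmers)) continue;

      for (int s = 0; s < ns; ++s) {
        preA[s].clear(); preB[s].clear(); sufA[s].clear(); sufB[s].clear();
      }
      prefix_hits(rbuf.data(), &region_a[0], region_a.size(), L, rl,
                  max_mismatches, smin, smax, preA);
      prefix_hits(rbuf.data(), &region_b[0], region_b.size(), L, rl,
                  max_mismatches, smin, smax, preB);
      suffix_hits(rbuf.data(), &region_a[0], region_a.size(), L, rl,
                  max_mismatches, smin, smax, sufA);
      suffix_hits(rbuf.data(), &region_b[0], region_b.size(), L, rl,
                  max_mismatches, smin, smax, sufB);

      for (int si = 0; si < ns; ++si) {
        int s = smin + si;
        int offset = L - s;
        // orientation AB: prefix in A, suffix in B
        for (size_t i = 0; i < preA[si].size(); ++i) {
          for (size_t j = 0; j < sufB[si].size(); ++j) {
            int tot = preA[si][i].mm + sufB[si][j].mm;
            if (tot <= max_mismatches) {
              o_read.push_back(r + 1);
              o_orient.push_back(0);
              o_tile_a.push_back(preA[si][i].pos + 1);
              o_tile_b.push_back(sufB[si][j].pos + 1);
              o_offset.push_back(offset);
              o_mm.push_back(tot);
              o_strand.push_back(strand);
            }
          }
        }
        // orientation BA: prefix in B, suffix in A
        for (size_t i = 0; i < preB[si].size(); ++i) {
          for (size_t j = 0; j < sufA[si].size(); ++j) {
            int tot = preB[si][i].mm + sufA[si][j].mm;
            if (tot <= max_mismatches) {
              o_read.push_back(r + 1);
              o_orient.push_back(1);
              o_tile_b.push_back(preB[si][i].pos + 1);
              o_tile_a.push_back(sufA[si][j].pos + 1);
              o_offset.push_back(offset);
              o_mm.push_back(tot);
              o_strand.push_back(strand);
            }
          }
        }
      }
    }
  }

  return DataFrame::create(
    _["read"] = o_read, _["orient"] = o_orient,
    _["tile_a"] = o_tile_a, _["tile_b"] = o_tile_b,
    _["offset"] = o_offset, _["mismatches"] = o_mm,
    _["strand"] = o_strand);
}
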