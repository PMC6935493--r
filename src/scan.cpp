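#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// 'N' never matches anything, including another 'N'.
static inline bool base_eq(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

// Mismatches between q and g over len bases, early-exiting past cap. The
// first block is counted branchlessly: at a random offset it accumulates
// ~0.75 * block mismatches, so nearly all positions are rejected without a
// data-dependent branch per base.
static inline int mismatches_capped(const char* q, const char* g, int len,
                                    int cap) {
  int blk = len < 16 ? len : 16;
  int mm = 0;
  for (int i = 0; i < blk; ++i) mm += !base_eq(q[i], g[i]);
  if (mm > cap) return mm;
  for (int i = blk; i < len; ++i) {
    if (!base_eq(q[i], g[i])) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': out[i] = 'T'; break;
      case 'C': out[i] = 'G'; break;
      case 'G': out[i] = 'C'; break;
      case 'T': out[i] = 'A'; break;
      case 'a': out[i] = 't'; break;
      case 'c': out[i] = 'g'; break;
      case 'g': out[i] = 'c'; break;
      case 't': out[i] = 'a'; break;
      default:  out[i] = 'N';
    }
  }
  return out;
}

// Exhaustive candidate search for the micro-aligner: every position of every
// chromosome, both strands, mismatch-only scoring with early exit past max_mm.
// Returns one row per candidate: read (1-based), chrom (1-based), start
// (0-based on the forward reference), strand ("+" / "-"), mm.
// [[Rcpp::export]]
DataFrame cpp_scan_reads(CharacterVector reads, CharacterVector chroms,
                         int max_mm) {
  std::vector<int> out_read, out_chrom, out_start, out_mm;
  std::vector<int> out_strand; // 0 = plus, 1 = minus

  std::vector<std::string> refs(chroms.size());
  for (int c = 0; c < chroms.size(); ++c) refs[c] = as<std::string>(chroms[c]);

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    int L = (int)fwd.size();
    for (int c = 0; c < (int)refs.size(); ++c) {
      const std::string& ref = refs[c];
      int n = (int)ref.size();
      if (L > n) continue;
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& q = strand == 0 ? fwd : rev;
        const char* qp = q.c_str();
        const char* rp = ref.c_str();
        for (int p = 0; p + L <= n; ++p) {
          int mm = mismatches_capped(qp, rp + p, L, max_mm);
          if (mm <= max_mm) {
            out_read.push_back(r + 1);
            out_chrom.push_back(c + 1);
            out_start.push_back(p);
            out_strand.push_back(strand);
            out_mm.push_back(mm);
          }
        }
      }
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(
    _["read"] = out_read, _["chrom"] = out_chrom, _["start"] = out_start,
    _["strand_minus"] = out_strand, _["mm"] = out_mm);
}

// Mappability oracle helper, written independently of cpp_scan_reads: for each
// query window (chrom index + 0-based start, fixed length), count genome
// positions on either strand matching with <= k mismatches. Counting stops at
// `cap` hits (the unique-fraction computation only needs to distinguish 1 from
// >= 2), so the returned value is min(true count, cap).
// [[Rcpp::export]]
IntegerVector cpp_window_hit_counts(CharacterVector chroms,
                                    IntegerVector win_chrom,
                                    IntegerVector win_start,
                                    int read_len, int k, int cap) {
  std::vector<std::string> refs(chroms.size());
  std::vector<std::string> refs_rc(chroms.size());
  for (int c = 0; c < chroms.size(); ++c) {
    refs[c] = as<std::string>(chroms[c]);
    refs_rc[c] = revcomp(refs[c]);
  }
  int nw = win_chrom.size();
  IntegerVector counts(nw);

  for (int w = 0; w < nw; ++w) {
    int wc = win_chrom[w] - 1;
    int ws = win_start[w];
    const char* query = refs[wc].c_str() + ws;
    int hits = 0;
    for (int c = 0; c < (int)refs.size() && hits < cap; ++c) {
      for (int pass = 0; pass < 2 && hits < cap; ++pass) {
        const std::string& ref = pass == 0 ? refs[c] : refs_rc[c];
        int n = (int)ref.size();
        const char* rp = ref.c_str();
        for (int p = 0; p + read_len <= n; ++p) {
          int blk = read_len < 16 ? read_len : 16;
          int mm = 0;
          for (int i = 0; i < blk; ++i) mm += !base_eq(query[i], rp[p + i]);
          if (mm > k) continue;
          for (int i = blk; i < read_len && mm <= k; ++i) {
            mm += !base_eq(query[i], rp[p + i]);
          }
          if (mm <= k) {
            ++hits;
            if (hits >= cap) break;
          }
        }
      }
    }
    counts[w] = hits;
    if (w % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
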