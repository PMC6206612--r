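#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Pair merging. The reverse read is reverse-complemented by the caller; here
// `f` and `rc` are both in forward orientation. Two geometries are scanned:
//   normal  (insert >= read length): f suffix overlaps rc prefix;
//           merged = f + non-overlapping tail of rc.
//   readthrough (insert < read length): rc suffix overlaps f prefix;
//           merged = overlap region only (overhangs clipped).
// The overlap maximizing the match count wins; ties go to the longer
// overlap, then to the normal geometry. 'N' never counts as a match.

static inline bool base_match(char x, char y) {
  return x == y && x != 'N';
}

struct Overlap { int len; int matches; int mismatches; bool readthrough; };

static bool scan_overlaps(const std::string& f, const std::string& rc,
                          int min_overlap, double max_mm_rate, Overlap& best) {
  int lf = f.size(), lr = rc.size();
  int maxo = std::min(lf, lr);
  bool have = false;
  for (int o = min_overlap; o <= maxo; ++o) {
    // normal: f[lf-o .. lf-1] vs rc[0 .. o-1]
    int mm = 0, mt = 0;
    for (int k = 0; k < o; ++k) {
      if (base_match(f[lf - o + k], rc[k])) ++mt; else ++mm;
    }
    if ((double)mm / o <= max_mm_rate) {
      if (!have || mt > best.matches ||
          (mt == best.matches && (o > best.len || (o == best.len && best.readthrough)))) {
        best.len = o; best.matches = mt; best.mismatches = mm; best.readthrough = false;
        have = true;
      }
    }
    if (o < maxo) {  // readthrough with o == maxo coincides with normal full overlap
      // readthrough: rc[lr-o .. lr-1] vs f[0 .. o-1]
      mm = 0; mt = 0;
      for (int k = 0; k < o; ++k) {
        if (base_match(rc[lr - o + k], f[k])) ++mt; else ++mm;
      }
      if ((double)mm / o <= max_mm_rate) {
        if (!have || mt > best.matches || (mt == best.matches && o > best.len)) {
          best.len = o; best.matches = mt; best.mismatches = mm; best.readthrough = true;
          have = true;
        }
      }
    }
  }
  return have;
}

// [[Rcpp::export(name = ".find_overlap_cpp")]]
List find_overlap_cpp(std::string f, std::string rc,
                      int min_overlap, double max_mm_rate) {
  Overlap best;
  if (!scan_overlaps(f, rc, min_overlap, max_mm_rate, best))
    return List::create(_["overlap"] = IntegerVector::get_na());
  return List::create(_["overlap"] = best.len,
                      _["matches"] = best.matches,
                      _["mismatches"] = best.mismatches,
                      _["readthrough"] = best.readthrough);
}

// Consensus rules in the overlap: agreement keeps the base with quality
// min(q1+q2, cap); disagreement keeps the higher-quality base with quality
// |q1-q2| (ties: forward base, quality 2). An N never wins a disagreement.
// Outside the overlap bases/qualities are copied from their source read.
// Qualities are Phred+33 characters.

// [[Rcpp::export(name = ".merge_pair_cpp")]]
List merge_pair_cpp(std::string f, std::string fq,
                    std::string rc, std::string rq,
                    int min_overlap, double max_mm_rate, int quality_cap) {
  Overlap best;
  if (!scan_overlaps(f, rc, min_overlap, max_mm_rate, best))
    return List::create(_["merged"] = R_NilValue);
  int lf = f.size(), lr = rc.size(), o = best.len;
  std::string seq, qual;
  int fpos0;  // position in f where the overlap starts
  if (!best.readthrough) {
    fpos0 = lf - o;
    seq = f.substr(0, fpos0);
    qual = fq.substr(0, fpos0);
  } else {
    fpos0 = 0;
    seq.clear(); qual.clear();
  }
  int rpos0 = best.readthrough ? (lr - o) : 0;
  for (int k = 0; k < o; ++k) {
    char xb = f[fpos0 + k], yb = rc[rpos0 + k];
    int xq = (int)fq[fpos0 + k] - 33, yq = (int)rq[rpos0 + k] - 33;
    char cb; int cq;
    if (xb == yb) {
      cb = xb;
      cq = std::min(xq + yq, quality_cap);
    } else if (xb == 'N') {
      cb = yb; cq = yq;
    } else if (yb == 'N') {
      cb = xb; cq = xq;
    } else if (xq > yq) {
      cb = xb; cq = xq - yq;
    } else if (yq > xq) {
      cb = yb; cq = yq - xq;
    } else {
      cb = xb; cq = 2;
    }
    seq.push_back(cb);
    qual.push_back((char)(cq + 33));
  }
  if (!best.readthrough && o < lr) {
    seq += rc.substr(o);
    qual += rq.substr(o);
  }
  return List::create(_["merged"] = seq, _["qual"] = qual,
                      _["overlap"] = o, _["readthrough"] = best.readthrough,
                      _["mismatches"] = best.mismatches);
}
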