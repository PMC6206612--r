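#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh). Gap convention: the FIRST gap base
// costs `gap_open`, each subsequent base of the same gap costs `gap_extend`.
// Traceback tie-break: diagonal (match/mismatch) > gap-in-a > gap-in-b.

static const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  std::string a_aln;
  std::string b_aln;
};

static inline double subst(char x, char y, double match, double mismatch) {
  // N never counts as a match
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

static AlnResult align_affine(const std::string& a, const std::string& b,
                              double match, double mismatch,
                              double gap_open, double gap_extend,
                              bool traceback) {
  const int n = a.size(), m = b.size();
  // layers: 0 = M (diagonal), 1 = Ia (gap in a, consumes b), 2 = Ib (gap in b, consumes a)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ia((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ib((n + 1) * (m + 1), NEG_INF);
  // backpointer: layer of predecessor, encoded 0/1/2, 3 = none
  std::vector<unsigned char> bpM, bpIa, bpIb;
  if (traceback) {
    bpM.assign((n + 1) * (m + 1), 3);
    bpIa.assign((n + 1) * (m + 1), 3);
    bpIb.assign((n + 1) * (m + 1), 3);
  }
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Ia[idx(0, j)] = gap_open + (j - 1) * gap_extend;
    if (traceback) bpIa[idx(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    Ib[idx(i, 0)] = gap_open + (i - 1) * gap_extend;
    if (traceback) bpIb[idx(i, 0)] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume a[i-1], b[j-1]; predecessor preference M > Ia > Ib on ties
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double best = M[idx(i - 1, j - 1)];
      unsigned char bp = 0;
      if (Ia[idx(i - 1, j - 1)] > best) { best = Ia[idx(i - 1, j - 1)]; bp = 1; }
      if (Ib[idx(i - 1, j - 1)] > best) { best = Ib[idx(i - 1, j - 1)]; bp = 2; }
      M[idx(i, j)] = best + s;
      if (traceback) bpM[idx(i, j)] = bp;

      // Ia: gap in a, consumes b[j-1]
      double open_from_M = M[idx(i, j - 1)] + gap_open;
      double open_from_Ib = Ib[idx(i, j - 1)] + gap_open;
      double ext = Ia[idx(i, j - 1)] + gap_extend;
      best = open_from_M; bp = 0;
      if (ext > best) { best = ext; bp = 1; }
      if (open_from_Ib > best) { best = open_from_Ib; bp = 2; }
      Ia[idx(i, j)] = best;
      if (traceback) bpIa[idx(i, j)] = bp;

      // Ib: gap in b, consumes a[i-1]
      open_from_M = M[idx(i - 1, j)] + gap_open;
      double open_from_Ia = Ia[idx(i - 1, j)] + gap_open;
      ext = Ib[idx(i - 1, j)] + gap_extend;
      best = open_from_M; bp = 0;
      if (open_from_Ia > best) { best = open_from_Ia; bp = 1; }
      if (ext > best) { best = ext; bp = 2; }
      Ib[idx(i, j)] = best;
      if (traceback) bpIb[idx(i, j)] = bp;
    }
  }

  AlnResult res;
  int layer = 0;
  res.score = M[idx(n, m)];
  if (Ia[idx(n, m)] > res.score) { res.score = Ia[idx(n, m)]; layer = 1; }
  if (Ib[idx(n, m)] > res.score) { res.score = Ib[idx(n, m)]; layer = 2; }

  if (traceback) {
    std::string ra, rb;
    int i = n, j = m;
    while (i > 0 || j > 0) {
      unsigned char bp;
      if (layer == 0) {
        bp = bpM[idx(i, j)];
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
        --i; --j;
      } else if (layer == 1) {
        bp = bpIa[idx(i, j)];
        ra.push_back('-'); rb.push_back(b[j - 1]);
        --j;
      } else {
        bp = bpIb[idx(i, j)];
        ra.push_back(a[i - 1]); rb.push_back('-');
        --i;
      }
      layer = bp;
    }
    res.a_aln.assign(ra.rbegin(), ra.rend());
    res.b_aln.assign(rb.rbegin(), rb.rend());
  }
  return res;
}

// [[Rcpp::export(name = ".global_align_cpp")]]
List global_align_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  AlnResult r = align_affine(a, b, match, mismatch, gap_open, gap_extend, true);
  return List::create(_["score"] = r.score,
                      _["a_aln"] = r.a_aln,
                      _["b_aln"] = r.b_aln);
}

// [[Rcpp::export(name = ".align_score_cpp")]]
double align_score_cpp(std::string a, std::string b,
                       double match, double mismatch,
                       double gap_open, double gap_extend) {
  return align_affine(a, b, match, mismatch, gap_open, gap_extend, false).score;
}

static double identity_of(const std::string& a, const std::string& b,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
  AlnResult r = align_affine(a, b, match, mismatch, gap_open, gap_extend, true);
  int cols = r.a_aln.size(), matches = 0;
  for (int k = 0; k < cols; ++k) {
    char x = r.a_aln[k], y = r.b_aln[k];
    if (x == y && x != '-' && x != 'N') ++matches;
  }
  return cols ? (double)matches / cols : 0.0;
}

// [[Rcpp::export(name = ".pairwise_identity_cpp")]]
double pairwise_identity_cpp(std::string a, std::string b,
                             double match, double mismatch,
                             double gap_open, double gap_extend) {
  return identity_of(a, b, match, mismatch, gap_open, gap_extend);
}

// ---- greedy centroid clustering -------------------------------------------
// Sequences arrive sorted (descending abundance); each sequence joins the
// first earlier-founded cluster whose representative is within `threshold`
// identity, else founds a new cluster. A shared-k-mer count lower bound
// screens representatives before the full alignment; the bound is lossless:
// an alignment at identity >= t has at most (1-t)*(la+lb) non-match columns,
// each destroying at most k of a's (la-k+1) k-mer windows.

static void kmer_list(const std::string& s, int k, std::vector<uint32_t>& out) {
  out.clear();
  int n = s.size();
  if (n < k) return;
  for (int i = 0; i + k <= n; ++i) {
    uint32_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c;
      switch (s[i + j]) {
        case 'A': c = 0; break; case 'C': c = 1; break;
        case 'G': c = 2; break; case 'T': c = 3; break;
        default: c = -1;
      }
      if (c < 0) { ok = false; break; }
      code = (code << 2) | (uint32_t)c;
    }
    if (ok) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
}

static int shared_kmers(const std::vector<uint32_t>& x, const std::vector<uint32_t>& y) {
  size_t i = 0, j = 0; int n = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] == y[j]) { ++n; ++i; ++j; }
    else if (x[i] < y[j]) ++i;
    else ++j;
  }
  return n;
}

// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold,
                                 double match, double mismatch,
                                 double gap_open, double gap_extend,
                                 int kmer_k, bool use_prefilter) {
  int n = seqs.size();
  IntegerVector assign(n);  // 1-based cluster index
  std::vector<int> rep_idx;                 // input index of each representative
  std::vector<std::vector<uint32_t> > rep_kmers;
  std::vector<std::string> rep_seq;

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<uint32_t> km;
    if (use_prefilter) kmer_list(s, kmer_k, km);
    int found = -1;
    for (size_t c = 0; c < rep_idx.size(); ++c) {
      const std::string& r = rep_seq[c];
      if (use_prefilter) {
        int la = s.size(), lb = r.size();
        double bound = (la - kmer_k + 1) - kmer_k * (1.0 - threshold) * (la + lb);
        if (bound > 0 && shared_kmers(km, rep_kmers[c]) < bound) continue;
      }
      if (identity_of(s, r, match, mismatch, gap_open, gap_extend) >= threshold) {
        found = (int)c;
        break;
      }
    }
    if (found < 0) {
      rep_idx.push_back(i);
      rep_seq.push_back(s);
      if (use_prefilter) rep_kmers.push_back(km);
      else rep_kmers.push_back(std::vector<uint32_t>());
      found = (int)rep_idx.size() - 1;
    }
    assign[i] = found + 1;
  }
  return assign;
}
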