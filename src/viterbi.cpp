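#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local Viterbi for a nucleotide profile HMM in log2-odds space.
//
// Core states per model position j (1..M): match M_j, insert I_j, delete D_j.
// Local on both sequence and model: a path enters at any M_j (entry cost
// log2(1/M)) and exits after any match state for free (uni-local
// approximation); flanking sequence is emitted by the background and
// contributes 0 to the log-odds score. Paths start and end in match states.
//
// Inputs:
//   em   : M x 4 match emission log2-odds (A,C,G,T)
//   ins  : 4 insert emission log2-odds
//   tr   : M x 7 transition log2 probabilities, columns
//          0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 DM, 6 DD  (row j = leaving pos j+1;
//          rows are 0-based model positions, transitions from position j to j+1)
//   x    : integer sequence, values 0..3, -1 for N (emission log-odds 0)
// Returns best bit score and the 0-based half-open alignment footprint on
// sequence and model.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".viterbi_local_cpp")]]
List viterbi_local_cpp(NumericMatrix em, NumericVector ins, NumericMatrix tr,
                       IntegerVector x) {
  const int M = em.nrow();
  const int L = x.size();
  const double entry = -log2((double)M);

  std::vector<double> vm(M, NEG_INF), vi(M, NEG_INF), vd(M, NEG_INF);
  std::vector<double> pm(M), pi(M), pd(M);
  // backpointers: state type 0=M,1=I,2=D,3=start; store (i, j, type) chains
  // compactly: bp[t][i*M+j] = predecessor type; alignment footprint recovered
  // by walking back.
  std::vector<unsigned char> bpM((size_t)L * M), bpI((size_t)L * M), bpD((size_t)L * M);

  double best = NEG_INF;
  int best_i = -1, best_j = -1;

  for (int i = 0; i < L; ++i) {
    int c = x[i];
    // match and insert states for row i (emitting x[i]) from row i-1
    for (int j = 0; j < M; ++j) {
      double e = (c >= 0) ? em(j, c) : 0.0;
      double v = entry; unsigned char bp = 3;  // fresh local entry
      if (i > 0 && j > 0) {
        double fm = pm[j - 1] + tr(j - 1, 0);  // M -> M
        double fi = pi[j - 1] + tr(j - 1, 3);  // I -> M
        double fd = pd[j - 1] + tr(j - 1, 5);  // D -> M
        if (fm > v) { v = fm; bp = 0; }
        if (fi > v) { v = fi; bp = 1; }
        if (fd > v) { v = fd; bp = 2; }
      }
      double nvm = v + e;
      // I_j emitting x[i] (no insert after the last match state)
      double nvi = NEG_INF; unsigned char ibp = 3;
      if (i > 0 && j < M - 1) {
        double fm = pm[j] + tr(j, 1);          // M -> I
        double fi = pi[j] + tr(j, 4);          // I -> I
        double ei = (c >= 0) ? ins[c] : 0.0;
        if (fm >= fi) { nvi = fm + ei; ibp = 0; } else { nvi = fi + ei; ibp = 1; }
      }
      vm[j] = nvm; bpM[(size_t)i * M + j] = bp;
      vi[j] = nvi; bpI[(size_t)i * M + j] = ibp;
      if (nvm > best) { best = nvm; best_i = i; best_j = j; }
    }
    // delete states consume no residue: same row, left to right
    for (int j = 0; j < M; ++j) {
      double dv = NEG_INF; unsigned char dbp = 3;
      if (j > 0) {
        double fm = vm[j - 1] + tr(j - 1, 2);  // M -> D
        double fd = vd[j - 1] + tr(j - 1, 6);  // D -> D
        if (fm >= fd) { dv = fm; dbp = 0; } else { dv = fd; dbp = 2; }
      }
      vd[j] = dv; bpD[(size_t)i * M + j] = dbp;
    }
    pm = vm; pi = vi; pd = vd;
  }

  if (best_i < 0)
    return List::create(_["score"] = NA_REAL);

  // walk back from (best_i, best_j, M) to the entry point
  int i = best_i, j = best_j; int type = 0;
  int start_i = best_i, start_j = best_j;
  while (true) {
    unsigned char bp;
    if (type == 0) bp = bpM[(size_t)i * M + j];
    else if (type == 1) bp = bpI[(size_t)i * M + j];
    else bp = bpD[(size_t)i * M + j];
    if (type == 0 && bp == 3) { start_i = i; start_j = j; break; }
    if (type == 0) { // came from (i-1, j-1, bp)
      --i; --j; type = bp;
    } else if (type == 1) { // insert: came from (i-1, j, bp)
      --i; type = bp;
    } else { // delete: same row, from (i, j-1, bp)
      --j; type = bp;
    }
  }

  return List::create(_["score"] = best,
                      _["seq_start"] = start_i,        // 0-based inclusive
                      _["seq_end"] = best_i + 1,       // 0-based exclusive
                      _["profile_start"] = start_j,    // 0-based inclusive
                      _["profile_end"] = best_j + 1);  // 0-based exclusive
}

// Best ungapped diagonal match-state score (MSV-like prefilter statistic):
// maximum over all diagonals of the maximum sub-segment sum of match
// emission log2-odds, plus the local entry cost.

// [[Rcpp::export(name = ".ungapped_best_cpp")]]
double ungapped_best_cpp(NumericMatrix em, IntegerVector x) {
  const int M = em.nrow();
  const int L = x.size();
  const double entry = -log2((double)M);
  double best = NEG_INF;
  // diagonal d: sequence position i aligned to model position i - d
  for (int d = -(M - 1); d <= L - 1; ++d) {
    double run = 0.0;
    bool active = false;
    int j0 = std::max(0, -d);
    int j1 = std::min(M - 1, L - 1 - d);
    for (int j = j0; j <= j1; ++j) {
      int c = x[j + d];
      double e = (c >= 0) ? em(j, c) : 0.0;
      run = active ? run + e : e;
      active = true;
      if (run > best) best = run;
      if (run < 0) { run = 0.0; active = false; }
    }
  }
  return (best == NEG_INF) ? NA_REAL : best + entry;
}
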