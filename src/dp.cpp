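#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Needleman-Wunsch global alignment, linear gap penalty.
// Traceback tie-break: diagonal, then up (gap in b), then left (gap in a),
// so the reported alignment is canonical among equal-score alternatives.
// Identity = matched columns / alignment length (gap columns count against).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be nonempty");
  std::vector<double> S((n + 1) * (m + 1));
  std::vector<unsigned char> tb((n + 1) * (m + 1)); // 1 diag, 2 up, 3 left
  const int W = m + 1;
  S[0] = 0.0;
  for (int j = 1; j <= m; ++j) { S[j] = j * gap; tb[j] = 3; }
  for (int i = 1; i <= n; ++i) {
    S[i * W] = i * gap; tb[i * W] = 2;
    for (int j = 1; j <= m; ++j) {
      double sub = S[(i - 1) * W + (j - 1)] +
        (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = S[(i - 1) * W + j] + gap;
      double left = S[i * W + (j - 1)] + gap;
      double best = sub; unsigned char dir = 1;
      if (up > best) { best = up; dir = 2; }
      if (left > best) { best = left; dir = 3; }
      S[i * W + j] = best; tb[i * W + j] = dir;
    }
  }
  // traceback
  std::string ra, rb;
  int i = n, j = m, matches = 0;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[i * W + j];
    if (dir == 1) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (dir == 2) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  const double len = (double) ra.size();
  return List::create(
    _["score"] = S[n * W + m],
    _["identity"] = matches / len,
    _["matches"] = matches,
    _["alignment_length"] = (int) len,
    _["aligned_a"] = ra,
    _["aligned_b"] = rb);
}

// Viterbi best local-path score (bits) of a sequence against a profile.
//
// Model: M match states with per-residue emission log-odds (bits); insert
// states emit at background (log-odds 0); delete states are silent. Entry
// is free into any match state at any sequence position; exit is free
// after any match state. Transition costs are log2 probabilities shared
// across states. seq holds 0-based residue indices into the emission
// rows; -1 marks an out-of-alphabet residue scored background-neutral.
//
// VM[i][k]: best path ending in match k having just emitted residue i.
// VI[i][k]: ending in insert k (between match k and k+1) emitting i.
// VD[i][k]: ending in silent delete k after emitting i residues total.
// [[Rcpp::export(name = ".profile_viterbi_cpp")]]
double profile_viterbi_cpp(NumericMatrix emis, IntegerVector seq,
                           double tMM, double tMI, double tMD,
                           double tIM, double tII,
                           double tDM, double tDD) {
  const int M = emis.ncol();
  const int L = seq.size();
  if (M < 1) stop("profile must have at least one match state");
  if (L < 1) stop("sequence must be nonempty");
  const double NEG = -1e30;
  std::vector<double> VMp(M, NEG), VIp(M, NEG), VDp(M, NEG);
  std::vector<double> VM(M), VI(M), VD(M);
  double best = NEG;
  for (int i = 0; i < L; ++i) {
    const int x = seq[i];
    for (int k = 0; k < M; ++k) {
      const double e = (x >= 0) ? emis(x, k) : 0.0;
      double from = 0.0; // free local entry into any match state
      if (k > 0) {
        if (VMp[k - 1] + tMM > from) from = VMp[k - 1] + tMM;
        if (VIp[k - 1] + tIM > from) from = VIp[k - 1] + tIM;
        if (VDp[k - 1] + tDM > from) from = VDp[k - 1] + tDM;
      }
      VM[k] = e + from;
      // insert k emits residue i at background after match/insert k at i-1
      double v = VMp[k] + tMI;
      if (VIp[k] + tII > v) v = VIp[k] + tII;
      VI[k] = v;
      if (VM[k] > best) best = VM[k];
    }
    // silent deletes within the current emission count, left to right
    VD[0] = NEG;
    for (int k = 1; k < M; ++k) {
      double d = VM[k - 1] + tMD;
      if (VD[k - 1] + tDD > d) d = VD[k - 1] + tDD;
      VD[k] = d;
    }
    std::swap(VMp, VM); std::swap(VIp, VI); std::swap(VDp, VD);
  }
  return best;
}
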