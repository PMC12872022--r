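// Dynamic-programming kernels for the profile HMM scorer.
// All scores are in bits (log2 odds against the null model); emissions and
// transitions arrive as log2 values precomputed in R.
#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log2(2^a + 2^b), safe for -Inf operands
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  double d = (a > b ? b : a) - m;
  return m + std::log1p(std::exp2(d)) / M_LN2;
}

// Transition column order (matches R side): MM MI MD IM II DM DD
enum { TMM = 0, TMI, TMD, TIM, TII, TDM, TDD };

// Forward bit score.  local = TRUE: alignment may enter any match state
// (uniform 1/L) and exit from any match state (uniform 1/L); residues
// outside the alignment score 0 bits (null/null).  local = FALSE: the
// whole sequence aligns M1..ML (consensus-anchored global mode).
// [[Rcpp::export]]
double phmm_forward(const NumericMatrix& lm, const NumericMatrix& li,
                    const NumericMatrix& lt, const IntegerVector& x,
                    bool local) {
  const int L = lm.nrow(), n = x.size();
  const double entry = local ? -std::log2((double)L) : 0.0;
  const double exitw = local ? -std::log2((double)L) : 0.0;
  std::vector<double> pM(L, NEG_INF), pI(L, NEG_INF), pD(L, NEG_INF);
  std::vector<double> cM(L), cI(L), cD(L);
  double total = NEG_INF;
  for (int i = 0; i < n; ++i) {
    const int xi = x[i] - 1;
    for (int k = 0; k < L; ++k) {
      double s = NEG_INF;
      if (local) s = entry;               // fresh start at (i, k)
      else if (i == 0 && k == 0) s = 0.0; // global start: M1 emits x1
      if (k > 0) {
        s = lse2(s, pM[k - 1] + lt(k - 1, TMM));
        s = lse2(s, pI[k - 1] + lt(k - 1, TIM));
        s = lse2(s, pD[k - 1] + lt(k - 1, TDM));
      }
      cM[k] = lm(k, xi) + s;
    }
    for (int k = 0; k < L; ++k) {
      if (k < L - 1) {
        cI[k] = li(k, xi) + lse2(pM[k] + lt(k, TMI), pI[k] + lt(k, TII));
      } else {
        cI[k] = NEG_INF; // no insert state after the last match
      }
    }
    cD[0] = NEG_INF; // alignments cannot start in a delete state
    for (int k = 1; k < L; ++k)
      cD[k] = lse2(cM[k - 1] + lt(k - 1, TMD), cD[k - 1] + lt(k - 1, TDD));
    if (local)
      for (int k = 0; k < L; ++k) total = lse2(total, cM[k] + exitw);
    std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
  }
  if (!local) total = pM[L - 1];
  return total;
}

// Viterbi bit score with traceback.  Returns the max-scoring alignment,
// its envelope on the sequence (1-based, inclusive) and the state path.
// [[Rcpp::export]]
List phmm_viterbi(const NumericMatrix& lm, const NumericMatrix& li,
                  const NumericMatrix& lt, const IntegerVector& x,
                  bool local) {
  const int L = lm.nrow(), n = x.size();
  const double entry = local ? -std::log2((double)L) : 0.0;
  const double exitw = local ? -std::log2((double)L) : 0.0;
  NumericMatrix M(n, L), I(n, L), D(n, L);
  IntegerMatrix bM(n, L), bI(n, L), bD(n, L); // 0 start, 1 M, 2 I, 3 D
  for (int i = 0; i < n; ++i) {
    const int xi = x[i] - 1;
    for (int k = 0; k < L; ++k) {
      double best = NEG_INF; int ptr = -1;
      if (local) { best = entry; ptr = 0; }
      else if (i == 0 && k == 0) { best = 0.0; ptr = 0; }
      if (i > 0 && k > 0) {
        double v = M(i - 1, k - 1) + lt(k - 1, TMM);
        if (v > best) { best = v; ptr = 1; }
        v = I(i - 1, k - 1) + lt(k - 1, TIM);
        if (v > best) { best = v; ptr = 2; }
      }
      if (k > 0) {
        double v = (i > 0 ? D(i - 1, k - 1) : NEG_INF) + lt(k - 1, TDM);
        if (v > best) { best = v; ptr = 3; }
      }
      M(i, k) = lm(k, xi) + best;
      bM(i, k) = ptr;
    }
    for (int k = 0; k < L; ++k) {
      if (k < L - 1 && i > 0) {
        double vm = M(i - 1, k) + lt(k, TMI);
        double vi = I(i - 1, k) + lt(k, TII);
        if (vm >= vi) { I(i, k) = li(k, xi) + vm; bI(i, k) = 1; }
        else          { I(i, k) = li(k, xi) + vi; bI(i, k) = 2; }
      } else {
        I(i, k) = NEG_INF; bI(i, k) = -1;
      }
    }
    D(i, 0) = NEG_INF; bD(i, 0) = -1;
    for (int k = 1; k < L; ++k) {
      double vm = M(i, k - 1) + lt(k - 1, TMD);
      double vd = D(i, k - 1) + lt(k - 1, TDD);
      if (vm >= vd) { D(i, k) = vm; bD(i, k) = 1; }
      else          { D(i, k) = vd; bD(i, k) = 3; }
    }
  }
  double best = NEG_INF; int ei = -1, ek = -1;
  if (local) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < L; ++k)
        if (M(i, k) + exitw > best) { best = M(i, k) + exitw; ei = i; ek = k; }
  } else {
    best = M(n - 1, L - 1); ei = n - 1; ek = L - 1;
  }
  // traceback
  std::vector<std::string> path;
  int i = ei, k = ek; char st = 'M';
  int start_i = ei;
  while (true) {
    path.push_back(std::string(1, st) + std::to_string(k + 1));
    if (st == 'M') {
      start_i = i;
      int p = bM(i, k);
      if (p == 0) break;
      if (p == 1) { st = 'M'; --i; --k; }
      else if (p == 2) { st = 'I'; --i; --k; }
      else { st = 'D'; --i; --k; } // D(i-1, k-1) fed M via TDM
    } else if (st == 'I') {
      int p = bI(i, k);
      if (p == 1) { st = 'M'; --i; }
      else { st = 'I'; --i; }
    } else { // D: same residue index
      int p = bD(i, k);
      if (p == 1) { st = 'M'; --k; }
      else { st = 'D'; --k; }
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["bits"] = best,
                      _["ali_start"] = start_i + 1,
                      _["ali_end"] = ei + 1,
                      _["path"] = wrap(path));
}
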