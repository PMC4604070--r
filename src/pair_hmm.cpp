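#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Local pairwise HMM-HMM Viterbi alignment over the five pair states
// MM, MI, IM, DG, GD (HHsearch-style). Scores are log2 (bits).
//
// State semantics at cell (i, j), 1-based over match states:
//   MM: match i of A aligned to match j of B (emits the column score)
//   MI: match i of A against an insert of B after its match j (no emission)
//   IM: insert of A after its match i against match j of B
//   DG: match i of A deleted, B does not advance
//   GD: match j of B deleted, A does not advance
//
// Transition matrices trA/trB have one row per model position 0..L
// (row p = transitions out of position p) and 7 columns in the order
// MM, MI, MD, IM, II, DM, DD. A pair-state step costs log2 of the product
// of the two models' corresponding transition probabilities; DG/GD steps
// involve only the advancing model. Local alignment: MM cells are floored
// at zero (restart), paths start and end in MM, and the empty alignment
// scores 0.

enum { TMM = 0, TMI = 1, TMD = 2, TIM = 3, TII = 4, TDM = 5, TDD = 6 };
enum { SMM = 0, SMI = 1, SIM = 2, SDG = 3, SGD = 4, SSTART = 5, SNONE = 6 };

// [[Rcpp::export]]
List pair_hmm_align_cpp(NumericMatrix emA, NumericMatrix emB,
                        NumericVector bg,
                        NumericMatrix trA, NumericMatrix trB,
                        bool score_only = false) {
  const int La = emA.nrow(), Lb = emB.nrow(), K = bg.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  // column co-emission scores, bits; divide one operand by the
  // background once so the inner loop is a plain dot product
  std::vector<double> ad(La * K);
  for (int i = 0; i < La; ++i)
    for (int k = 0; k < K; ++k) ad[i * K + k] = emA(i, k) / bg[k];
  std::vector<double> bt(Lb * K);
  for (int j = 0; j < Lb; ++j)
    for (int k = 0; k < K; ++k) bt[j * K + k] = emB(j, k);
  std::vector<double> S(La * Lb);
  for (int i = 0; i < La; ++i) {
    const double *ai = &ad[i * K];
    for (int j = 0; j < Lb; ++j) {
      const double *bj = &bt[j * K];
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += ai[k] * bj[k];
      S[i * Lb + j] = (s > 0.0) ? std::log2(s) : NEG;
    }
  }

  // log2 transitions
  NumericMatrix lA(trA.nrow(), 7), lB(trB.nrow(), 7);
  for (int i = 0; i < trA.nrow(); ++i)
    for (int c = 0; c < 7; ++c)
      lA(i, c) = (trA(i, c) > 0.0) ? std::log2(trA(i, c)) : NEG;
  for (int j = 0; j < trB.nrow(); ++j)
    for (int c = 0; c < 7; ++c)
      lB(j, c) = (trB(j, c) > 0.0) ? std::log2(trB(j, c)) : NEG;

  const int na = La + 1, nb = Lb + 1;
  // NB: Rcpp matrices copy shallowly; build each state's tables separately
  std::vector<std::vector<double> > V(5, std::vector<double>(na * nb, NEG));
  std::vector<std::vector<int> > P(5, std::vector<int>(na * nb, SNONE));
#define AT(M, s, i, j) M[s][(std::size_t)(i) * nb + (j)]

  double best = 0.0;
  int bi = -1, bj = -1;

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      // MM from diagonal predecessors (transitions out of i-1 / j-1) or restart
      {
        double cand[6];
        cand[SSTART] = 0.0;
        cand[SMM] = AT(V, SMM, i - 1, j - 1) + lA(i - 1, TMM) + lB(j - 1, TMM);
        cand[SMI] = AT(V, SMI, i - 1, j - 1) + lA(i - 1, TMM) + lB(j - 1, TIM);
        cand[SIM] = AT(V, SIM, i - 1, j - 1) + lA(i - 1, TIM) + lB(j - 1, TMM);
        cand[SDG] = AT(V, SDG, i - 1, j - 1) + lA(i - 1, TDM) + lB(j - 1, TMM);
        cand[SGD] = AT(V, SGD, i - 1, j - 1) + lA(i - 1, TMM) + lB(j - 1, TDM);
        int arg = SSTART; double mx = cand[SSTART];
        for (int s = 0; s < 5; ++s) if (cand[s] > mx) { mx = cand[s]; arg = s; }
        double v = S[(i - 1) * Lb + (j - 1)] + mx;
        AT(V, SMM, i, j) = v; AT(P, SMM, i, j) = arg;
        if (v > best) { best = v; bi = i; bj = j; }
      }
      // MI: A advances (M->M out of i-1), B sits in insert after j
      {
        double c1 = AT(V, SMM, i - 1, j) + lA(i - 1, TMM) + lB(j, TMI);
        double c2 = AT(V, SMI, i - 1, j) + lA(i - 1, TMM) + lB(j, TII);
        if (c1 >= c2) { AT(V, SMI, i, j) = c1; AT(P, SMI, i, j) = SMM; }
        else          { AT(V, SMI, i, j) = c2; AT(P, SMI, i, j) = SMI; }
      }
      // IM: B advances, A sits in insert after i
      {
        double c1 = AT(V, SMM, i, j - 1) + lA(i, TMI) + lB(j - 1, TMM);
        double c2 = AT(V, SIM, i, j - 1) + lA(i, TII) + lB(j - 1, TMM);
        if (c1 >= c2) { AT(V, SIM, i, j) = c1; AT(P, SIM, i, j) = SMM; }
        else          { AT(V, SIM, i, j) = c2; AT(P, SIM, i, j) = SIM; }
      }
      // DG: match i of A deleted
      {
        double c1 = AT(V, SMM, i - 1, j) + lA(i - 1, TMD);
        double c2 = AT(V, SDG, i - 1, j) + lA(i - 1, TDD);
        if (c1 >= c2) { AT(V, SDG, i, j) = c1; AT(P, SDG, i, j) = SMM; }
        else          { AT(V, SDG, i, j) = c2; AT(P, SDG, i, j) = SDG; }
      }
      // GD: match j of B deleted
      {
        double c1 = AT(V, SMM, i, j - 1) + lB(j - 1, TMD);
        double c2 = AT(V, SGD, i, j - 1) + lB(j - 1, TDD);
        if (c1 >= c2) { AT(V, SGD, i, j) = c1; AT(P, SGD, i, j) = SMM; }
        else          { AT(V, SGD, i, j) = c2; AT(P, SGD, i, j) = SGD; }
      }
    }
  }

  if (bi < 0 || best <= 0.0) {
    return List::create(_["score_bits"] = 0.0,
                        _["path"] = IntegerMatrix(0, 3));
  }
  if (score_only)
    return List::create(_["score_bits"] = best,
                        _["path"] = IntegerMatrix(0, 3));

  // traceback from the best MM cell
  std::vector<int> st, ii, jj;
  int s = SMM, i = bi, j = bj;
  while (s != SSTART) {
    st.push_back(s); ii.push_back(i); jj.push_back(j);
    int prev = AT(P, s, i, j);
    if (s == SMM) { --i; --j; }
    else if (s == SMI || s == SDG) { --i; }
    else { --j; }
    s = prev;
    if (s == SNONE) stop("traceback reached an unreachable cell");
  }
  const int n = st.size();
  IntegerMatrix path(n, 3);
  for (int r = 0; r < n; ++r) {
    path(r, 0) = st[n - 1 - r];
    path(r, 1) = ii[n - 1 - r];
    path(r, 2) = jj[n - 1 - r];
  }
  return List::create(_["score_bits"] = best, _["path"] = path);
}

// Ungapped best-offset identity of a peptide against a protein.
// [[Rcpp::export]]
List best_offset_identity_cpp(IntegerVector pep, IntegerVector prot) {
  const int lp = pep.size(), ln = prot.size();
  if (lp > ln) stop("peptide longer than protein");
  int best_m = -1, best_off = 0;
  for (int off = 0; off + lp <= ln; ++off) {
    int m = 0;
    for (int k = 0; k < lp; ++k) if (pep[k] == prot[off + k]) ++m;
    if (m > best_m) { best_m = m; best_off = off; }
  }
  return List::create(_["matches"] = best_m,
                      _["offset"] = best_off,
                      _["identity"] = (double)best_m / (double)lp);
}
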