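#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log2-sum-exp of two values in bits
static inline double ls2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log2(1.0 + std::exp2(-(std::fabs(a - b))));
}

// Local (Smith-Waterman-style entry/exit) profile alignment over
// match/insert/delete states. Emissions are log-odds bits per match state
// (columns: 20 residues + X). Insert states emit at background (0 bits).
// Entry into any match state and exit from any match state are free.
// Viterbi (best path) and, optionally, forward (log-sum over all local
// paths) are computed in one pass; the forward recursion is skipped when
// only the best path is wanted.
//
// emissions: L x 21 matrix (bits)
// trans: list of numeric vectors tMM,tMI,tMD,tIM,tII,tDM,tDD (bits),
//   indexed by the source state of the inter-state move.
// query: integer vector, 0-based residue indices (0..19, 20 = X)
// Returns c(viterbi_bits, forward_bits).
// [[Rcpp::export]]
NumericVector profile_score_cpp(NumericMatrix emissions, List trans,
                                IntegerVector query, bool forward = true) {
  const int L = emissions.nrow();
  const int n = query.size();
  NumericVector tMM_ = trans["tMM"], tMI_ = trans["tMI"], tMD_ = trans["tMD"],
                tIM_ = trans["tIM"], tII_ = trans["tII"], tDM_ = trans["tDM"],
                tDD_ = trans["tDD"];
  const double *tMM = tMM_.begin(), *tMI = tMI_.begin(), *tMD = tMD_.begin(),
               *tIM = tIM_.begin(), *tII = tII_.begin(), *tDM = tDM_.begin(),
               *tDD = tDD_.begin();
  const double *em = emissions.begin(); // column-major, L rows
  const double NEG = R_NegInf;

  std::vector<double> Mv(L, NEG), Iv(L, NEG), Dv(L, NEG),
      pMv(L, NEG), pIv(L, NEG), pDv(L, NEG);
  std::vector<double> Mf, If, Df, pMf, pIf, pDf;
  if (forward) {
    Mf.assign(L, NEG); If.assign(L, NEG); Df.assign(L, NEG);
    pMf.assign(L, NEG); pIf.assign(L, NEG); pDf.assign(L, NEG);
  }
  double bestV = NEG, sumF = NEG;

  for (int i = 0; i < n; ++i) {
    std::swap(pMv, Mv); std::swap(pIv, Iv); std::swap(pDv, Dv);
    if (forward) { std::swap(pMf, Mf); std::swap(pIf, If); std::swap(pDf, Df); }
    const double *ecol = em + (size_t)query[i] * L;
    const bool first = (i == 0);
    // k = 0: entry only
    {
      const double e = ecol[0];
      Mv[0] = e;          // free entry
      Iv[0] = (L > 1 && !first)
        ? std::max(pMv[0] + tMI[0], pIv[0] + tII[0]) : NEG;
      Dv[0] = NEG;
      if (Mv[0] > bestV) bestV = Mv[0];
      if (forward) {
        Mf[0] = e;
        If[0] = (L > 1 && !first)
          ? ls2(pMf[0] + tMI[0], pIf[0] + tII[0]) : NEG;
        Df[0] = NEG;
        sumF = ls2(sumF, Mf[0]);
      }
    }
    if (!forward) {
      for (int k = 1; k < L; ++k) {
        const double e = ecol[k];
        double mv = 0.0;
        if (!first) {
          const double a = pMv[k - 1] + tMM[k - 1];
          const double b = pIv[k - 1] + tIM[k - 1];
          const double c = pDv[k - 1] + tDM[k - 1];
          if (a > mv) mv = a;
          if (b > mv) mv = b;
          if (c > mv) mv = c;
        }
        const double m = e + mv;
        Mv[k] = m;
        Iv[k] = (k < L - 1 && !first)
          ? std::max(pMv[k] + tMI[k], pIv[k] + tII[k]) : NEG;
        Dv[k] = std::max(Mv[k - 1] + tMD[k - 1], Dv[k - 1] + tDD[k - 1]);
        if (m > bestV) bestV = m;
      }
    } else {
      for (int k = 1; k < L; ++k) {
        const double e = ecol[k];
        double mv = 0.0, mf = 0.0;
        if (!first) {
          const double a = pMv[k - 1] + tMM[k - 1];
          const double b = pIv[k - 1] + tIM[k - 1];
          const double c = pDv[k - 1] + tDM[k - 1];
          if (a > mv) mv = a;
          if (b > mv) mv = b;
          if (c > mv) mv = c;
          mf = ls2(mf, pMf[k - 1] + tMM[k - 1]);
          mf = ls2(mf, pIf[k - 1] + tIM[k - 1]);
          mf = ls2(mf, pDf[k - 1] + tDM[k - 1]);
        }
        Mv[k] = e + mv;
        Mf[k] = e + mf;
        if (k < L - 1 && !first) {
          Iv[k] = std::max(pMv[k] + tMI[k], pIv[k] + tII[k]);
          If[k] = ls2(pMf[k] + tMI[k], pIf[k] + tII[k]);
        } else { Iv[k] = NEG; If[k] = NEG; }
        Dv[k] = std::max(Mv[k - 1] + tMD[k - 1], Dv[k - 1] + tDD[k - 1]);
        Df[k] = ls2(Mf[k - 1] + tMD[k - 1], Df[k - 1] + tDD[k - 1]);
        if (Mv[k] > bestV) bestV = Mv[k];
        sumF = ls2(sumF, Mf[k]);
      }
    }
  }
  return NumericVector::create(bestV, forward ? sumF : NA_REAL);
}

// Batch scorer: list of integer queries against one profile.
// [[Rcpp::export]]
NumericMatrix profile_score_batch_cpp(NumericMatrix emissions, List trans,
                                      List queries, bool forward = true) {
  const int m = queries.size();
  NumericMatrix out(m, 2);
  for (int j = 0; j < m; ++j) {
    IntegerVector q = queries[j];
    NumericVector s = profile_score_cpp(emissions, trans, q, forward);
    out(j, 0) = s[0];
    out(j, 1) = s[1];
  }
  colnames(out) = CharacterVector::create("viterbi_bits", "forward_bits");
  return out;
}
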