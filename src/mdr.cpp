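// Cross-validated MDR scan core: per-pair, per-fold 3x3 case/control cell
// counts, case:control-ratio labeling and balanced accuracy. Exhaustive
// two-way scans over C(m,2) pairs times K folds times permutation nulls are
// tabulation-bound, hence compiled.

#include <Rcpp.h>
using namespace Rcpp;

// geno: n x m minor-allele counts with NA -> -1; pheno 0/1; fold 0..K-1.
// pairsA/pairsB: 0-based SNP column indices.
// Returns train/test balanced accuracy (P x K). T per fold = training-fold
// case:control ratio over all training samples. Cells labeled high when
// cases/controls >= T (controls == 0 with cases > 0 -> high); empty -> low.
// Test BA is NaN when the test fold lacks cases or controls after pairwise
// missing exclusion.
// [[Rcpp::export(name = ".cpp_mdr_scan")]]
List cpp_mdr_scan(const IntegerMatrix& geno, const IntegerVector& pheno,
                  const IntegerVector& fold, int K,
                  const IntegerVector& pairsA, const IntegerVector& pairsB) {
  const int n = geno.nrow();
  const int P = pairsA.size();

  // fold-level phenotype totals (all samples, missingness ignored for T)
  std::vector<double> n1(K, 0.0), n0(K, 0.0);
  for (int i = 0; i < n; ++i) {
    if (pheno[i] == 1) n1[fold[i]] += 1; else n0[fold[i]] += 1;
  }
  double N1 = 0, N0 = 0;
  for (int k = 0; k < K; ++k) { N1 += n1[k]; N0 += n0[k]; }

  NumericMatrix train_ba(P, K), test_ba(P, K);
  std::vector<int> cnt(K * 18);

  for (int pidx = 0; pidx < P; ++pidx) {
    const int a = pairsA[pidx], b = pairsB[pidx];
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int ga = geno(i, a), gb = geno(i, b);
      if (ga < 0 || gb < 0) continue;
      const int cell = 3 * ga + gb;
      cnt[fold[i] * 18 + cell * 2 + pheno[i]]++;
    }
    // per-cell totals across folds
    int tot[18];
    for (int c = 0; c < 18; ++c) {
      int s = 0;
      for (int k = 0; k < K; ++k) s += cnt[k * 18 + c];
      tot[c] = s;
    }
    for (int k = 0; k < K; ++k) {
      double tr1 = N1 - n1[k], tr0 = N0 - n0[k];
      double T = (tr0 > 0) ? tr1 / tr0 : 1.0;
      double tp_tr = 0, fn_tr = 0, fp_tr = 0, tn_tr = 0;
      double tp_te = 0, fn_te = 0, fp_te = 0, tn_te = 0;
      for (int c = 0; c < 9; ++c) {
        const int te0 = cnt[k * 18 + c * 2 + 0], te1 = cnt[k * 18 + c * 2 + 1];
        const int trc0 = tot[c * 2 + 0] - te0, trc1 = tot[c * 2 + 1] - te1;
        bool high;
        if (trc0 == 0 && trc1 == 0) high = false;
        else if (trc0 == 0) high = true;
        else high = ((double)trc1 / (double)trc0 >= T);
        if (high) { tp_tr += trc1; fp_tr += trc0; tp_te += te1; fp_te += te0; }
        else      { fn_tr += trc1; tn_tr += trc0; fn_te += te1; tn_te += te0; }
      }
      double sens_tr = (tp_tr + fn_tr > 0) ? tp_tr / (tp_tr + fn_tr) : NA_REAL;
      double spec_tr = (fp_tr + tn_tr > 0) ? tn_tr / (fp_tr + tn_tr) : NA_REAL;
      train_ba(pidx, k) = (sens_tr + spec_tr) / 2.0;
      if (tp_te + fn_te > 0 && fp_te + tn_te > 0) {
        double sens_te = tp_te / (tp_te + fn_te);
        double spec_te = tn_te / (fp_te + tn_te);
        test_ba(pidx, k) = (sens_te + spec_te) / 2.0;
      } else {
        test_ba(pidx, k) = NA_REAL;
      }
    }
  }
  return List::create(_["train_ba"] = train_ba, _["test_ba"] = test_ba);
}
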