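#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo ancestor-tracing inbreeding coefficients.
// sire/dam are 1-based indices into the ordered pedigree, 0 = unknown.
// For the Mendelian-sampling variance D_j the F of an unknown parent is
// taken as -1, which folds the one-parent (0.75 - F_k/4) and no-parent (1)
// cases into the single expression D = 0.5 - 0.25 (F_s + F_d).
// [[Rcpp::export]]
NumericVector meuwissen_luo_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n);
  std::vector<double> ws(n, 0.0), wd(n, 0.0);

  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    double fs = (s > 0) ? F[s - 1] : -1.0;
    double fd = (d > 0) ? F[d - 1] : -1.0;
    D[i] = 0.5 - 0.25 * (fs + fd);
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }

    int si = s - 1, di = d - 1;
    // gene-contribution rows L_{s,.} and L_{d,.} by downward recursion
    ws[si] += 1.0;
    for (int j = si; j >= 0; --j) {
      double w = ws[j];
      if (w == 0.0) continue;
      if (sire[j] > 0) ws[sire[j] - 1] += 0.5 * w;
      if (dam[j] > 0)  ws[dam[j] - 1]  += 0.5 * w;
    }
    wd[di] += 1.0;
    for (int j = di; j >= 0; --j) {
      double w = wd[j];
      if (w == 0.0) continue;
      if (sire[j] > 0) wd[sire[j] - 1] += 0.5 * w;
      if (dam[j] > 0)  wd[dam[j] - 1]  += 0.5 * w;
    }
    double a_sd = 0.0;
    int top = std::max(si, di);
    for (int j = 0; j <= top; ++j) {
      if (ws[j] != 0.0 && wd[j] != 0.0) a_sd += ws[j] * wd[j] * D[j];
      ws[j] = 0.0; wd[j] = 0.0;
    }
    F[i] = 0.5 * a_sd;
  }
  return F;
}

// Dense numerator relationship matrix by the tabular method.
// [[Rcpp::export]]
NumericMatrix tabular_a_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s > 0) a += 0.5 * A(j, s - 1);
      if (d > 0) a += 0.5 * A(j, d - 1);
      A(i, j) = a;
      A(j, i) = a;
    }
    A(i, i) = 1.0 + ((s > 0 && d > 0) ? 0.5 * A(s - 1, d - 1) : 0.0);
  }
  return A;
}
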