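#include <Rcpp.h>
using namespace Rcpp;

// Score every SNP combination of one interaction order against a phenotype
// class vector. `cells` holds, per combination (column), each sample's
// mixed-radix multi-locus genotype cell in 0..n_cells-1 (NA = missing
// genotype at one of the combination's SNPs -> sample excluded listwise for
// that combination only). `y` holds 0-based phenotype classes. stat: 0 =
// GIDS, 1 = Pearson chi-squared. Combinations whose retained samples cover
// fewer than two phenotype classes get NA (degenerate denominator).
// [[Rcpp::export]]
NumericVector scan_statistic_cpp(const IntegerMatrix& cells,
                                 const IntegerVector& y,
                                 int n_cells, int J, int stat) {
  const int n = cells.nrow();
  const int M = cells.ncol();
  if (y.size() != n) stop("length(y) must match nrow(cells)");
  NumericVector out(M);
  std::vector<double> counts(static_cast<size_t>(n_cells) * J);
  std::vector<double> rowtot(n_cells), coltot(J);

  for (int m = 0; m < M; ++m) {
    std::fill(counts.begin(), counts.end(), 0.0);
    std::fill(rowtot.begin(), rowtot.end(), 0.0);
    std::fill(coltot.begin(), coltot.end(), 0.0);
    double ntot = 0.0;
    for (int i = 0; i < n; ++i) {
      const int c = cells(i, m);
      if (c == NA_INTEGER) continue;
      const int j = y[i];
      counts[static_cast<size_t>(c) * J + j] += 1.0;
      rowtot[c] += 1.0;
      coltot[j] += 1.0;
      ntot += 1.0;
    }
    if (ntot <= 0.0) { out[m] = NA_REAL; continue; }
    double value = 0.0;
    if (stat == 0) {
      double denom = 0.0;
      for (int j = 0; j < J; ++j) {
        const double pj = coltot[j] / ntot;
        denom += ntot * pj * (1.0 - pj);
      }
      if (denom <= 0.0) { out[m] = NA_REAL; continue; }
      double num = 0.0;
      for (int c = 0; c < n_cells; ++c) {
        if (rowtot[c] == 0.0) continue;
        for (int j = 0; j < J; ++j) {
          const double e = rowtot[c] * coltot[j] / ntot;
          num += std::fabs(counts[static_cast<size_t>(c) * J + j] - e);
        }
      }
      value = 0.5 * num / denom;
    } else {
      for (int c = 0; c < n_cells; ++c) {
        if (rowtot[c] == 0.0) continue;
        for (int j = 0; j < J; ++j) {
          const double e = rowtot[c] * coltot[j] / ntot;
          if (e > 0.0) {
            const double d = counts[static_cast<size_t>(c) * J + j] - e;
            value += d * d / e;
          }
        }
      }
    }
    out[m] = value;
  }
  return out;
}

// Max statistic over all combinations for B phenotype permutations.
// `perms` is an n x B matrix of 0-based sample orderings; column b scores
// y[perms[, b]] against the fixed genotype cells.
// [[Rcpp::export]]
NumericVector permutation_max_cpp(const IntegerMatrix& cells,
                                  const IntegerVector& y,
                                  const IntegerMatrix& perms,
                                  int n_cells, int J, int stat) {
  const int n = cells.nrow();
  const int B = perms.ncol();
  if (perms.nrow() != n) stop("nrow(perms) must match nrow(cells)");
  NumericVector out(B);
  IntegerVector yp(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) yp[i] = y[perms(i, b)];
    NumericVector v = scan_statistic_cpp(cells, yp, n_cells, J, stat);
    double mx = R_NegInf;
    for (int m = 0; m < v.size(); ++m)
      if (!NumericVector::is_na(v[m]) && v[m] > mx) mx = v[m];
    out[b] = mx;
  }
  return out;
}
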