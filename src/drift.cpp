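#include <Rcpp.h>
using namespace Rcpp;

// Forward binomial drift of two daughter populations with symmetric
// migration, one allele frequency per locus (loci independent).
// Time scaling: n_gen generations of Wright-Fisher drift in demes of
// 2*n_dip chromosomes; m is the per-generation migration proportion.
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
NumericMatrix drift_pair_cpp(NumericVector p0, int n_gen, int n_dip,
                             double m) {
  int L = p0.size();
  double two_n = 2.0 * n_dip;
  NumericMatrix out(2, L);
  for (int l = 0; l < L; ++l) {
    double p1 = p0[l], p2 = p0[l];
    for (int g = 0; g < n_gen; ++g) {
      double q1 = (1.0 - m) * p1 + m * p2;
      double q2 = (1.0 - m) * p2 + m * p1;
      p1 = R::rbinom(two_n, q1) / two_n;
      p2 = R::rbinom(two_n, q2) / two_n;
      if (p1 <= 0.0 && p2 <= 0.0) break;   // jointly absorbed
      if (p1 >= 1.0 && p2 >= 1.0) break;
    }
    out(0, l) = p1;
    out(1, l) = p2;
  }
  return out;
}
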