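#include <Rcpp.h>
using namespace Rcpp;

// Draw a (mother, father) pair for every seedling from its full
// conditional categorical distribution. Mothers index 1..N (mapped
// in-plot adults) plus N+1 (out-of-plot); fathers likewise.
//
//   G        list of K (N+1)x(N+1) genotype-probability matrices
//            (rows = mother slot, columns = father slot)
//   Sin      K x N seed terms f_i K(d_ik; u_s)
//   Pin      N x N pollen terms f_i' K(d_i'i; u_p), mother rows
//   PoutIn   length N: exterior pollen mass reaching each in-plot mother
//   SPoutIn  K x N: exterior-mother seed mass x in-plot-father pollen,
//            already integrated over the exterior grid
//   SPoutOut length K: both-parents-exterior mass
//
// The i == j diagonal carries weight zero: a tree cannot be both mother
// and father of the same seedling. Uses R's RNG, so draws are
// reproducible under set.seed(). All matrices are walked column-major.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_pairs(List G, NumericMatrix Sin,
                                 NumericMatrix Pin, NumericVector PoutIn,
                                 NumericMatrix SPoutIn,
                                 NumericVector SPoutOut) {
  const int K = Sin.nrow(), N = Sin.ncol();
  const int M = N + 1;
  IntegerMatrix out(K, 2);
  std::vector<double> w((size_t)M * M);
  std::vector<double> s((size_t)N), sp((size_t)N);
  const double *pin = Pin.begin();
  for (int k = 0; k < K; ++k) {
    NumericMatrix g = G[k];
    if (g.nrow() != M || g.ncol() != M)
      stop("genotype weight matrix has wrong dimensions");
    const double *gp = g.begin();
    for (int i = 0; i < N; ++i) {
      s[i] = Sin(k, i);
      sp[i] = SPoutIn(k, i);
    }
    double tot = 0.0;
    for (int j = 0; j < N; ++j) {          // in-plot father columns
      const double *gcol = gp + (size_t)j * M;
      const double *pcol = pin + (size_t)j * N;
      double *wcol = &w[(size_t)j * M];
      for (int i = 0; i < N; ++i) {
        const double v = (i == j) ? 0.0 : s[i] * pcol[i] * gcol[i];
        wcol[i] = v;
        tot += v;
      }
      const double v = sp[j] * gcol[N];    // out-of-plot mother row
      wcol[N] = v;
      tot += v;
    }
    {                                      // out-of-plot father column
      const double *gcol = gp + (size_t)N * M;
      double *wcol = &w[(size_t)N * M];
      for (int i = 0; i < N; ++i) {
        const double v = s[i] * PoutIn[i] * gcol[i];
        wcol[i] = v;
        tot += v;
      }
      const double v = SPoutOut[k] * gcol[N];
      wcol[N] = v;
      tot += v;
    }
    if (!(tot > 0.0) || !R_finite(tot))
      stop("all parent-pair weights are zero (or non-finite) for seedling %d",
           k + 1);
    const double u = unif_rand() * tot;
    double c = 0.0;
    size_t pick = w.size() - 1;
    for (size_t idx = 0; idx < w.size(); ++idx) {
      c += w[idx];
      if (u <= c) { pick = idx; break; }
    }
    out(k, 0) = (int)(pick % M) + 1;  // mother slot (N+1 = out-of-plot)
    out(k, 1) = (int)(pick / M) + 1;  // father slot
  }
  return out;
}
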