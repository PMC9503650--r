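#include <Rcpp.h>
using namespace Rcpp;

// Profile scanning inner loops. Profiles are column x 21 log-odds matrices in
// half-bits (columns 1..20 = residues in the package alphabet, column 21 = X,
// fixed at 0 so unknown residues score as background). Sequences arrive
// integer-coded 1..21.

// All window scores of one sequence against a profile (ungapped).
// [[Rcpp::export]]
NumericVector window_scores_cpp(const NumericMatrix lo, const IntegerVector seq) {
  const int m = lo.nrow();
  const int n = seq.size();
  const int nw = n - m + 1;
  if (nw < 1) return NumericVector(0);
  NumericVector out(nw);
  for (int o = 0; o < nw; ++o) {
    long double s = 0.0;  // match R's long-double summation for tie stability
    for (int i = 0; i < m; ++i) s += lo(i, seq[o + i] - 1);
    out[o] = (double) s;
  }
  return out;
}

// Best window per sequence: returns score and 1-based start (ties -> smallest
// start). Sequences shorter than the profile get -Inf / start 0.
// [[Rcpp::export]]
List scan_best_cpp(const NumericMatrix lo, const List seqs) {
  const int m = lo.nrow();
  const int ns = seqs.size();
  NumericVector best(ns);
  IntegerVector start(ns);
  for (int k = 0; k < ns; ++k) {
    IntegerVector seq = seqs[k];
    const int nw = seq.size() - m + 1;
    if (nw < 1) {
      best[k] = R_NegInf;
      start[k] = 0;
      continue;
    }
    double b = R_NegInf;
    int bo = 0;
    for (int o = 0; o < nw; ++o) {
      long double acc = 0.0;
      for (int i = 0; i < m; ++i) acc += lo(i, seq[o + i] - 1);
      const double s = (double) acc;
      if (s > b) { b = s; bo = o; }
    }
    best[k] = b;
    start[k] = bo + 1;
  }
  return List::create(_["score"] = best, _["start"] = start);
}

// Max window scores of i.i.d. background decoys, drawn with R's RNG so a
// set.seed() in R makes the calibration reproducible. bg_cum is the
// cumulative background distribution over the 20 residues. A branch-and-bound
// on suffix maxima skips windows that cannot beat the current decoy maximum.
// [[Rcpp::export]]
NumericVector decoy_max_scores_cpp(const NumericMatrix lo, const int n_decoys,
                                   const int decoy_length,
                                   const NumericVector bg_cum) {
  const int m = lo.nrow();
  if (decoy_length < m) stop("decoy_length shorter than profile");
  RNGScope scope;

  // per-column maximum over residues, then suffix sums of those maxima
  std::vector<double> colmax(m), suffmax(m + 1, 0.0);
  for (int i = 0; i < m; ++i) {
    double cm = lo(i, 0);
    for (int a = 1; a < 20; ++a) if (lo(i, a) > cm) cm = lo(i, a);
    colmax[i] = cm;
  }
  for (int i = m - 1; i >= 0; --i) suffmax[i] = suffmax[i + 1] + colmax[i];

  const int nw = decoy_length - m + 1;
  NumericVector out(n_decoys);
  std::vector<int> seq(decoy_length);
  for (int d = 0; d < n_decoys; ++d) {
    for (int j = 0; j < decoy_length; ++j) {
      const double u = unif_rand();
      int a = 0;
      while (a < 19 && u > bg_cum[a]) ++a;
      seq[j] = a;
    }
    double best = R_NegInf;
    for (int o = 0; o < nw; ++o) {
      long double s = 0.0;
      int i = 0;
      for (; i < m; ++i) {
        s += lo(i, seq[o + i]);
        if ((double) s + suffmax[i + 1] <= best) break;  // cannot beat best
      }
      if (i == m && (double) s > best) best = (double) s;
    }
    out[d] = best;
  }
  return out;
}
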