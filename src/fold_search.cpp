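#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive site->fold assignment minimizing the sum over folds and bins of
// squared deviations of bin counts from the balanced ideal. The objective is
// invariant under fold relabeling, so the search is restricted to canonical
// assignments (site i may open fold f only if folds 0..f-1 are already open),
// cutting the 5^n space by up to nFolds! .

static void recurse(int site, int nSites, int nFolds, int nBins, int maxOpen,
                    const IntegerMatrix &siteBins, NumericMatrix &cnt,
                    const NumericVector &target,
                    IntegerVector &cur, double &bestObj, IntegerVector &best) {
  if (site == nSites) {
    double o = 0.0;
    for (int f = 0; f < nFolds; ++f)
      for (int b = 0; b < nBins; ++b) {
        double d = cnt(f, b) - target[b];
        o += d * d;
      }
    if (o < bestObj) { bestObj = o; best = clone(cur); }
    return;
  }
  int open = maxOpen;
  int lim = (open < nFolds) ? open + 1 : nFolds;
  for (int f = 0; f < lim; ++f) {
    cur[site] = f;
    for (int b = 0; b < nBins; ++b) cnt(f, b) += siteBins(site, b);
    recurse(site + 1, nSites, nFolds, nBins, std::max(open, f + 1), siteBins,
            cnt, target, cur, bestObj, best);
    for (int b = 0; b < nBins; ++b) cnt(f, b) -= siteBins(site, b);
  }
}

// [[Rcpp::export]]
List exhaustiveFoldSearch(IntegerMatrix siteBins, int nFolds) {
  int nSites = siteBins.nrow(), nBins = siteBins.ncol();
  NumericVector target(nBins);
  for (int b = 0; b < nBins; ++b) {
    double tot = 0;
    for (int s = 0; s < nSites; ++s) tot += siteBins(s, b);
    target[b] = tot / nFolds;
  }
  NumericMatrix cnt(nFolds, nBins);
  IntegerVector cur(nSites), best(nSites);
  double bestObj = R_PosInf;
  recurse(0, nSites, nFolds, nBins, 0, siteBins, cnt, target, cur,
          bestObj, best);
  return List::create(_["assignment"] = best, _["objective"] = bestObj);
}

// [[Rcpp::export]]
double foldObjectiveCpp(IntegerMatrix siteBins, IntegerVector assignment,
                        int nFolds) {
  int nSites = siteBins.nrow(), nBins = siteBins.ncol();
  NumericMatrix cnt(nFolds, nBins);
  for (int s = 0; s < nSites; ++s)
    for (int b = 0; b < nBins; ++b) cnt(assignment[s], b) += siteBins(s, b);
  double o = 0.0;
  for (int b = 0; b < nBins; ++b) {
    double tot = 0;
    for (int s = 0; s < nSites; ++s) tot += siteBins(s, b);
    double t = tot / nFolds;
    for (int f = 0; f < nFolds; ++f) {
      double d = cnt(f, b) - t;
      o += d * d;
    }
  }
  return o;
}
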