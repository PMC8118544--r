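// Exact event-driven (Gillespie) simulation of the post-field-defect part of
// the process: premalignant clones are seeded by a Poisson process with rate
// mu1 from the field-defect onset onward; each clone is a linear birth-death
// process (division alpha, death beta) whose cells transform at rate mu2.
// A transformation produces one malignant daughter and one dysplastic
// daughter, so the dysplastic count is unchanged and the first transformation
// time across all clones sets the cancer time; clinical cancer follows after
// a fixed lag.  Uses R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List tsce_clone_sim(NumericVector fd_age, double mu1, double alpha,
                    double beta, double mu2, double lag, double max_age,
                    double cap) {
  int n = fd_age.size();
  NumericVector cancer(n, NA_REAL);
  IntegerVector capped(n, 0);
  double tcap = max_age - lag;  // transformations later than this are censored
  double tot = alpha + beta + mu2;

  for (int i = 0; i < n; ++i) {
    double s = fd_age[i];
    if (NumericVector::is_na(s) || s >= tcap) continue;
    double best = R_PosInf;
    double tau = s;
    for (;;) {
      tau += R::rexp(1.0 / mu1);  // next clone initiation
      double hor = (best < tcap) ? best : tcap;
      if (tau >= hor) break;
      double tc = tau;
      double ncell = 1.0;
      while (ncell > 0.0) {
        tc += R::rexp(1.0 / (ncell * tot));
        if (tc >= hor) break;
        double u = R::unif_rand() * tot;
        if (u < alpha) {
          ncell += 1.0;
          if (ncell > cap) { capped[i] = 1; break; }
        } else if (u < alpha + beta) {
          ncell -= 1.0;
        } else {
          best = tc;  // first malignant transformation in this clone
          break;
        }
      }
      if (capped[i]) break;
    }
    if (capped[i] == 0 && best < tcap) cancer[i] = best + lag;
  }
  return List::create(_["cancer_age"] = cancer, _["capped"] = capped);
}
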