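#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Optimized PCIT trio scan. Mirrors the pure-R reference triple loop
// expression-for-expression so the two implementations agree exactly
// under IEEE double arithmetic.
// [[Rcpp::export]]
List pcit_counts_cpp(NumericMatrix r) {
  const int n = r.nrow();
  IntegerMatrix evaluated(n, n), flagged(n, n);
  const double eps0 = 1e-12;
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      const double rij = r(i, j);
      for (int k = j + 1; k < n; ++k) {
        const double rik = r(i, k);
        const double rjk = r(j, k);
        const double dij = (1.0 - rik * rik) * (1.0 - rjk * rjk);
        const double dik = (1.0 - rij * rij) * (1.0 - rjk * rjk);
        const double djk = (1.0 - rij * rij) * (1.0 - rik * rik);
        if (dij <= 0.0 || dik <= 0.0 || djk <= 0.0) continue;
        const double pij = (rij - rik * rjk) / std::sqrt(dij);
        const double pik = (rik - rij * rjk) / std::sqrt(dik);
        const double pjk = (rjk - rij * rik) / std::sqrt(djk);
        double s = 0.0;
        int cnt = 0;
        if (std::abs(rij) >= eps0) { s += pij / rij; ++cnt; }
        if (std::abs(rik) >= eps0) { s += pik / rik; ++cnt; }
        if (std::abs(rjk) >= eps0) { s += pjk / rjk; ++cnt; }
        if (cnt == 0) continue;
        const double eps = s / cnt;
        evaluated(i, j) += 1;
        evaluated(i, k) += 1;
        evaluated(j, k) += 1;
        if (std::abs(pij) < std::abs(eps * pik) &&
            std::abs(pij) < std::abs(eps * pjk)) flagged(i, j) += 1;
        if (std::abs(pik) < std::abs(eps * pij) &&
            std::abs(pik) < std::abs(eps * pjk)) flagged(i, k) += 1;
        if (std::abs(pjk) < std::abs(eps * pij) &&
            std::abs(pjk) < std::abs(eps * pik)) flagged(j, k) += 1;
      }
    }
  }
  IntegerMatrix ev(n, n), fl(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      ev(i, j) = evaluated(i, j) + evaluated(j, i);
      fl(i, j) = flagged(i, j) + flagged(j, i);
    }
  return List::create(_["evaluated"] = ev, _["flagged"] = fl);
}
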