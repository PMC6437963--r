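#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Greedy forward scan over masses in their given (canonical enumeration)
// order: record i survives iff no previously surviving record lies strictly
// within `tolerance` of it.  Equivalent to the sequential pairwise removal
// where eliminated records lose their power to eliminate.  Kept masses are
// held in an ordered multiset so each query is O(log k).
// [[Rcpp::export(name = ".greedy_mass_keep")]]
LogicalVector greedy_mass_keep(NumericVector masses, double tolerance) {
  const int n = masses.size();
  LogicalVector keep(n);
  std::multiset<double> kept;
  for (int i = 0; i < n; ++i) {
    const double m = masses[i];
    bool ok = true;
    if (!kept.empty()) {
      std::multiset<double>::iterator it = kept.lower_bound(m);
      if (it != kept.end() && *it - m < tolerance) ok = false;
      if (ok && it != kept.begin()) {
        --it;
        if (m - *it < tolerance) ok = false;
      }
    }
    if (ok) {
      keep[i] = true;
      kept.insert(m);
    }
  }
  return keep;
}
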