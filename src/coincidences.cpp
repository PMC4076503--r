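#include <Rcpp.h>

// Count ordered pairs (s in a, t in b) with |s - t| <= dt, for sorted a, b.
// Two-pointer sweep: for each s, advance lo to the first b >= s - dt and
// hi to one past the last b <= s + dt; both pointers only move forward.
// O(|a| + |b| + #pairs-free) time, no allocation.
// [[Rcpp::export(name = ".coincident_count_cpp")]]
double coincident_count_cpp(Rcpp::NumericVector a, Rcpp::NumericVector b,
                            double dt) {
  const R_xlen_t na = a.size(), nb = b.size();
  double count = 0;
  R_xlen_t lo = 0, hi = 0;
  for (R_xlen_t i = 0; i < na; ++i) {
    const double s = a[i];
    while (lo < nb && b[lo] < s - dt) ++lo;
    if (hi < lo) hi = lo;
    while (hi < nb && b[hi] <= s + dt) ++hi;
    count += (double)(hi - lo);
  }
  return count;
}
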