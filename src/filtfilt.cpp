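#include <Rcpp.h>
typedef double ftype;
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One direct-form-II-transposed ARMA pass with the state initialized to
// zi * mean(x) (steady-state response to the signal's DC level), so a
// signal fluctuating around a constant level produces no spurious start-up
// transient in slow high-pass sections whose poles sit very close to z = 1.
static void iirPass(std::vector<ftype> &x,
                    const std::vector<ftype> &b,
                    const std::vector<ftype> &a,
                    const std::vector<ftype> &zi) {
  const int n = (int)x.size(), ns = (int)zi.size();
  ftype level = 0.0;
  for (int i = 0; i < n; ++i) level += x[i];
  level /= (ftype)n;
  std::vector<ftype> s(ns + 1, 0.0);
  for (int j = 0; j < ns; ++j) s[j] = zi[j] * level;
  for (int i = 0; i < n; ++i) {
    const ftype xi = x[i];
    const ftype yi = b[0] * xi + s[0];
    for (int j = 0; j < ns; ++j)
      s[j] = b[j + 1] * xi - a[j + 1] * yi + s[j + 1];
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) application of a cascade of IIR filters to
// each row of a channels x samples matrix. The signal is even-reflection
// padded by padLen samples at both ends before filtering; padding plus the
// steady-state initialization suppresses edge transients of slow high-pass
// sections.
// [[Rcpp::export(name = ".filtfiltCascade")]]
NumericMatrix filtfiltCascade(NumericMatrix x, List bList, List aList,
                              List ziList, int padLen) {
  const int nCh = x.nrow(), n = x.ncol(), nf = bList.size();
  if (padLen >= n) padLen = n - 1;
  std::vector<std::vector<ftype> > bs(nf), as(nf), zis(nf);
  for (int f = 0; f < nf; ++f) {
    NumericVector b = bList[f], a = aList[f], zi = ziList[f];
    if (b.size() != a.size() || zi.size() != a.size() - 1)
      stop("coefficient lengths inconsistent");
    bs[f] = std::vector<ftype>(b.begin(), b.end());
    as[f] = std::vector<ftype>(a.begin(), a.end());
    zis[f] = std::vector<ftype>(zi.begin(), zi.end());
  }
  NumericMatrix out(nCh, n);
  const int m = n + 2 * padLen;
  std::vector<ftype> z(m);
  for (int c = 0; c < nCh; ++c) {
    // even (symmetric) reflection: keeps the local mean level of the pads
    // equal to that of the data, so slow high-pass poles see no spurious
    // DC plateaus at the edges
    for (int i = 0; i < padLen; ++i)
      z[i] = x(c, padLen - i);
    for (int i = 0; i < n; ++i) z[padLen + i] = x(c, i);
    for (int i = 0; i < padLen; ++i)
      z[padLen + n + i] = x(c, n - 2 - i);
    for (int f = 0; f < nf; ++f) {
      iirPass(z, bs[f], as[f], zis[f]);
      std::reverse(z.begin(), z.end());
      iirPass(z, bs[f], as[f], zis[f]);
      std::reverse(z.begin(), z.end());
    }
    for (int i = 0; i < n; ++i) out(c, i) = (double)z[padLen + i];
  }
  return out;
}
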