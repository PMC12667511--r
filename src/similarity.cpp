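#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

// Jaro and Jaro-Winkler similarity over byte strings. Inputs are expected to
// be ASCII after normalization (normalize_text folds diacritics), so byte
// comparison equals character comparison.

static double jaro_one(const char *a, int la, const char *b, int lb) {
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  int win = std::max(la, lb) / 2 - 1;
  if (win < 0) win = 0;
  std::vector<char> amatch(la, 0), bmatch(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    int lo = std::max(0, i - win);
    int hi = std::min(lb - 1, i + win);
    for (int j = lo; j <= hi; ++j) {
      if (!bmatch[j] && a[i] == b[j]) {
        amatch[i] = 1;
        bmatch[j] = 1;
        ++m;
        break;
      }
    }
  }
  if (m == 0) return 0.0;
  // transpositions: matched characters out of order, counted pairwise
  int t = 0, k = 0;
  for (int i = 0; i < la; ++i) {
    if (amatch[i]) {
      while (!bmatch[k]) ++k;
      if (a[i] != b[k]) ++t;
      ++k;
    }
  }
  double half_t = t / 2.0;
  return ((double)m / la + (double)m / lb + (m - half_t) / m) / 3.0;
}

static double jw_one(const char *a, int la, const char *b, int lb,
                     double p, int lmax, double boost) {
  double j = jaro_one(a, la, b, lb);
  if (j <= boost) return j;
  int lim = std::min(std::min(la, lb), lmax);
  int l = 0;
  while (l < lim && a[l] == b[l]) ++l;
  return j + l * p * (1.0 - j);
}

// [[Rcpp::export(name = ".jaro_cpp")]]
Rcpp::NumericVector jaro_cpp(Rcpp::CharacterVector a, Rcpp::CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    Rcpp::String sa = a[i % a.size()];
    Rcpp::String sb = b[i % b.size()];
    if (sa == NA_STRING || sb == NA_STRING) {
      out[i] = NA_REAL;
      continue;
    }
    const char *ca = sa.get_cstring();
    const char *cb = sb.get_cstring();
    out[i] = jaro_one(ca, (int)strlen(ca), cb, (int)strlen(cb));
  }
  return out;
}

// [[Rcpp::export(name = ".jaro_winkler_cpp")]]
Rcpp::NumericVector jaro_winkler_cpp(Rcpp::CharacterVector a,
                                     Rcpp::CharacterVector b,
                                     double p, int lmax, double boost) {
  R_xlen_t n = std::max(a.size(), b.size());
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    Rcpp::String sa = a[i % a.size()];
    Rcpp::String sb = b[i % b.size()];
    if (sa == NA_STRING || sb == NA_STRING) {
      out[i] = NA_REAL;
      continue;
    }
    const char *ca = sa.get_cstring();
    const char *cb = sb.get_cstring();
    out[i] = jw_one(ca, (int)strlen(ca), cb, (int)strlen(cb), p, lmax, boost);
  }
  return out;
}
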