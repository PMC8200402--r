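#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy with Chebyshev distance, template length m, tolerance r
// (absolute units). Self-matches excluded. Returns NA when no template
// pairs match at length m.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) return NA_REAL;
  long long A = 0, B = 0; // matches of length m+1 and m
  int nm = n - m;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
      }
      if (d <= r) {
        ++B;
        if (i + m < n && j + m < n) {
          double diff = std::fabs(x[i + m] - x[j + m]);
          if (std::max(d, diff) <= r) ++A;
        }
      }
    }
  }
  if (B == 0 || A == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Approximate entropy (Pincus), template length m, tolerance r.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) return NA_REAL;
  double phi[2] = {0.0, 0.0};
  for (int w = 0; w < 2; ++w) {
    int mm = m + w;
    int nm = n - mm + 1;
    double s = 0.0;
    for (int i = 0; i < nm; ++i) {
      int cnt = 0;
      for (int j = 0; j < nm; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double diff = std::fabs(x[i + k] - x[j + k]);
          if (diff > d) d = diff;
        }
        if (d <= r) ++cnt;
      }
      s += std::log((double)cnt / nm);
    }
    phi[w] = s / nm;
  }
  return phi[0] - phi[1];
}

// Higuchi fractal dimension with maximum delay kmax.
// [[Rcpp::export(name = ".higuchi_cpp")]]
double higuchi_cpp(NumericVector x, int kmax) {
  int n = x.size();
  if (n < kmax * 3) return NA_REAL;
  std::vector<double> lk(kmax), lnk(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    for (int m = 0; m < k; ++m) {
      int np = (n - 1 - m) / k;
      if (np < 1) continue;
      double L = 0.0;
      for (int i = 1; i <= np; ++i)
        L += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      L *= (double)(n - 1) / (np * k);
      Lk += L / k;
    }
    lk[k - 1] = std::log(Lk / k);
    lnk[k - 1] = std::log(1.0 / k);
  }
  // least-squares slope of log L(k) vs log(1/k)
  double mx = 0, my = 0;
  for (int i = 0; i < kmax; ++i) { mx += lnk[i]; my += lk[i]; }
  mx /= kmax; my /= kmax;
  double sxy = 0, sxx = 0;
  for (int i = 0; i < kmax; ++i) {
    sxy += (lnk[i] - mx) * (lk[i] - my);
    sxx += (lnk[i] - mx) * (lnk[i] - mx);
  }
  return sxy / sxx;
}

// Lempel-Ziv complexity (LZ76) of a binary sequence, normalized by
// n / log2(n).
// [[Rcpp::export(name = ".lz_cpp")]]
double lz_cpp(IntegerVector s) {
  int n = s.size();
  if (n < 2) return NA_REAL;
  // Kaspar-Schuster scan
  int cc = 1;
  int l = 1, ii = 0, kk = 1, kkmax = 1;
  while (true) {
    if (s[ii + kk - 1] == s[l + kk - 1]) {
      ++kk;
      if (l + kk > n) { ++cc; break; }
    } else {
      if (kk > kkmax) kkmax = kk;
      ++ii;
      if (ii == l) {
        ++cc;
        l += kkmax;
        if (l + 1 > n) break;
        ii = 0; kk = 1; kkmax = 1;
      } else {
        kk = 1;
      }
    }
  }
  double norm = (double)n / (std::log(n) / std::log(2.0));
  return (double)cc / norm;
}
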