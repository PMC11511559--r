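#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Chebyshev (max-norm) template match up to length m; early abort on first
// coordinate exceeding r.
static inline bool cheb_match(const double* x, int i, int j, int m, double r) {
  for (int k = 0; k < m; ++k) {
    if (std::fabs(x[i + k] - x[j + k]) > r) return false;
  }
  return true;
}

// Approximate entropy, Pincus formulation: phi^m(r) - phi^(m+1)(r) with
// self-matches included and N - m + 1 templates at order m.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const double* xp = REAL(x);
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    const int mm = m + s;
    const int nt = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) {
      int cnt = 0;
      for (int j = 0; j < nt; ++j) {
        if (cheb_match(xp, i, j, mm, r)) ++cnt;
      }
      acc += std::log((double)cnt / (double)nt);
    }
    phi[s] = acc / (double)nt;
  }
  return phi[0] - phi[1];
}

// Sample entropy: -log(A/B) over the N - m templates common to both orders,
// self-matches excluded. Returns +Inf when A == 0, NaN when B == 0.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const double* xp = REAL(x);
  const int nt = n - m; // templates of length m (and m+1) indexed 0..nt-1
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (cheb_match(xp, i, j, m, r)) {
        ++B;
        if (std::fabs(xp[i + m] - xp[j + m]) <= r) ++A;
      }
    }
  }
  if (B == 0) return R_NaN;
  if (A == 0) return R_PosInf;
  return -std::log((double)A / (double)B);
}

// Fused ApEn + SampEn in one symmetric O(n^2/2) pass over template pairs.
// Equals apen_cpp / sampen_cpp exactly (same counting conventions); used by
// the feature bank where both measures are needed per channel.
// [[Rcpp::export(name = ".apen_sampen_cpp")]]
NumericVector apen_sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const double* xp = REAL(x);
  const int nt1 = n - m + 1;  // order-m templates (ApEn)
  const int nt2 = n - m;      // order-(m+1) templates; also SampEn's range
  std::vector<int> cnt1(nt1, 1), cnt2(nt2, 1);  // self-matches included
  long long A = 0, B = 0;
  for (int i = 0; i < nt1 - 1; ++i) {
    for (int j = i + 1; j < nt1; ++j) {
      if (!cheb_match(xp, i, j, m, r)) continue;
      ++cnt1[i]; ++cnt1[j];
      if (j < nt2) {
        ++B;
        if (std::fabs(xp[i + m] - xp[j + m]) <= r) {
          ++A;
          ++cnt2[i]; ++cnt2[j];
        }
      }
    }
  }
  double phi1 = 0.0, phi2 = 0.0;
  for (int i = 0; i < nt1; ++i) phi1 += std::log((double)cnt1[i] / nt1);
  for (int i = 0; i < nt2; ++i) phi2 += std::log((double)cnt2[i] / nt2);
  double apen = phi1 / nt1 - phi2 / nt2;
  double sampen;
  if (B == 0) sampen = R_NaN;
  else if (A == 0) sampen = R_PosInf;
  else sampen = -std::log((double)A / (double)B);
  return NumericVector::create(apen, sampen);
}

// Permutation entropy (natural log) of ordinal patterns of order m and the
// given delay; ties ranked by temporal order of appearance (stable sort).
// [[Rcpp::export(name = ".perm_entropy_cpp")]]
double perm_entropy_cpp(NumericVector x, int m, int delay) {
  const int n = x.size();
  const int nw = n - (m - 1) * delay;
  std::map<std::vector<int>, int> counts;
  std::vector<int> idx(m);
  for (int t = 0; t < nw; ++t) {
    for (int k = 0; k < m; ++k) idx[k] = k;
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return x[t + a * delay] < x[t + b * delay];
    });
    ++counts[idx];
  }
  double h = 0.0;
  for (auto& kv : counts) {
    double p = (double)kv.second / (double)nw;
    h -= p * std::log(p);
  }
  return h;
}

// Higuchi fractal dimension: mean curve length L(k) over k = 1..kmax,
// slope of log(L) against log(1/k).
// [[Rcpp::export(name = ".higuchi_cpp")]]
double higuchi_cpp(NumericVector x, int kmax) {
  const int n = x.size();
  std::vector<double> lk(kmax), lo(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double lsum = 0.0;
    for (int m = 0; m < k; ++m) {
      int nm = (n - 1 - m) / k; // number of increments in this subseries
      if (nm < 1) continue;
      double L = 0.0;
      for (int i = 1; i <= nm; ++i) L += std::fabs(x[m + i * k] - x[m + (i - 1) * k]);
      L *= (double)(n - 1) / ((double)nm * k * k);
      lsum += L;
    }
    lk[k - 1] = std::log(lsum / k);
    lo[k - 1] = std::log(1.0 / k);
  }
  // least-squares slope of lk on lo
  double mx = 0, my = 0;
  for (int k = 0; k < kmax; ++k) { mx += lo[k]; my += lk[k]; }
  mx /= kmax; my /= kmax;
  double sxy = 0, sxx = 0;
  for (int k = 0; k < kmax; ++k) {
    sxy += (lo[k] - mx) * (lk[k] - my);
    sxx += (lo[k] - mx) * (lo[k] - mx);
  }
  return sxy / sxx;
}
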