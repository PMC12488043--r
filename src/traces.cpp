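#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Find all peak traces for one (peptide mass, charge) in one MS1 run.
//
// peaks are given sorted ascending by m/z. A scan is "valid" if it holds a
// peak within ppm_tol of the most abundant theoretical isotopologue and the
// cosine between the observed isotopologue intensities (absent = 0) and the
// theoretical abundances is at least min_cos. Traces are runs of valid
// scans whose scan indices differ by at most gap_tol + 1. The apex is the
// member scan with the maximal sum of log-intensities over matched
// isotopologue peaks (ties -> lowest scan index).
//
// Returns a list with:
//   traces: numeric matrix, one row per trace, columns
//     (start_scan, end_scan_excl, apex_scan, apex_rt, intensity,
//      envelope_cos, mz_obs, n_valid_scans)
//   detail (only when detail = true): per-trace list with members
//     scans, rt, log_sum, cos, iso (n_valid x K intensity matrix)
// [[Rcpp::export]]
List find_traces_cpp(NumericVector peak_mz, NumericVector peak_int,
                     IntegerVector peak_scan, NumericVector scan_rt,
                     NumericVector iso_mz, NumericVector theo_ab,
                     int most_idx, double ppm_tol, double min_cos,
                     int gap_tol, bool detail) {
  const int n_scans = scan_rt.size();
  const int K = iso_mz.size();
  const double *mz = REAL(peak_mz);
  const int n_peaks = peak_mz.size();

  std::vector<double> intens((size_t)K * n_scans, 0.0);
  std::vector<double> mz_most(n_scans, 0.0);

  for (int k = 0; k < K; ++k) {
    const double lo = iso_mz[k] * (1.0 - ppm_tol * 1e-6);
    const double hi = iso_mz[k] * (1.0 + ppm_tol * 1e-6);
    const double *it_lo = std::lower_bound(mz, mz + n_peaks, lo);
    const double *it_hi = std::upper_bound(mz, mz + n_peaks, hi);
    for (const double *p = it_lo; p < it_hi; ++p) {
      const int idx = (int)(p - mz);
      const int s = peak_scan[idx];
      if (s < 0 || s >= n_scans) continue;
      double &cur = intens[(size_t)k * n_scans + s];
      if (peak_int[idx] > cur) {
        cur = peak_int[idx];
        if (k == most_idx) mz_most[s] = peak_mz[idx];
      }
    }
  }

  double ab_norm = 0.0;
  for (int k = 0; k < K; ++k) ab_norm += theo_ab[k] * theo_ab[k];
  ab_norm = std::sqrt(ab_norm);

  std::vector<int> valid;
  std::vector<double> vcos, vlog;
  valid.reserve(64);
  for (int s = 0; s < n_scans; ++s) {
    const double base = intens[(size_t)most_idx * n_scans + s];
    if (base <= 0.0) continue;
    double dot = 0.0, xn = 0.0, lg = 0.0;
    for (int k = 0; k < K; ++k) {
      const double x = intens[(size_t)k * n_scans + s];
      dot += x * theo_ab[k];
      xn += x * x;
      if (x > 0.0) lg += std::log(x);
    }
    const double cosv = (xn > 0.0) ? dot / (std::sqrt(xn) * ab_norm) : 0.0;
    if (cosv >= min_cos) {
      valid.push_back(s);
      vcos.push_back(cosv);
      vlog.push_back(lg);
    }
  }

  std::vector<int> t_start;  // index into `valid` where each trace begins
  std::vector<int> t_len;
  for (size_t i = 0; i < valid.size(); ++i) {
    if (i == 0 || valid[i] - valid[i - 1] > gap_tol + 1) {
      t_start.push_back((int)i);
      t_len.push_back(1);
    } else {
      ++t_len.back();
    }
  }

  const int n_traces = (int)t_start.size();
  NumericMatrix out(n_traces, 8);
  List det(detail ? n_traces : 0);
  for (int t = 0; t < n_traces; ++t) {
    const int b = t_start[t], len = t_len[t];
    int apex_i = b;
    for (int i = b + 1; i < b + len; ++i)
      if (vlog[i] > vlog[apex_i]) apex_i = i;
    const int apex_scan = valid[apex_i];
    double apex_int = 0.0;
    for (int k = 0; k < K; ++k)
      apex_int += intens[(size_t)k * n_scans + apex_scan];
    out(t, 0) = valid[b];
    out(t, 1) = valid[b + len - 1] + 1;
    out(t, 2) = apex_scan;
    out(t, 3) = scan_rt[apex_scan];
    out(t, 4) = apex_int;
    out(t, 5) = vcos[apex_i];
    out(t, 6) = mz_most[apex_scan];
    out(t, 7) = len;
    if (detail) {
      IntegerVector sc(len);
      NumericVector rt(len), ls(len), cs(len);
      NumericMatrix iso(len, K);
      for (int i = 0; i < len; ++i) {
        sc[i] = valid[b + i];
        rt[i] = scan_rt[valid[b + i]];
        ls[i] = vlog[b + i];
        cs[i] = vcos[b + i];
        for (int k = 0; k < K; ++k)
          iso(i, k) = intens[(size_t)k * n_scans + valid[b + i]];
      }
      det[t] = List::create(Named("scans") = sc, Named("rt") = rt,
                            Named("log_sum") = ls, Named("cos") = cs,
                            Named("iso") = iso);
    }
  }
  colnames(out) = CharacterVector::create(
      "start_scan", "end_scan_excl", "apex_scan", "apex_rt", "intensity",
      "envelope_cos", "mz_obs", "n_valid_scans");
  if (detail) return List::create(Named("traces") = out,
                                  Named("detail") = det);
  return List::create(Named("traces") = out);
}

// k-nearest-anchor median shift: for each query RT, take the k anchors
// nearest in donor RT (ties prefer the earlier anchor) and return the
// median of their acceptor-minus-donor shifts. anchor_d is sorted.
// [[Rcpp::export]]
NumericVector knn_median_shift_cpp(NumericVector anchor_d,
                                   NumericVector shift, int k,
                                   NumericVector t) {
  const int n = anchor_d.size();
  const int m = t.size();
  const int kk = std::min(k, n);
  NumericVector out(m);
  std::vector<double> sel(kk);
  for (int q = 0; q < m; ++q) {
    const double x = t[q];
    int ri = (int)(std::upper_bound(anchor_d.begin(), anchor_d.end(), x) -
                   anchor_d.begin());
    int li = ri - 1;
    for (int j = 0; j < kk; ++j) {
      bool take_left;
      if (li < 0) take_left = false;
      else if (ri >= n) take_left = true;
      else take_left = (x - anchor_d[li]) <= (anchor_d[ri] - x);
      if (take_left) sel[j] = shift[li--];
      else sel[j] = shift[ri++];
    }
    std::sort(sel.begin(), sel.end());
    out[q] = (kk % 2) ? sel[kk / 2]
                      : 0.5 * (sel[kk / 2 - 1] + sel[kk / 2]);
  }
  return out;
}
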