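#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-segment descriptor set (SDS) over half-overlapping windows.
//
// xyz:  n x 3 acceleration matrix (g), axis order AP, ML, Ver.
// len:  window length in samples; nseg windows start at floor(i*len/2).
//
// Returns nseg x 11 matrix: vm, rmsr_ap, rmsr_ml, rmsr_ver,
// disp_ap, disp_ml, disp_ver, ar_ap, ar_ml, ar_ver, valid.
// A segment is flagged invalid (valid = 0) when all samples are exactly
// zero on all axes, in which case the normalised RMS is undefined.
//
// Dispersion per axis: within-segment z-scores (population SD); samples
// with |z| > 2 on any axis with positive SD are excluded; the mean
// absolute pairwise difference of the remaining z-scores is computed by
// the sorted prefix-sum identity
//   sum_{pairs} |z_a - z_b| = sum_k (2k - m - 1) z_(k)
// over the m sorted valid values, divided by S = m(m-1)/2 unordered
// pairs.  Axes with zero SD, or fewer than 2 valid samples, get 0.
// [[Rcpp::export(name = ".sds_descriptors_cpp")]]
NumericMatrix sds_descriptors_cpp(NumericMatrix xyz, int len, int nseg) {
  const int n = xyz.nrow();
  if (len < 1) stop("window length must be at least 1 sample");
  if (nseg < 0) stop("negative segment count");
  NumericMatrix out(nseg, 11);
  std::vector<double> z[3];
  for (int a = 0; a < 3; ++a) z[a].resize(len);
  std::vector<bool> valid(len);
  std::vector<double> zv(len);

  const double *col[3] = {&xyz(0, 0), &xyz(0, 1), &xyz(0, 2)};

  for (int s = 0; s < nseg; ++s) {
    const long start = ((long)s * len) / 2;
    if (start + len > n) stop("segment exceeds signal length");
    double vm = 0.0, ssq[3], mean[3], mn[3], mx[3];
    for (int a = 0; a < 3; ++a) {
      ssq[a] = 0.0; mean[a] = 0.0;
      mn[a] = R_PosInf; mx[a] = R_NegInf;
    }
    const double *x0 = col[0] + start, *x1 = col[1] + start,
                 *x2 = col[2] + start;
    for (int t = 0; t < len; ++t) {
      const double v0 = x0[t], v1 = x1[t], v2x = x2[t];
      if (!R_finite(v0) || !R_finite(v1) || !R_finite(v2x))
        stop("non-finite sample in segment");
      ssq[0] += v0 * v0; ssq[1] += v1 * v1; ssq[2] += v2x * v2x;
      mean[0] += v0; mean[1] += v1; mean[2] += v2x;
      if (v0 < mn[0]) mn[0] = v0;
      if (v0 > mx[0]) mx[0] = v0;
      if (v1 < mn[1]) mn[1] = v1;
      if (v1 > mx[1]) mx[1] = v1;
      if (v2x < mn[2]) mn[2] = v2x;
      if (v2x > mx[2]) mx[2] = v2x;
      vm += std::sqrt(v0 * v0 + v1 * v1 + v2x * v2x);
    }
    out(s, 0) = vm / len;
    // normalised RMS: rms_dir / sqrt(sum rms^2)
    double denom2 = (ssq[0] + ssq[1] + ssq[2]) / len;
    bool ok = denom2 > 0.0;
    double denom = ok ? std::sqrt(denom2) : 1.0;
    for (int a = 0; a < 3; ++a)
      out(s, 1 + a) = ok ? std::sqrt(ssq[a] / len) / denom : 0.0;
    out(s, 10) = ok ? 1.0 : 0.0;
    // acceleration range
    for (int a = 0; a < 3; ++a) out(s, 7 + a) = mx[a] - mn[a];
    // dispersion
    double sd[3];
    for (int a = 0; a < 3; ++a) {
      mean[a] /= len;
      double var = ssq[a] / len - mean[a] * mean[a];
      sd[a] = var > 0.0 ? std::sqrt(var) : 0.0;
      const double *xa = col[a] + start;
      if (sd[a] > 0.0) {
        const double inv = 1.0 / sd[a], mu = mean[a];
        for (int t = 0; t < len; ++t) z[a][t] = (xa[t] - mu) * inv;
      } else
        for (int t = 0; t < len; ++t) z[a][t] = 0.0;
    }
    int m = 0;
    for (int t = 0; t < len; ++t) {
      bool keep = true;
      for (int a = 0; a < 3; ++a)
        if (sd[a] > 0.0 && std::fabs(z[a][t]) > 2.0) { keep = false; break; }
      valid[t] = keep;
      if (keep) ++m;
    }
    for (int a = 0; a < 3; ++a) {
      if (m < 2 || sd[a] <= 0.0) { out(s, 4 + a) = 0.0; continue; }
      int j = 0;
      for (int t = 0; t < len; ++t) if (valid[t]) zv[j++] = z[a][t];
      std::sort(zv.begin(), zv.begin() + m);
      double acc = 0.0;
      for (int k = 0; k < m; ++k) acc += (2.0 * (k + 1) - m - 1.0) * zv[k];
      const double pairs = (double)m * (m - 1) / 2.0;
      out(s, 4 + a) = acc / pairs;
    }
  }
  colnames(out) = CharacterVector::create(
      "vm", "rmsr_ap", "rmsr_ml", "rmsr_ver", "disp_ap", "disp_ml",
      "disp_ver", "ar_ap", "ar_ml", "ar_ver", "valid");
  return out;
}

// Nearest-medoid assignment under Euclidean distance.
// pts: n x p, med: k x p (same coordinate system, typically standardized).
// Returns 1-based assignments, per-point squared distance, and total WCSS.
// [[Rcpp::export(name = ".nearest_medoid_cpp")]]
List nearest_medoid_cpp(NumericMatrix pts, NumericMatrix med) {
  const int n = pts.nrow(), p = pts.ncol(), k = med.nrow();
  if (med.ncol() != p) stop("dimension mismatch between points and medoids");
  if (k < 1) stop("no medoids");
  IntegerVector assign(n);
  NumericVector d2(n);
  double wcss = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bi = 0;
    for (int c = 0; c < k; ++c) {
      double acc = 0.0;
      for (int j = 0; j < p; ++j) {
        const double d = pts(i, j) - med(c, j);
        acc += d * d;
        if (acc >= best) break;
      }
      if (acc < best) { best = acc; bi = c; }
    }
    assign[i] = bi + 1;
    d2[i] = best;
    wcss += best;
  }
  return List::create(_["cluster"] = assign, _["d2"] = d2, _["wcss"] = wcss);
}
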