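#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rotate a square raster about its center by angle_deg (bilinear).
// Positive angles bring the world bearing angle_deg to the top of the view:
// the output pixel at offset (dr, dc) from the center samples the source at
// offset (cos*dr + sin*dc, -sin*dr + cos*dc). Output cells whose pre-image
// falls outside the source, or touches an NA source cell, are NA; they are
// discarded by the circular field-of-view mask downstream.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_bilinear(NumericMatrix src, double angle_deg) {
  const int n = src.nrow();
  if (src.ncol() != n) stop("rotation requires a square raster");
  NumericMatrix out(n, n);
  const double c0 = (n + 1) / 2.0;
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  for (int j = 0; j < n; ++j) {
    const double dc = (j + 1) - c0;
    for (int i = 0; i < n; ++i) {
      const double dr = (i + 1) - c0;
      double sr = c0 + ct * dr + st * dc;
      double sc = c0 - st * dr + ct * dc;
      if (sr < 0.5 || sr > n + 0.5 || sc < 0.5 || sc > n + 0.5) {
        out(i, j) = NA_REAL;
        continue;
      }
      // half-pixel rim between the pixel-center domain and the square edge
      // clamps to the edge pixels, so the inscribed circle is always defined
      if (sr < 1.0) sr = 1.0; else if (sr > n) sr = n;
      if (sc < 1.0) sc = 1.0; else if (sc > n) sc = n;
      int r0 = (int)std::floor(sr), c0i = (int)std::floor(sc);
      if (r0 >= n) r0 = n - 1;  // sr == n exactly
      if (c0i >= n) c0i = n - 1;
      const double fr = sr - r0, fc = sc - c0i;
      const double v00 = src(r0 - 1, c0i - 1);
      const double v10 = src(r0, c0i - 1);
      const double v01 = src(r0 - 1, c0i);
      const double v11 = src(r0, c0i);
      if (ISNAN(v00) || ISNAN(v10) || ISNAN(v01) || ISNAN(v11)) {
        out(i, j) = NA_REAL;
      } else {
        out(i, j) = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                    fr * ((1 - fc) * v10 + fc * v11);
      }
    }
  }
  return out;
}

// Sum of absolute differences between each row of M and the vector v.
// M is n_views x n_pixels (one stored view per row, masked cells only).
// [[Rcpp::export]]
NumericVector cpp_absdiff_rowsums(NumericMatrix M, NumericVector v) {
  const int n = M.nrow(), p = M.ncol();
  if (v.size() != p) stop("pixel count mismatch");
  NumericVector out(n);
  for (int j = 0; j < p; ++j) {
    const double vj = v[j];
    for (int i = 0; i < n; ++i) out[i] += std::fabs(M(i, j) - vj);
  }
  return out;
}

// For each row i of V (one view per row), the summed image difference to all
// other rows: out[i] = sum_j sum_p |V(i,p) - V(j,p)|.
// [[Rcpp::export]]
NumericVector cpp_pairwise_diff_totals(NumericMatrix V) {
  const int n = V.nrow(), p = V.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += std::fabs(V(i, k) - V(j, k));
      out[i] += s;
      out[j] += s;
    }
  }
  return out;
}

// Full rotation-scan kernel: for each angle, rotate the raw crop, optionally
// histogram-equalize (rank -> 255*cdf over defined cells), block-mean
// downsample to out_res, quantize to gray_levels, apply the circular mask in
// column-major order, and score against every row of the memory matrix V.
// Returns per-angle minimum scores and memory indices (1-based) plus the sum
// of all rotation x memory scores. Exact 90-degree multiples snap to exact
// index permutations (no interpolation error).
// [[Rcpp::export]]
List cpp_scan_rotations(NumericMatrix crop, NumericVector angles_deg,
                        NumericMatrix V, LogicalMatrix mask,
                        int out_res, int gray_levels, bool equalize) {
  const int n = crop.nrow();
  if (crop.ncol() != n) stop("crop must be square");
  const int n_ang = angles_deg.size();
  const int n_view = V.nrow();
  const int n_pix = V.ncol();
  const double c0 = (n + 1) / 2.0;

  // downsample bin index per source row/col (0-based)
  std::vector<int> bin(n);
  for (int i = 0; i < n; ++i) bin[i] = (int)((long long)i * out_res / n);

  // masked cell list in column-major order
  std::vector<int> mi, mj;
  for (int j = 0; j < out_res; ++j)
    for (int i = 0; i < out_res; ++i)
      if (mask(i, j)) { mi.push_back(i); mj.push_back(j); }
  if ((int)mi.size() != n_pix) stop("mask size does not match memory pixels");

  // contiguous per-view pixel blocks for the scoring loop
  std::vector<double> Vt((size_t)n_view * n_pix);
  for (int m = 0; m < n_view; ++m)
    for (int t = 0; t < n_pix; ++t)
      Vt[(size_t)m * n_pix + t] = V(m, t);

  std::vector<double> rot(n * n), sorted;
  std::vector<double> dsum(out_res * out_res);
  std::vector<int> dcnt(out_res * out_res);
  std::vector<double> vq(n_pix);
  NumericVector min_score(n_ang), total(1);
  IntegerVector min_index(n_ang);
  double grand_total = 0.0;

  for (int a = 0; a < n_ang; ++a) {
    double ang = angles_deg[a] - 360.0 * std::floor(angles_deg[a] / 360.0);
    double ct, st;
    const double r90 = std::fabs(ang / 90.0 - std::floor(ang / 90.0 + 0.5));
    if (r90 < 1e-12) {
      const int k = ((int)std::floor(ang / 90.0 + 0.5)) % 4;
      ct = (k == 0) ? 1.0 : (k == 2) ? -1.0 : 0.0;
      st = (k == 1) ? 1.0 : (k == 3) ? -1.0 : 0.0;
    } else {
      const double th = ang * M_PI / 180.0;
      ct = std::cos(th); st = std::sin(th);
    }
    // rotate
    int n_ok = 0;
    for (int j = 0; j < n; ++j) {
      const double dc = (j + 1) - c0;
      for (int i = 0; i < n; ++i) {
        const double dr = (i + 1) - c0;
        const double sr = c0 + ct * dr + st * dc;
        const double sc = c0 - st * dr + ct * dc;
        double val = NA_REAL;
        if (sr >= 0.5 && sr <= n + 0.5 && sc >= 0.5 && sc <= n + 0.5) {
          double srx = sr < 1.0 ? 1.0 : (sr > n ? (double)n : sr);
          double scx = sc < 1.0 ? 1.0 : (sc > n ? (double)n : sc);
          int r0 = (int)std::floor(srx), c0i = (int)std::floor(scx);
          if (r0 >= n) r0 = n - 1;
          if (c0i >= n) c0i = n - 1;
          const double fr = srx - r0, fc = scx - c0i;
          val = (1 - fr) * ((1 - fc) * crop(r0 - 1, c0i - 1) +
                            fc * crop(r0 - 1, c0i)) +
                fr * ((1 - fc) * crop(r0, c0i - 1) + fc * crop(r0, c0i));
          ++n_ok;
        }
        rot[i + (size_t)n * j] = val;
      }
    }
    // equalize (rank-based cdf remap, ties share their maximal rank)
    if (equalize) {
      sorted.clear();
      sorted.reserve(n_ok);
      for (size_t t = 0; t < rot.size(); ++t)
        if (!ISNAN(rot[t])) sorted.push_back(rot[t]);
      std::sort(sorted.begin(), sorted.end());
      const double scale = 255.0 / n_ok;
      for (size_t t = 0; t < rot.size(); ++t) {
        if (!ISNAN(rot[t])) {
          const int r = std::upper_bound(sorted.begin(), sorted.end(),
                                         rot[t]) - sorted.begin();
          rot[t] = r * scale;
        }
      }
    }
    // block-mean downsample
    std::fill(dsum.begin(), dsum.end(), 0.0);
    std::fill(dcnt.begin(), dcnt.end(), 0);
    for (int j = 0; j < n; ++j) {
      const int bj = bin[j];
      for (int i = 0; i < n; ++i) {
        const double v = rot[i + (size_t)n * j];
        if (!ISNAN(v)) {
          dsum[bin[i] + out_res * bj] += v;
          dcnt[bin[i] + out_res * bj] += 1;
        }
      }
    }
    // quantize + mask
    for (int t = 0; t < n_pix; ++t) {
      const int idx = mi[t] + out_res * mj[t];
      if (dcnt[idx] == 0) { vq[t] = NA_REAL; continue; }
      int lev = (int)std::floor(dsum[idx] / dcnt[idx] * gray_levels / 256.0);
      if (lev > gray_levels - 1) lev = gray_levels - 1;
      vq[t] = lev;
    }
    // score against every memory view
    double best = R_PosInf;
    int best_i = 0;
    for (int m = 0; m < n_view; ++m) {
      const double *vm = &Vt[(size_t)m * n_pix];
      double s = 0.0;
      for (int t = 0; t < n_pix; ++t) s += std::fabs(vm[t] - vq[t]);
      grand_total += s;
      if (s < best) { best = s; best_i = m; }
    }
    min_score[a] = best;
    min_index[a] = best_i + 1;
  }
  return List::create(_["min_score"] = min_score,
                      _["min_index"] = min_index,
                      _["total"] = grand_total,
                      _["n_comparisons"] = (double)n_ang * n_view);
}
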