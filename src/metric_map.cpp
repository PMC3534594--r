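// Exhaustive entropy evaluation over the two-interval heart-rate grid.
//
// For every (hr1, hr2) pair: assign each flow-encoded k-space line to a
// cardiac phase bin under the hypothesis (phase continuous across the
// acquisition midpoint), complex-average multiple hits per (k-row, phase)
// cell, fill empty cells from the nearest occupied cyclic phase bin of the
// same k-row (forward preferred on ties), inverse-Fourier-transform each
// phase and accumulate the Shannon entropy of the ROI magnitudes across
// phases.
//
// Two exact factorisations keep the grid affordable:
//  * the inverse FFT along the readout (line) dimension commutes with the
//    complex averaging, so every measured line is transformed once up front
//    and only the image columns the ROI touches are kept;
//  * first-half cell sums depend only on hr1 and are cached per grid row.
//
// Must stay numerically equivalent to the R reference path
// (binMeasurements -> reconstructCine -> imageEntropy on encode 2); the
// test suite asserts this on toy acquisitions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".entropy_grid_cpp")]]
Rcpp::NumericMatrix entropy_grid_cpp(const arma::cx_mat& lines,
                                     const arma::ivec& krow,
                                     const arma::vec& time_s,
                                     double t_mid,
                                     const arma::vec& hr1_grid,
                                     const arma::vec& hr2_grid,
                                     int n_phases,
                                     const arma::umat& roi_xy,  // 0-based (x, y)
                                     int N) {
  const uword n_meas = lines.n_rows;
  if (krow.n_elem != n_meas || time_s.n_elem != n_meas)
    Rcpp::stop("per-line vectors must match the number of lines");
  if ((int)lines.n_cols != N) Rcpp::stop("line length must equal N");
  if (roi_xy.n_rows == 0) Rcpp::stop("ROI is empty");

  // unique image columns (y) the ROI touches, and the ROI x-indices per column
  std::vector<int> ycols;
  std::vector<std::vector<uword>> xs_per_col;
  for (uword j = 0; j < roi_xy.n_rows; ++j) {
    int y = (int)roi_xy(j, 1);
    size_t k = 0;
    for (; k < ycols.size(); ++k) if (ycols[k] == y) break;
    if (k == ycols.size()) { ycols.push_back(y); xs_per_col.emplace_back(); }
    xs_per_col[k].push_back(roi_xy(j, 0));
  }
  const uword ny = ycols.size();

  // inverse FFT along the readout dimension, once per measured line,
  // restricted to the ROI columns (ifft normalises by 1/N)
  cx_mat hybrid_full = ifft(lines.st()).st();  // n_meas x N
  cx_mat hybrid(n_meas, ny);
  for (uword k = 0; k < ny; ++k) hybrid.col(k) = hybrid_full.col(ycols[k]);
  hybrid_full.reset();

  std::vector<uword> first, second;
  first.reserve(n_meas); second.reserve(n_meas);
  for (uword i = 0; i < n_meas; ++i)
    (time_s[i] <= t_mid ? first : second).push_back(i);

  const uword ncell = (uword)N * (uword)n_phases;
  Rcpp::NumericMatrix out(hr1_grid.n_elem, hr2_grid.n_elem);

  cx_mat A1(ncell, ny), A(ncell, ny);
  uvec c1(ncell), cnt(ncell);
  cx_mat H(N, ny);
  std::vector<double> mags(roi_xy.n_rows * n_phases);

  for (uword i1 = 0; i1 < hr1_grid.n_elem; ++i1) {
    const double hr1 = hr1_grid[i1];
    A1.zeros(); c1.zeros();
    for (uword m : first) {
      double ph = time_s[m] * hr1 / 60.0;
      ph -= std::floor(ph);
      int b = std::min((int)(ph * n_phases), n_phases - 1);
      const uword cell = (uword)krow[m] + (uword)N * (uword)b;
      A1.row(cell) += hybrid.row(m);
      c1[cell] += 1;
    }
    const double phase_mid = t_mid * hr1 / 60.0;

    for (uword i2 = 0; i2 < hr2_grid.n_elem; ++i2) {
      const double hr2 = hr2_grid[i2];
      A = A1; cnt = c1;
      for (uword m : second) {
        double ph = phase_mid + (time_s[m] - t_mid) * hr2 / 60.0;
        ph -= std::floor(ph);
        int b = std::min((int)(ph * n_phases), n_phases - 1);
        const uword cell = (uword)krow[m] + (uword)N * (uword)b;
        A.row(cell) += hybrid.row(m);
        cnt[cell] += 1;
      }
      size_t mi = 0;
      for (int b = 0; b < n_phases; ++b) {
        for (int r = 0; r < N; ++r) {
          uword cell = (uword)r + (uword)N * (uword)b;
          uword src_cell = cell;
          if (cnt[cell] == 0) {
            int src = -1;
            for (int d = 1; d < n_phases; ++d) {   // forward preferred
              int fwd = (b + d) % n_phases;
              int bwd = ((b - d) % n_phases + n_phases) % n_phases;
              if (cnt[(uword)r + (uword)N * (uword)fwd] > 0) { src = fwd; break; }
              if (cnt[(uword)r + (uword)N * (uword)bwd] > 0) { src = bwd; break; }
            }
            if (src < 0)
              Rcpp::stop("k-row %d has no measurements in any phase bin", r);
            src_cell = (uword)r + (uword)N * (uword)src;
          }
          H.row(r) = A.row(src_cell) / (double)cnt[src_cell];
        }
        cx_mat img = ifft(H);  // remaining transform along phase encode
        for (uword k = 0; k < ny; ++k)
          for (uword x : xs_per_col[k])
            mags[mi++] = std::abs(img(x, k));
      }
      double s = 0.0;
      for (double m : mags) s += m;
      if (s <= 0.0)
        Rcpp::stop("entropy undefined: all ROI magnitudes are zero");
      double e = 0.0;
      for (double m : mags) {
        if (m > 0.0) { double p = m / s; e -= p * std::log(p); }
      }
      out(i1, i2) = e;
    }
  }
  return out;
}
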