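// Local regularized thin-plate-spline interpolation on regular lat/lon
// grids. For every target cell center the n_neighbors nearest non-missing
// source cell centers are gathered (window search on the regular source
// grid, with optional longitude wrap across the antimeridian) and a 2-D
// thin-plate spline with kernel phi(r) = r^2 log(r) plus an affine part is
// fitted; `weight` is added to the kernel diagonal as the regularization
// (weight = 0 interpolates exactly through the data points; any weight
// reproduces affine fields exactly because the polynomial part absorbs
// them). Degenerate neighborhoods (singular systems, e.g. collinear
// points) fall back to inverse-distance weighting; the count of fallbacks
// is returned so callers can warn.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double tps_phi(double r) {
  return (r <= 0.0) ? 0.0 : r * r * std::log(r);
}

// [[Rcpp::export]]
List tps_interpolate_cpp(NumericVector src_lat, NumericVector src_lon,
                         NumericMatrix z, NumericVector tgt_lat,
                         NumericVector tgt_lon, double weight,
                         int n_neighbors, bool lon_wrap) {
  const int nr = src_lat.size(), nc = src_lon.size();
  const int tr = tgt_lat.size(), tc = tgt_lon.size();
  const double lat0 = src_lat[0];
  const double lat_step = (nr > 1) ? (src_lat[0] - src_lat[1]) : 1.0;
  const double lon0 = src_lon[0];
  const double lon_step = (nc > 1) ? (src_lon[1] - src_lon[0]) : 1.0;

  NumericMatrix out(tr, tc);
  int n_fallback = 0;

  std::vector<int> cand_r, cand_c;
  arma::mat A; arma::vec rhs, sol;

  for (int ti = 0; ti < tr; ++ti) {
    const double tlat = tgt_lat[ti];
    int r0 = (int)std::lround((lat0 - tlat) / lat_step);
    if (r0 < 0) r0 = 0; if (r0 >= nr) r0 = nr - 1;
    for (int tj = 0; tj < tc; ++tj) {
      const double tlon = tgt_lon[tj];
      int c0 = (int)std::lround((tlon - lon0) / lon_step);
      if (lon_wrap) {
        c0 = ((c0 % nc) + nc) % nc;
      } else {
        if (c0 < 0) c0 = 0; if (c0 >= nc) c0 = nc - 1;
      }

      // expand a square window until enough valid cells, then one extra ring
      int half = (int)std::ceil(std::sqrt((double)n_neighbors) / 2.0) + 1;
      int found = 0;
      cand_r.clear(); cand_c.clear();
      for (;;) {
        cand_r.clear(); cand_c.clear(); found = 0;
        int rlo = std::max(0, r0 - half), rhi = std::min(nr - 1, r0 + half);
        int clo = c0 - half, chi = c0 + half;
        if (!lon_wrap) { clo = std::max(0, clo); chi = std::min(nc - 1, chi); }
        if (chi - clo + 1 > nc) { clo = 0; chi = nc - 1; }
        for (int r = rlo; r <= rhi; ++r)
          for (int cc = clo; cc <= chi; ++cc) {
            int c = lon_wrap ? ((cc % nc) + nc) % nc : cc;
            if (!NumericMatrix::is_na(z(r, c))) {
              cand_r.push_back(r); cand_c.push_back(c); ++found;
            }
          }
        bool whole = (rlo == 0 && rhi == nr - 1 &&
                      (chi - clo + 1) >= nc);
        if (found >= n_neighbors || whole) break;
        half *= 2;
      }
      if (found == 0) { out(ti, tj) = NA_REAL; continue; }

      const int m = std::min(found, n_neighbors);
      // local coordinates relative to the target point
      std::vector<double> x(found), y(found), d2(found);
      std::vector<int> idx(found);
      for (int k = 0; k < found; ++k) {
        double dx = src_lon[cand_c[k]] - tlon;
        if (lon_wrap) {
          while (dx > 180.0) dx -= 360.0;
          while (dx < -180.0) dx += 360.0;
        }
        double dy = src_lat[cand_r[k]] - tlat;
        x[k] = dx; y[k] = dy; d2[k] = dx * dx + dy * dy;
        idx[k] = k;
      }
      std::partial_sort(idx.begin(), idx.begin() + m, idx.end(),
                        [&](int a, int b) { return d2[a] < d2[b]; });

      A.zeros(m + 3, m + 3);
      rhs.zeros(m + 3);
      for (int a = 0; a < m; ++a) {
        int ka = idx[a];
        for (int b = a + 1; b < m; ++b) {
          int kb = idx[b];
          double dx = x[ka] - x[kb], dy = y[ka] - y[kb];
          double p = tps_phi(std::sqrt(dx * dx + dy * dy));
          A(a, b) = p; A(b, a) = p;
        }
        A(a, a) = weight;
        A(a, m) = 1.0; A(a, m + 1) = x[ka]; A(a, m + 2) = y[ka];
        A(m, a) = 1.0; A(m + 1, a) = x[ka]; A(m + 2, a) = y[ka];
        rhs(a) = z(cand_r[ka], cand_c[ka]);
      }
      bool ok = arma::solve(sol, A, rhs,
                            arma::solve_opts::no_approx);
      double val;
      if (ok && sol.is_finite()) {
        val = sol(m); // affine part at local origin (target point)
        for (int a = 0; a < m; ++a)
          val += sol(a) * tps_phi(std::sqrt(d2[idx[a]]));
      } else {
        ++n_fallback;
        double wsum = 0.0, vsum = 0.0; bool exact = false;
        for (int a = 0; a < m; ++a) {
          int ka = idx[a];
          if (d2[ka] <= 1e-24) {
            val = z(cand_r[ka], cand_c[ka]); exact = true; break;
          }
          double w = 1.0 / d2[ka];
          wsum += w; vsum += w * z(cand_r[ka], cand_c[ka]);
        }
        if (!exact) val = vsum / wsum;
      }
      out(ti, tj) = val;
    }
  }
  return List::create(_["values"] = out, _["n_idw_fallback"] = n_fallback);
}
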