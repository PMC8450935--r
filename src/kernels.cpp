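#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double mimg(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

// Sequential hard-core insertion. Proposals are tested in order against the
// already-accepted set (existing points plus earlier accepted proposals) under
// the minimum-image convention; a proposal closer than rmin to any accepted
// point is rejected. Returns a keep flag per proposal. Cell lists keep the
// check O(1) per proposal; boxes too small for a 3x3x3 stencil fall back to
// brute force.
// [[Rcpp::export]]
LogicalVector hardcore_add_cpp(NumericMatrix existing, NumericMatrix proposals,
                               NumericVector box, double rmin) {
  const int ne = existing.nrow(), np = proposals.nrow();
  LogicalVector keep(np);
  const double r2 = rmin * rmin;

  int ncell[3];
  bool use_cells = true;
  for (int k = 0; k < 3; ++k) {
    ncell[k] = (int)std::floor(box[k] / rmin);
    if (ncell[k] < 3) use_cells = false;
  }

  if (!use_cells) {
    std::vector<double> ax, ay, az;
    ax.reserve(ne + np); ay.reserve(ne + np); az.reserve(ne + np);
    for (int i = 0; i < ne; ++i) {
      ax.push_back(existing(i, 0)); ay.push_back(existing(i, 1)); az.push_back(existing(i, 2));
    }
    for (int i = 0; i < np; ++i) {
      bool ok = true;
      for (size_t j = 0; j < ax.size(); ++j) {
        double dx = mimg(proposals(i, 0) - ax[j], box[0]);
        double dy = mimg(proposals(i, 1) - ay[j], box[1]);
        double dz = mimg(proposals(i, 2) - az[j], box[2]);
        if (dx * dx + dy * dy + dz * dz < r2) { ok = false; break; }
      }
      keep[i] = ok;
      if (ok) { ax.push_back(proposals(i, 0)); ay.push_back(proposals(i, 1)); az.push_back(proposals(i, 2)); }
    }
    return keep;
  }

  // flat cell storage: a cell of side >= rmin holds at most 8 points with
  // pairwise separation >= rmin; capacity 14 leaves ample slack
  const int CAP = 14;
  const int ntot = ncell[0] * ncell[1] * ncell[2];
  std::vector<double> cx_(ntot * CAP), cy_(ntot * CAP), cz_(ntot * CAP);
  std::vector<int> cnt(ntot, 0);
  const double bx = box[0], by = box[1], bz = box[2];
  const double hx = bx / 2, hy = by / 2, hz = bz / 2;
  const double sx = ncell[0] / bx, sy = ncell[1] / by, sz = ncell[2] / bz;

  auto cell_idx = [&](double x, double y, double z) {
    int ix = (int)(x * sx); if (ix >= ncell[0]) ix = ncell[0] - 1; if (ix < 0) ix = 0;
    int iy = (int)(y * sy); if (iy >= ncell[1]) iy = ncell[1] - 1; if (iy < 0) iy = 0;
    int iz = (int)(z * sz); if (iz >= ncell[2]) iz = ncell[2] - 1; if (iz < 0) iz = 0;
    return ix + ncell[0] * (iy + ncell[1] * iz);
  };
  auto insert_pt = [&](double x, double y, double z) {
    int c = cell_idx(x, y, z);
    if (cnt[c] >= CAP) stop("hard-core cell overflow");
    int off = c * CAP + cnt[c]++;
    cx_[off] = x; cy_[off] = y; cz_[off] = z;
  };
  for (int i = 0; i < ne; ++i) {
    double x = existing(i, 0); x -= bx * std::floor(x / bx);
    double y = existing(i, 1); y -= by * std::floor(y / by);
    double z = existing(i, 2); z -= bz * std::floor(z / bz);
    insert_pt(x, y, z);
  }

  for (int i = 0; i < np; ++i) {
    double x = proposals(i, 0); x -= bx * std::floor(x / bx);
    double y = proposals(i, 1); y -= by * std::floor(y / by);
    double z = proposals(i, 2); z -= bz * std::floor(z / bz);
    int ix0 = (int)(x * sx); if (ix0 >= ncell[0]) ix0 = ncell[0] - 1;
    int iy0 = (int)(y * sy); if (iy0 >= ncell[1]) iy0 = ncell[1] - 1;
    int iz0 = (int)(z * sz); if (iz0 >= ncell[2]) iz0 = ncell[2] - 1;
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx) {
      int ix = ix0 + dx; if (ix < 0) ix += ncell[0]; else if (ix >= ncell[0]) ix -= ncell[0];
      for (int dy = -1; dy <= 1 && ok; ++dy) {
        int iy = iy0 + dy; if (iy < 0) iy += ncell[1]; else if (iy >= ncell[1]) iy -= ncell[1];
        for (int dz = -1; dz <= 1 && ok; ++dz) {
          int iz = iz0 + dz; if (iz < 0) iz += ncell[2]; else if (iz >= ncell[2]) iz -= ncell[2];
          int c = ix + ncell[0] * (iy + ncell[1] * iz);
          int n_in = cnt[c], off = c * CAP;
          for (int j = 0; j < n_in; ++j) {
            double ddx = x - cx_[off + j];
            if (ddx > hx) ddx -= bx; else if (ddx < -hx) ddx += bx;
            double ddy = y - cy_[off + j];
            if (ddy > hy) ddy -= by; else if (ddy < -hy) ddy += by;
            double ddz = z - cz_[off + j];
            if (ddz > hz) ddz -= bz; else if (ddz < -hz) ddz += bz;
            if (ddx * ddx + ddy * ddy + ddz * ddz < r2) { ok = false; break; }
          }
        }
      }
    }
    keep[i] = ok;
    if (ok) insert_pt(x, y, z);
  }
  return keep;
}

// For each query point, min over reference atoms of (distance - pad_j) under
// the minimum-image convention (pass box <= 0 for no periodicity). pad is
// typically a vdW radius, so the result is a surface margin.
// [[Rcpp::export]]
NumericVector min_margin_cpp(NumericMatrix pts, NumericMatrix refs,
                             NumericVector pad, NumericVector box) {
  const int n = pts.nrow(), m = refs.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = mimg(pts(i, 0) - refs(j, 0), box[0]);
      double dy = mimg(pts(i, 1) - refs(j, 1), box[1]);
      double dz = mimg(pts(i, 2) - refs(j, 2), box[2]);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - pad[j];
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// Index (1-based) of the nearest reference atom for each query point.
// [[Rcpp::export]]
IntegerVector nearest_ref_cpp(NumericMatrix pts, NumericMatrix refs,
                              NumericVector box) {
  const int n = pts.nrow(), m = refs.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = mimg(pts(i, 0) - refs(j, 0), box[0]);
      double dy = mimg(pts(i, 1) - refs(j, 1), box[1]);
      double dz = mimg(pts(i, 2) - refs(j, 2), box[2]);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}
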