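#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Pixel grid convention (shared with the R side):
//   row r (1-based) has patient z = originZ - (r - 1) * spacingRow   (row 1 = most superior)
//   col c (1-based) has patient x = originX + (c - 1) * spacingCol   (col 1 = most patient-right)
// originX/originZ are the patient coordinates of the CENTER of pixel [1, 1].

// Orthographic coronal z-buffer render: project triangles along the
// anterior-posterior (y) axis, keeping the most anterior (max y) surface
// depth per covered pixel. Returns a numeric matrix with NA_REAL outside
// the silhouette and the anterior depth (mm) inside.
// [[Rcpp::export]]
NumericMatrix cpp_render_mesh(NumericVector vx, NumericVector vy, NumericVector vz,
                              IntegerMatrix faces,
                              double originX, double originZ,
                              double spacingCol, double spacingRow,
                              int nrow, int ncol) {
  NumericMatrix depth(nrow, ncol);
  std::fill(depth.begin(), depth.end(), NA_REAL);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    const int i0 = faces(f, 0) - 1, i1 = faces(f, 1) - 1, i2 = faces(f, 2) - 1;
    const double x0 = vx[i0], x1 = vx[i1], x2 = vx[i2];
    const double z0 = vz[i0], z1 = vz[i1], z2 = vz[i2];
    const double y0 = vy[i0], y1 = vy[i1], y2 = vy[i2];
    // pixel index range covered by the triangle bounding box
    const double xmin = std::min(x0, std::min(x1, x2));
    const double xmax = std::max(x0, std::max(x1, x2));
    const double zmin = std::min(z0, std::min(z1, z2));
    const double zmax = std::max(z0, std::max(z1, z2));
    int clo = (int)std::ceil((xmin - originX) / spacingCol);
    int chi = (int)std::floor((xmax - originX) / spacingCol);
    int rlo = (int)std::ceil((originZ - zmax) / spacingRow);
    int rhi = (int)std::floor((originZ - zmin) / spacingRow);
    if (clo < 0) clo = 0;
    if (chi > ncol - 1) chi = ncol - 1;
    if (rlo < 0) rlo = 0;
    if (rhi > nrow - 1) rhi = nrow - 1;
    if (clo > chi || rlo > rhi) continue;
    const double dX1 = x1 - x0, dZ1 = z1 - z0;
    const double dX2 = x2 - x0, dZ2 = z2 - z0;
    const double det = dX1 * dZ2 - dX2 * dZ1;
    if (det == 0.0) continue; // degenerate in projection
    for (int r = rlo; r <= rhi; ++r) {
      const double pz = originZ - r * spacingRow;
      for (int c = clo; c <= chi; ++c) {
        const double px = originX + c * spacingCol;
        const double u = ((px - x0) * dZ2 - (pz - z0) * dX2) / det;
        const double v = ((pz - z0) * dX1 - (px - x0) * dZ1) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        const double d = y0 + u * (y1 - y0) + v * (y2 - y0);
        double &cur = depth(r, c);
        if (NumericVector::is_na(cur) || d > cur) cur = d;
      }
    }
  }
  return depth;
}

// Even-odd point-in-polygon test for every pixel center of a grid.
// Polygon vertices in patient mm coordinates (closed implicitly). Pixel
// centers exactly on the boundary count as inside: the closed rule is
// mirror-symmetric, so laterality-flipped inputs rasterize to exact mirror
// images even when an edge coincides with a pixel-center line.
// [[Rcpp::export]]
LogicalMatrix cpp_polygon_mask(NumericVector px, NumericVector pz,
                               double originX, double originZ,
                               double spacingCol, double spacingRow,
                               int nrow, int ncol) {
  const int nv = px.size();
  const double eps = 1e-9;
  LogicalMatrix mask(nrow, ncol);
  for (int r = 0; r < nrow; ++r) {
    const double zc = originZ - r * spacingRow;
    for (int c = 0; c < ncol; ++c) {
      const double xc = originX + c * spacingCol;
      bool inside = false;
      bool onEdge = false;
      for (int i = 0, j = nv - 1; i < nv; j = i++) {
        // on-segment test (collinear and within the bounding box)
        const double crossp = (px[i] - px[j]) * (zc - pz[j]) -
                              (xc - px[j]) * (pz[i] - pz[j]);
        if (std::fabs(crossp) <= eps &&
            xc >= std::min(px[i], px[j]) - eps &&
            xc <= std::max(px[i], px[j]) + eps &&
            zc >= std::min(pz[i], pz[j]) - eps &&
            zc <= std::max(pz[i], pz[j]) + eps) {
          onEdge = true;
          break;
        }
        if ((pz[i] > zc) != (pz[j] > zc)) {
          const double xint = px[j] + (px[i] - px[j]) * (zc - pz[j]) / (pz[i] - pz[j]);
          if (xc < xint) inside = !inside;
        }
      }
      mask(r, c) = onEdge || inside;
    }
  }
  return mask;
}

// Largest 4-connected component of a logical mask.
// [[Rcpp::export]]
LogicalMatrix cpp_largest_component(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int nlab = 0;
  std::vector<int> counts(1, 0);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++nlab;
      counts.push_back(0);
      std::queue<std::pair<int,int> > q;
      q.push(std::make_pair(r, c));
      lab(r, c) = nlab;
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        counts[nlab]++;
        const int pr = p.first, pc = p.second;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int rr = pr + dr[k], cc = pc + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = nlab;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  if (nlab == 0) return out;
  int best = 1;
  for (int l = 2; l <= nlab; ++l) if (counts[l] > counts[best]) best = l;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = (lab(r, c) == best);
  return out;
}
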