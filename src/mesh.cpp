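// Isosurface extraction (marching tetrahedra) and brute-force geometry
// kernels used by the surface model. All coordinates are in voxel units
// here; scaling to mm happens on the R side.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct MeshAccum {
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
  std::unordered_map<uint64_t, int> edge_vertex;
};

// Interpolated vertex on the edge between sample points a and b (linear
// indices), shared between all tetrahedra touching that edge.
int edge_point(MeshAccum &m, uint64_t ia, uint64_t ib,
               const double *px, const double *py, const double *pz,
               double va, double vb, double iso) {
  if (ia > ib) { std::swap(ia, ib); std::swap(va, vb); }
  uint64_t key = ia * 0x100000000ULL + ib;
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  double t = (iso - va) / (vb - va);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  m.vx.push_back(px[ia] + t * (px[ib] - px[ia]));
  m.vy.push_back(py[ia] + t * (py[ib] - py[ia]));
  m.vz.push_back(pz[ia] + t * (pz[ib] - pz[ia]));
  int id = (int)m.vx.size() - 1;
  m.edge_vertex[key] = id;
  return id;
}

void add_tri(MeshAccum &m, int a, int b, int c,
             double refx, double refy, double refz) {
  // Orient so the normal points along ref (inside -> outside direction).
  double ux = m.vx[b] - m.vx[a], uy = m.vy[b] - m.vy[a], uz = m.vz[b] - m.vz[a];
  double wx = m.vx[c] - m.vx[a], wy = m.vy[c] - m.vy[a], wz = m.vz[c] - m.vz[a];
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  if (nx * refx + ny * refy + nz * refz < 0) std::swap(b, c);
  m.f1.push_back(a + 1); m.f2.push_back(b + 1); m.f3.push_back(c + 1);
}

} // namespace

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector vol, IntegerVector dim, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = vol.begin();
  // Sample-point coordinates: voxel centers at (index + 0.5) voxel units,
  // with 0-based indices.
  std::vector<double> px((size_t)nx * ny * nz), py(px.size()), pz(px.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = (size_t)i + nx * ((size_t)j + (size_t)ny * k);
        px[idx] = i + 0.5; py[idx] = j + 0.5; pz[idx] = k + 0.5;
      }
  // Six tetrahedra per cube around the 0-6 diagonal; cube corners indexed
  // by (dx, dy, dz) offsets.
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};
  MeshAccum m;
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        uint64_t cid[8]; double cv[8]; bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          size_t idx = (size_t)(i + corner[c][0]) +
            nx * ((size_t)(j + corner[c][1]) + (size_t)ny * (k + corner[c][2]));
          cid[c] = idx; cv[c] = v[idx];
          (cv[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          uint64_t id[4]; double val[4]; int in[4], out[4]; int nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            id[c] = cid[tets[t][c]]; val[c] = cv[tets[t][c]];
            if (val[c] > iso) in[nin++] = c; else out[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          // Reference direction: from inside centroid to outside centroid.
          double rix = 0, riy = 0, riz = 0, rox = 0, roy = 0, roz = 0;
          for (int c = 0; c < nin; ++c) {
            rix += px[id[in[c]]]; riy += py[id[in[c]]]; riz += pz[id[in[c]]];
          }
          for (int c = 0; c < nout; ++c) {
            rox += px[id[out[c]]]; roy += py[id[out[c]]]; roz += pz[id[out[c]]];
          }
          double refx = rox / nout - rix / nin, refy = roy / nout - riy / nin,
                 refz = roz / nout - riz / nin;
          if (nin == 1) {
            int a = in[0];
            int e0 = edge_point(m, id[a], id[out[0]], px.data(), py.data(), pz.data(), val[a], val[out[0]], iso);
            int e1 = edge_point(m, id[a], id[out[1]], px.data(), py.data(), pz.data(), val[a], val[out[1]], iso);
            int e2 = edge_point(m, id[a], id[out[2]], px.data(), py.data(), pz.data(), val[a], val[out[2]], iso);
            add_tri(m, e0, e1, e2, refx, refy, refz);
          } else if (nin == 3) {
            int a = out[0];
            int e0 = edge_point(m, id[a], id[in[0]], px.data(), py.data(), pz.data(), val[a], val[in[0]], iso);
            int e1 = edge_point(m, id[a], id[in[1]], px.data(), py.data(), pz.data(), val[a], val[in[1]], iso);
            int e2 = edge_point(m, id[a], id[in[2]], px.data(), py.data(), pz.data(), val[a], val[in[2]], iso);
            add_tri(m, e0, e1, e2, refx, refy, refz);
          } else { // 2 in, 2 out: quad split into two triangles
            int a = in[0], b = in[1], c = out[0], d = out[1];
            int e_ac = edge_point(m, id[a], id[c], px.data(), py.data(), pz.data(), val[a], val[c], iso);
            int e_ad = edge_point(m, id[a], id[d], px.data(), py.data(), pz.data(), val[a], val[d], iso);
            int e_bc = edge_point(m, id[b], id[c], px.data(), py.data(), pz.data(), val[b], val[c], iso);
            int e_bd = edge_point(m, id[b], id[d], px.data(), py.data(), pz.data(), val[b], val[d], iso);
            add_tri(m, e_ac, e_ad, e_bd, refx, refy, refz);
            add_tri(m, e_ac, e_bd, e_bc, refx, refy, refz);
          }
        }
      }
  int nv = (int)m.vx.size(), nf = (int)m.f1.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = m.vx[i]; V(i,1) = m.vy[i]; V(i,2) = m.vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i,0) = m.f1[i]; F(i,1) = m.f2[i]; F(i,2) = m.f3[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Nearest mesh vertex for each query point (brute force, exact).
// [[Rcpp::export(name = ".nearest_vertex")]]
List nearest_vertex(NumericMatrix pts, NumericMatrix verts) {
  int n = pts.nrow(), m = verts.nrow();
  IntegerVector idx(n); NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 0;
    double x = pts(i,0), y = pts(i,1), z = pts(i,2);
    for (int j = 0; j < m; ++j) {
      double dx = x - verts(j,0), dy = y - verts(j,1), dz = z - verts(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1; dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Trilinear interpolation of a 3-D volume at physical points. Voxel
// centers sit at (index - 0.5) * vs in each axis (1-based R indexing);
// queries are clamped to the center lattice.
// [[Rcpp::export(name = ".trilinear")]]
NumericVector trilinear(NumericVector vol, IntegerVector dim,
                        NumericMatrix pts, double vs) {
  int nx = dim[0], ny = dim[1], nz = dim[2], n = pts.nrow();
  const double *v = vol.begin();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double gx = pts(q,0) / vs - 0.5, gy = pts(q,1) / vs - 0.5, gz = pts(q,2) / vs - 0.5;
    if (gx < 0) gx = 0; if (gx > nx - 1) gx = nx - 1;
    if (gy < 0) gy = 0; if (gy > ny - 1) gy = ny - 1;
    if (gz < 0) gz = 0; if (gz > nz - 1) gz = nz - 1;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    if (i0 > nx - 2) i0 = nx - 2; if (j0 > ny - 2) j0 = ny - 2; if (k0 > nz - 2) k0 = nz - 2;
    if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double acc = 0;
    for (int dk = 0; dk <= (nz > 1 ? 1 : 0); ++dk)
      for (int dj = 0; dj <= (ny > 1 ? 1 : 0); ++dj)
        for (int di = 0; di <= (nx > 1 ? 1 : 0); ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          size_t idx = (size_t)(i0 + di) + nx * ((size_t)(j0 + dj) + (size_t)ny * (k0 + dk));
          acc += w * v[idx];
        }
    out[q] = acc;
  }
  return out;
}
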