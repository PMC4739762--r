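#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Place atom d given positions a (torsion ref), b (angle ref), c (parent),
// bond length r, bond angle theta (deg, b-c-d) and dihedral phi (deg, a-b-c-d).
static inline void nerf_place(const double* a, const double* b, const double* c,
                              double r, double theta, double phi, double* d) {
  double th = theta * DEG, ph = phi * DEG;
  double bc[3] = {c[0] - b[0], c[1] - b[1], c[2] - b[2]};
  double nb = std::sqrt(bc[0]*bc[0] + bc[1]*bc[1] + bc[2]*bc[2]);
  for (int k = 0; k < 3; ++k) bc[k] /= nb;
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double n[3] = {ab[1]*bc[2] - ab[2]*bc[1],
                 ab[2]*bc[0] - ab[0]*bc[2],
                 ab[0]*bc[1] - ab[1]*bc[0]};
  double nn = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
  for (int k = 0; k < 3; ++k) n[k] /= nn;
  double m[3] = {n[1]*bc[2] - n[2]*bc[1],
                 n[2]*bc[0] - n[0]*bc[2],
                 n[0]*bc[1] - n[1]*bc[0]};
  double d2x = -r * std::cos(th);
  double d2y = r * std::sin(th) * std::cos(ph);
  double d2z = r * std::sin(th) * std::sin(ph);
  for (int k = 0; k < 3; ++k)
    d[k] = c[k] + d2x * bc[k] + d2y * m[k] + d2z * n[k];
}

// Build Cartesian coordinates from an internal-coordinate table.
// zmat columns: p, g, gg (1-based indices, 0 = none), r, theta, phi_offset, tid
// (tid 0 = fixed entry, >0 = index into tors; actual phi = phi_offset + tors[tid-1]).
// Atom 1 sits at the origin, atom 2 on +x, atom 3 in the xy-plane.
static void build_coords_impl(const NumericMatrix& zmat, const double* tors,
                              NumericMatrix& X) {
  int n = zmat.nrow();
  X(0, 0) = X(0, 1) = X(0, 2) = 0.0;
  if (n > 1) { X(1, 0) = zmat(1, 3); X(1, 1) = X(1, 2) = 0.0; }
  if (n > 2) {
    double th = zmat(2, 4) * DEG;
    int p = (int)zmat(2, 0) - 1; // parent is atom 1 or 2
    double dir = (p == 0) ? 1.0 : -1.0;
    X(2, 0) = X(p, 0) + dir * zmat(2, 3) * std::cos(th);
    X(2, 1) = zmat(2, 3) * std::sin(th);
    X(2, 2) = 0.0;
  }
  for (int i = 3; i < n; ++i) {
    int p = (int)zmat(i, 0) - 1, g = (int)zmat(i, 1) - 1, gg = (int)zmat(i, 2) - 1;
    int tid = (int)zmat(i, 6);
    double phi = zmat(i, 5) + (tid > 0 ? tors[tid - 1] : 0.0);
    double a[3] = {X(gg, 0), X(gg, 1), X(gg, 2)};
    double b[3] = {X(g, 0), X(g, 1), X(g, 2)};
    double c[3] = {X(p, 0), X(p, 1), X(p, 2)};
    double d[3];
    nerf_place(a, b, c, zmat(i, 3), zmat(i, 4), phi, d);
    X(i, 0) = d[0]; X(i, 1) = d[1]; X(i, 2) = d[2];
  }
}

// [[Rcpp::export(name = ".pr_build_coords")]]
NumericMatrix pr_build_coords(NumericMatrix zmat, NumericVector tors) {
  NumericMatrix X(zmat.nrow(), 3);
  build_coords_impl(zmat, tors.begin(), X);
  return X;
}

// Rejection sampler for clash-free conformers.
//
// torspec columns: mode, c1, c2, hw, sign_random
//   mode 1: value = center c1 + U(-hw, hw); c2 ignored
//   mode 2: value = (c1 or c2, p = 1/2 each) + U(-hw, hw)
// sign_random 1: the whole value is multiplied by a random sign (twist
// enantiomers).
// clashpairs: rows (i, j, cutoff) 1-based, pairs separated by > 3 bonds.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".pr_sample_conformers")]]
List pr_sample_conformers(NumericMatrix zmat, NumericMatrix torspec,
                          NumericMatrix clashpairs, IntegerVector ends, int n,
                          double max_proposals, bool keep_coords) {
  int natom = zmat.nrow(), ntor = torspec.nrow(), npair = clashpairs.nrow();
  NumericMatrix tmat(n, ntor);
  NumericVector ss(n);
  List coords(keep_coords ? n : 0);
  NumericMatrix X(natom, 3);
  std::vector<double> tors(ntor);
  int end1 = ends[0] - 1, end2 = ends[1] - 1;

  double prop = 0;
  int acc = 0;
  while (acc < n && prop < max_proposals) {
    prop += 1;
    for (int t = 0; t < ntor; ++t) {
      double mode = torspec(t, 0), c1 = torspec(t, 1), c2 = torspec(t, 2),
             hw = torspec(t, 3), sr = torspec(t, 4);
      double center = c1;
      if (mode == 2 && unif_rand() < 0.5) center = c2;
      double v = center + (hw > 0 ? R::runif(-hw, hw) : 0.0);
      if (sr == 1 && unif_rand() < 0.5) v = -v;
      tors[t] = v;
    }
    build_coords_impl(zmat, tors.data(), X);
    bool clash = false;
    for (int k = 0; k < npair && !clash; ++k) {
      int i = (int)clashpairs(k, 0) - 1, j = (int)clashpairs(k, 1) - 1;
      double cut = clashpairs(k, 2);
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1), dz = X(i, 2) - X(j, 2);
      if (dx*dx + dy*dy + dz*dz < cut*cut) clash = true;
    }
    if (clash) continue;
    for (int t = 0; t < ntor; ++t) tmat(acc, t) = tors[t];
    double dx = X(end1, 0) - X(end2, 0), dy = X(end1, 1) - X(end2, 1),
           dz = X(end1, 2) - X(end2, 2);
    ss[acc] = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (keep_coords) coords[acc] = clone(X);
    ++acc;
  }
  return List::create(_["torsions"] = tmat, _["ss"] = ss, _["n_accepted"] = acc,
                      _["n_proposed"] = prop, _["coords"] = coords);
}

// Pore-radius profile: for each z, the largest sphere centred in that plane
// whose surface touches but does not overlap any atom's vdW sphere. The
// in-plane centre is found by a deterministic coarse grid scan (within
// max_offset of the axis) followed by step-halving local refinement.
// [[Rcpp::export(name = ".pr_pore_profile")]]
NumericMatrix pr_pore_profile(NumericMatrix coords, NumericVector radii,
                              NumericVector zvals, double coarse, double fine,
                              double max_offset) {
  int na = coords.nrow(), nz = zvals.size();
  NumericMatrix out(nz, 3);
  for (int iz = 0; iz < nz; ++iz) {
    double z = zvals[iz];
    double bcx = 0, bcy = 0, best = -1e300;
    auto eval = [&](double cx, double cy) {
      double mn = 1e300;
      for (int i = 0; i < na; ++i) {
        double dx = coords(i, 0) - cx, dy = coords(i, 1) - cy,
               dz = coords(i, 2) - z;
        double d = std::sqrt(dx*dx + dy*dy + dz*dz) - radii[i];
        if (d < mn) mn = d;
      }
      return mn;
    };
    int ng = (int)std::floor(max_offset / coarse);
    for (int ix = -ng; ix <= ng; ++ix)
      for (int iy = -ng; iy <= ng; ++iy) {
        double cx = ix * coarse, cy = iy * coarse;
        if (cx*cx + cy*cy > max_offset*max_offset + 1e-9) continue;
        double v = eval(cx, cy);
        if (v > best) { best = v; bcx = cx; bcy = cy; }
      }
    double step = coarse / 2;
    while (step >= fine - 1e-12) {
      bool improved = true;
      while (improved) {
        improved = false;
        const double dxs[8] = {1, -1, 0, 0, 1, 1, -1, -1};
        const double dys[8] = {0, 0, 1, -1, 1, -1, 1, -1};
        for (int k = 0; k < 8; ++k) {
          double cx = bcx + dxs[k] * step, cy = bcy + dys[k] * step;
          if (cx*cx + cy*cy > max_offset*max_offset + 1e-9) continue;
          double v = eval(cx, cy);
          if (v > best + 1e-12) { best = v; bcx = cx; bcy = cy; improved = true; }
        }
      }
      step /= 2;
    }
    out(iz, 0) = best; out(iz, 1) = bcx; out(iz, 2) = bcy;
  }
  return out;
}
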