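// Numerical core: 3D FFT grid correlation and the per-rotation docking scan.
// Grids are stored x-fastest (R array layout); FFT lengths are powers of two,
// chosen >= receptor_dim + ligand_dim - 1 per axis so the circular
// correlation equals the linear (zero-padded) correlation on every lag at
// which the two boxes overlap.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;
typedef std::complex<double> cplx;

static int next_pow2(int n) {
  int p = 1;
  while (p < n) p <<= 1;
  return p;
}

// precomputed radix-2 twiddle factors for length n (power of two):
// w[offset(len) + k] = exp(+-2*pi*i*k/len)
struct Twiddles {
  std::vector<cplx> w;
  explicit Twiddles(int n, bool inverse) {
    w.resize(n > 1 ? n - 1 : 0);
    int off = 0;
    for (int len = 2; len <= n; len <<= 1) {
      double ang = 2.0 * M_PI / len * (inverse ? 1.0 : -1.0);
      for (int k = 0; k < len / 2; k++)
        w[off + k] = cplx(std::cos(ang * k), std::sin(ang * k));
      off += len / 2;
    }
  }
};

// radix-2 FFT of length n over "rows" base + r*stride, each butterfly
// vectorized across `lane` contiguous elements.  With lane == nx this walks
// whole x-lines at a time, keeping the strided y/z passes cache-friendly.
static void fft_rows(cplx *base, int n, size_t stride, int lane,
                     const Twiddles &tw) {
  for (int i = 1, j = 0; i < n; i++) {
    int bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j |= bit;
    if (i < j) {
      cplx *p = base + (size_t)i * stride;
      cplx *q = base + (size_t)j * stride;
      for (int x = 0; x < lane; x++) std::swap(p[x], q[x]);
    }
  }
  int off = 0;
  for (int len = 2; len <= n; len <<= 1) {
    for (int i = 0; i < n; i += len)
      for (int k = 0; k < len / 2; k++) {
        cplx w = tw.w[off + k];
        cplx *p = base + (size_t)(i + k) * stride;
        cplx *q = base + (size_t)(i + k + len / 2) * stride;
        for (int x = 0; x < lane; x++) {
          cplx u = p[x], v = q[x] * w;
          p[x] = u + v;
          q[x] = u - v;
        }
      }
    off += len / 2;
  }
}

// 3D FFT over a contiguous x-fastest array of dims (nx, ny, nz).
// ylim/zlim prune the early passes when the input is known to be zero
// outside [0, ylim) x [0, zlim) (pass ny/nz when dense).
struct FFT3 {
  int nx, ny, nz;
  Twiddles twx_f, twy_f, twz_f, twx_i, twy_i, twz_i;
  FFT3(int nx, int ny, int nz)
      : nx(nx), ny(ny), nz(nz), twx_f(nx, false), twy_f(ny, false),
        twz_f(nz, false), twx_i(nx, true), twy_i(ny, true), twz_i(nz, true) {}
  void run(std::vector<cplx> &a, bool inverse, int ylim, int zlim) const {
    const Twiddles &tx = inverse ? twx_i : twx_f;
    const Twiddles &ty = inverse ? twy_i : twy_f;
    const Twiddles &tz = inverse ? twz_i : twz_f;
    size_t nxy = (size_t)nx * ny;
    for (int z = 0; z < zlim; z++)
      for (int y = 0; y < ylim; y++)
        fft_rows(&a[(size_t)z * nxy + (size_t)y * nx], nx, 1, 1, tx);
    for (int z = 0; z < zlim; z++)
      fft_rows(&a[(size_t)z * nxy], ny, nx, nx, ty);
    for (int y = 0; y < ny; y++)
      fft_rows(&a[(size_t)y * nx], nz, nxy, nx, tz);
    if (inverse) {
      double s = 1.0 / ((double)nx * ny * nz);
      for (size_t i = 0; i < (size_t)nx * ny * nz; i++) a[i] *= s;
    }
  }
};

// Correlation of two real grids R (rdim) and L (ldim):
//   C[t] = sum_u R[u + t] * L[u]
// Returns the full linear correlation as an array of dims rdim + ldim - 1;
// output index m (0-based) along each axis corresponds to lag t = m - (ldim - 1).
// [[Rcpp::export]]
NumericVector cpp_correlate(NumericVector rec, IntegerVector rdim,
                            NumericVector lig, IntegerVector ldim) {
  int rx = rdim[0], ry = rdim[1], rz = rdim[2];
  int lx = ldim[0], ly = ldim[1], lz = ldim[2];
  int nx = next_pow2(rx + lx - 1);
  int ny = next_pow2(ry + ly - 1);
  int nz = next_pow2(rz + lz - 1);
  size_t ntot = (size_t)nx * ny * nz;

  std::vector<cplx> A(ntot, cplx(0, 0)), B(ntot, cplx(0, 0));
  for (int z = 0; z < rz; z++)
    for (int y = 0; y < ry; y++)
      for (int x = 0; x < rx; x++)
        A[(size_t)z * nx * ny + (size_t)y * nx + x] =
            cplx(rec[(size_t)z * rx * ry + (size_t)y * rx + x], 0);
  for (int z = 0; z < lz; z++)
    for (int y = 0; y < ly; y++)
      for (int x = 0; x < lx; x++)
        B[(size_t)z * nx * ny + (size_t)y * nx + x] =
            cplx(lig[(size_t)z * lx * ly + (size_t)y * lx + x], 0);

  FFT3 plan(nx, ny, nz);
  plan.run(A, false, ry, rz);
  plan.run(B, false, ly, lz);
  for (size_t i = 0; i < ntot; i++) A[i] *= std::conj(B[i]);
  plan.run(A, true, ny, nz);

  int ox = rx + lx - 1, oy = ry + ly - 1, oz = rz + lz - 1;
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int z = 0; z < oz; z++) {
    int tz = z - (lz - 1);
    int cz = tz < 0 ? tz + nz : tz;
    for (int y = 0; y < oy; y++) {
      int ty = y - (ly - 1);
      int cy = ty < 0 ? ty + ny : ty;
      for (int x = 0; x < ox; x++) {
        int tx = x - (lx - 1);
        int cx = tx < 0 ? tx + nx : tx;
        out[(R_xlen_t)z * ox * oy + (R_xlen_t)y * ox + x] =
            A[(size_t)cz * nx * ny + (size_t)cy * nx + cx].real();
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Distance-dependent pair energy between two typed atom sets.
// pot is an ntypes x ntypes x nbins array (x-fastest); types are 0-based.
// Pairs closer than clash_dist get clash_energy each; pairs with
// clash_dist <= d < rmax read the table; beyond rmax contribute 0.
static double pair_energy(const double *axyz, const int *atype, int na,
                          const double *bxyz, const int *btype, int nb,
                          const double *pot, int ntypes, int nbins,
                          double bin_width, double rmax,
                          double clash_dist, double clash_energy) {
  double e = 0.0, rmax2 = rmax * rmax, clash2 = clash_dist * clash_dist;
  for (int i = 0; i < na; i++) {
    double xi = axyz[i], yi = axyz[i + na], zi = axyz[i + 2 * na];
    int ti = atype[i];
    for (int j = 0; j < nb; j++) {
      double dx = xi - bxyz[j];
      double dy = yi - bxyz[j + nb];
      double dz = zi - bxyz[j + 2 * nb];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= rmax2) continue;
      if (d2 < clash2) {
        e += clash_energy;
      } else {
        int b = (int)(std::sqrt(d2) / bin_width);
        if (b >= nbins) continue;
        e += pot[(size_t)b * ntypes * ntypes + (size_t)btype[j] * ntypes + ti];
      }
    }
  }
  return e;
}

// [[Rcpp::export]]
double cpp_pair_energy(NumericMatrix axyz, IntegerVector atype,
                       NumericMatrix bxyz, IntegerVector btype,
                       NumericVector pot, int ntypes, int nbins,
                       double bin_width, double rmax,
                       double clash_dist, double clash_energy) {
  return pair_energy(REAL(axyz), INTEGER(atype), axyz.nrow(),
                     REAL(bxyz), INTEGER(btype), bxyz.nrow(),
                     REAL(pot), ntypes, nbins, bin_width, rmax,
                     clash_dist, clash_energy);
}

struct Hit {
  double score;
  int sx, sy, sz; // pose lattice shift (receptor-lattice units)
};

// ranking: higher score first; ties -> smaller (z, y, x) lattice shift
static bool hit_better(const Hit &a, const Hit &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.sz != b.sz) return a.sz < b.sz;
  if (a.sy != b.sy) return a.sy < b.sy;
  return a.sx < b.sx;
}

// Full rotational scan. For each rotation the ligand is rotated about its
// heavy-atom centroid, digitized on the receptor lattice, correlated against
// the receptor grid by FFT, and the topk translations by shape score are
// rescored with the pair potential; the lowest-energy one is retained.
//
// recgrid: digitized receptor field (soft surface + core penalty), dims rdim,
//          cell centers at rec_origin + spacing * index.
// Returns a matrix with one row per rotation:
//   [rot_index(1-based), sx, sy, sz, shape_score, energy]
// where the pose is rotated_coords + spacing * (sx, sy, sz).
// [[Rcpp::export]]
NumericMatrix cpp_dock_scan(NumericVector recgrid, IntegerVector rdim,
                            NumericVector rec_origin, double spacing,
                            NumericMatrix lig_xyz, NumericVector centroid,
                            double r_occ, NumericMatrix rotmats, int topk,
                            NumericMatrix rec_txyz, IntegerVector rec_type,
                            IntegerVector lig_type,
                            NumericVector pot, int ntypes, int nbins,
                            double bin_width, double rmax,
                            double clash_dist, double clash_energy) {
  int rx = rdim[0], ry = rdim[1], rz = rdim[2];
  int nlig = lig_xyz.nrow();
  int nrot = rotmats.nrow();

  // rotation-invariant ligand bounding box centered on the centroid
  double dmax = 0.0;
  for (int i = 0; i < nlig; i++) {
    double dx = lig_xyz(i, 0) - centroid[0];
    double dy = lig_xyz(i, 1) - centroid[1];
    double dz = lig_xyz(i, 2) - centroid[2];
    dmax = std::max(dmax, std::sqrt(dx * dx + dy * dy + dz * dz));
  }
  double half = dmax + r_occ + spacing;
  int lvmin[3], ldim[3];
  for (int k = 0; k < 3; k++) {
    lvmin[k] = (int)std::floor((centroid[k] - half - rec_origin[k]) / spacing);
    int lvmax = (int)std::ceil((centroid[k] + half - rec_origin[k]) / spacing);
    ldim[k] = lvmax - lvmin[k] + 1;
  }
  int lx = ldim[0], ly = ldim[1], lz = ldim[2];

  int nx = next_pow2(rx + lx - 1);
  int ny = next_pow2(ry + ly - 1);
  int nz = next_pow2(rz + lz - 1);
  size_t ntot = (size_t)nx * ny * nz;

  // receptor FFT, computed once
  std::vector<cplx> FR(ntot, cplx(0, 0));
  for (int z = 0; z < rz; z++)
    for (int y = 0; y < ry; y++)
      for (int x = 0; x < rx; x++)
        FR[(size_t)z * nx * ny + (size_t)y * nx + x] =
            cplx(recgrid[(size_t)z * rx * ry + (size_t)y * rx + x], 0);
  FFT3 plan(nx, ny, nz);
  plan.run(FR, false, ry, rz);

  std::vector<cplx> L(ntot);
  std::vector<double> q(3 * nlig), pose(3 * nlig);
  NumericMatrix out(nrot, 6);
  int reach = (int)std::ceil(r_occ / spacing);
  double r_occ2 = r_occ * r_occ;

  for (int r = 0; r < nrot; r++) {
    // rotate about centroid (row r holds the 3x3 matrix row-major)
    const double *m = &rotmats(r, 0);
    double R9[9];
    for (int k = 0; k < 9; k++) R9[k] = rotmats(r, k);
    (void)m;
    for (int i = 0; i < nlig; i++) {
      double x = lig_xyz(i, 0) - centroid[0];
      double y = lig_xyz(i, 1) - centroid[1];
      double z = lig_xyz(i, 2) - centroid[2];
      q[i] = R9[0] * x + R9[1] * y + R9[2] * z + centroid[0];
      q[i + nlig] = R9[3] * x + R9[4] * y + R9[5] * z + centroid[1];
      q[i + 2 * nlig] = R9[6] * x + R9[7] * y + R9[8] * z + centroid[2];
    }

    // digitize rotated ligand: cell occupied iff some atom center within r_occ
    std::fill(L.begin(), L.end(), cplx(0, 0));
    for (int i = 0; i < nlig; i++) {
      double ax = q[i], ay = q[i + nlig], az = q[i + 2 * nlig];
      int ci = (int)std::floor((ax - rec_origin[0]) / spacing + 0.5);
      int cj = (int)std::floor((ay - rec_origin[1]) / spacing + 0.5);
      int ck = (int)std::floor((az - rec_origin[2]) / spacing + 0.5);
      for (int dk = -reach; dk <= reach; dk++) {
        int k = ck + dk - lvmin[2];
        if (k < 0 || k >= lz) continue;
        double zc = rec_origin[2] + (ck + dk) * spacing - az;
        for (int dj = -reach; dj <= reach; dj++) {
          int j = cj + dj - lvmin[1];
          if (j < 0 || j >= ly) continue;
          double yc = rec_origin[1] + (cj + dj) * spacing - ay;
          for (int di = -reach; di <= reach; di++) {
            int ii = ci + di - lvmin[0];
            if (ii < 0 || ii >= lx) continue;
            double xc = rec_origin[0] + (ci + di) * spacing - ax;
            if (xc * xc + yc * yc + zc * zc <= r_occ2)
              L[(size_t)k * nx * ny + (size_t)j * nx + ii] = cplx(1, 0);
          }
        }
      }
    }

    plan.run(L, false, ly, lz);
    for (size_t i = 0; i < ntot; i++) L[i] = FR[i] * std::conj(L[i]);
    plan.run(L, true, ny, nz);

    // top-k lags; lag t maps to pose shift s = t + lvmin
    std::vector<Hit> best;
    best.reserve(topk + 1);
    for (int tz = -(lz - 1); tz <= rz - 1; tz++) {
      int cz = tz < 0 ? tz + nz : tz;
      for (int ty = -(ly - 1); ty <= ry - 1; ty++) {
        int cy = ty < 0 ? ty + ny : ty;
        for (int tx = -(lx - 1); tx <= rx - 1; tx++) {
          int cx = tx < 0 ? tx + nx : tx;
          double sc = L[(size_t)cz * nx * ny + (size_t)cy * nx + cx].real();
          Hit h;
          h.score = sc;
          h.sx = tx - lvmin[0];
          h.sy = ty - lvmin[1];
          h.sz = tz - lvmin[2];
          if ((int)best.size() < topk || hit_better(h, best.back())) {
            best.insert(std::lower_bound(best.begin(), best.end(), h, hit_better), h);
            if ((int)best.size() > topk) best.pop_back();
          }
        }
      }
    }

    // rescore candidates with the pair potential; keep the lowest energy
    double bestE = R_PosInf;
    int bestIdx = 0;
    for (size_t c = 0; c < best.size(); c++) {
      double txr = best[c].sx * spacing;
      double tyr = best[c].sy * spacing;
      double tzr = best[c].sz * spacing;
      for (int i = 0; i < nlig; i++) {
        pose[i] = q[i] + txr;
        pose[i + nlig] = q[i + nlig] + tyr;
        pose[i + 2 * nlig] = q[i + 2 * nlig] + tzr;
      }
      double e = pair_energy(REAL(rec_txyz), INTEGER(rec_type), rec_txyz.nrow(),
                             pose.data(), INTEGER(lig_type), nlig,
                             REAL(pot), ntypes, nbins, bin_width, rmax,
                             clash_dist, clash_energy);
      if (e < bestE) {
        bestE = e;
        bestIdx = (int)c;
      }
    }

    out(r, 0) = r + 1;
    out(r, 1) = best[bestIdx].sx;
    out(r, 2) = best[bestIdx].sy;
    out(r, 3) = best[bestIdx].sz;
    out(r, 4) = best[bestIdx].score;
    out(r, 5) = bestE;
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
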