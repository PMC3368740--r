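// Numerical kernels for level-set evolution on 3D grids and per-voxel tensor
// algebra. Grids are R arrays in column-major order: linear index
// i = x + nx*(y + ny*z), 0-based here, 1-based on the R side.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * (long)z);
}

static inline void tens_to_mat(const double* t, long n, long i, arma::mat33& M) {
  // component order: Dxx, Dxy, Dyy, Dxz, Dyz, Dzz (lower-triangular)
  M(0,0) = t[i];         M(0,1) = t[i + n];     M(0,2) = t[i + 3*n];
  M(1,0) = t[i + n];     M(1,1) = t[i + 2*n];   M(1,2) = t[i + 4*n];
  M(2,0) = t[i + 3*n];   M(2,1) = t[i + 4*n];   M(2,2) = t[i + 5*n];
}

static inline void mat_to_tens(const arma::mat33& M, double* t, long n, long i) {
  t[i]       = M(0,0);
  t[i + n]   = 0.5 * (M(0,1) + M(1,0));
  t[i + 2*n] = M(1,1);
  t[i + 3*n] = 0.5 * (M(0,2) + M(2,0));
  t[i + 4*n] = 0.5 * (M(1,2) + M(2,1));
  t[i + 5*n] = M(2,2);
}

// Eigen-analysis of every tensor: descending eigenvalues, canonical-sign
// principal direction (zeroed when lambda1 is degenerate or non-positive),
// and fractional anisotropy.
// [[Rcpp::export]]
List cpp_eig3_fields(NumericVector tens, IntegerVector dim, double degen_tol) {
  long n = (long)dim[0] * dim[1] * dim[2];
  NumericMatrix evals(n, 3), pdd(n, 3);
  NumericVector fa(n);
  LogicalVector unstable(n);
  const double* t = tens.begin();
  arma::mat33 M;
  arma::vec3 ev;
  arma::mat33 V;
  for (long i = 0; i < n; ++i) {
    tens_to_mat(t, n, i, M);
    double scale = std::max({std::fabs(M(0,0)), std::fabs(M(1,1)), std::fabs(M(2,2)),
                             std::fabs(M(0,1)), std::fabs(M(0,2)), std::fabs(M(1,2))});
    if (scale == 0.0) {
      evals(i,0) = evals(i,1) = evals(i,2) = 0.0;
      fa[i] = 0.0; unstable[i] = true;
      continue;
    }
    arma::eig_sym(ev, V, M);  // ascending
    double l1 = ev[2], l2 = ev[1], l3 = ev[0];
    evals(i,0) = l1; evals(i,1) = l2; evals(i,2) = l3;
    double lb = (l1 + l2 + l3) / 3.0;
    double num = (l1-lb)*(l1-lb) + (l2-lb)*(l2-lb) + (l3-lb)*(l3-lb);
    double den = l1*l1 + l2*l2 + l3*l3;
    fa[i] = den > 0 ? std::sqrt(1.5 * num / den) : 0.0;
    if (fa[i] > 1.0) fa[i] = 1.0;
    bool degen = (l1 - l2) <= degen_tol * std::max(1.0, std::fabs(l1)) || l1 <= 0.0;
    unstable[i] = degen;
    if (degen) continue;  // pdd row stays zero: undefined
    double vx = V(0,2), vy = V(1,2), vz = V(2,2);
    // canonical sign: x >= 0, tie-break on y then z
    double s = 1.0;
    if (vx < -1e-12) s = -1.0;
    else if (std::fabs(vx) <= 1e-12) {
      if (vy < -1e-12) s = -1.0;
      else if (std::fabs(vy) <= 1e-12 && vz < 0) s = -1.0;
    }
    pdd(i,0) = s*vx; pdd(i,1) = s*vy; pdd(i,2) = s*vz;
  }
  return List::create(_["evals"] = evals, _["pdd"] = pdd,
                      _["fa"] = fa, _["unstable"] = unstable);
}

// Clamp negative eigenvalues to zero, reconstructing V max(L,0) V^T.
// [[Rcpp::export]]
NumericVector cpp_clamp_psd(NumericVector tens, IntegerVector dim) {
  long n = (long)dim[0] * dim[1] * dim[2];
  NumericVector out = clone(tens);
  double* t = out.begin();
  arma::mat33 M;
  arma::vec3 ev;
  arma::mat33 V;
  for (long i = 0; i < n; ++i) {
    tens_to_mat(t, n, i, M);
    arma::eig_sym(ev, V, M);
    if (ev[0] >= 0.0) continue;
    for (int k = 0; k < 3; ++k) if (ev[k] < 0) ev[k] = 0.0;
    arma::mat33 R = V * arma::diagmat(ev) * V.t();
    mat_to_tens(R, t, n, i);
  }
  return out;
}

// ---- finite differences ------------------------------------------------

static inline double phi_at(const double* p, int x, int y, int z,
                            int nx, int ny, int nz) {
  x = std::min(std::max(x, 0), nx - 1);
  y = std::min(std::max(y, 0), ny - 1);
  z = std::min(std::max(z, 0), nz - 1);
  return p[idx3(x, y, z, nx, ny)];
}

static double weno5(double v1, double v2, double v3, double v4, double v5) {
  double p1 = v1/3.0 - 7.0*v2/6.0 + 11.0*v3/6.0;
  double p2 = -v2/6.0 + 5.0*v3/6.0 + v4/3.0;
  double p3 = v3/3.0 + 5.0*v4/6.0 - v5/6.0;
  double s1 = (13.0/12.0)*std::pow(v1 - 2*v2 + v3, 2) + 0.25*std::pow(v1 - 4*v2 + 3*v3, 2);
  double s2 = (13.0/12.0)*std::pow(v2 - 2*v3 + v4, 2) + 0.25*std::pow(v2 - v4, 2);
  double s3 = (13.0/12.0)*std::pow(v3 - 2*v4 + v5, 2) + 0.25*std::pow(3*v3 - 4*v4 + v5, 2);
  double vmax = std::max({v1*v1, v2*v2, v3*v3, v4*v4, v5*v5});
  double eps = 1e-6 * vmax + 1e-99;
  double a1 = 0.1 / std::pow(s1 + eps, 2);
  double a2 = 0.6 / std::pow(s2 + eps, 2);
  double a3 = 0.3 / std::pow(s3 + eps, 2);
  return (a1*p1 + a2*p2 + a3*p3) / (a1 + a2 + a3);
}

// One-sided WENO5 derivatives along one axis at (x,y,z); clamped indexing at
// the grid boundary degrades the stencil gracefully to low order there.
static void weno_pair(const double* p, int x, int y, int z,
                      int nx, int ny, int nz, int axis,
                      double& dminus, double& dplus) {
  int dx = axis == 0, dy = axis == 1, dz = axis == 2;
  double f[7];
  for (int k = -3; k <= 3; ++k)
    f[k + 3] = phi_at(p, x + k*dx, y + k*dy, z + k*dz, nx, ny, nz);
  // divided differences f[i+1]-f[i]
  double d[6];
  for (int k = 0; k < 6; ++k) d[k] = f[k+1] - f[k];
  dminus = weno5(d[0], d[1], d[2], d[3], d[4]);
  dplus  = weno5(d[5], d[4], d[3], d[2], d[1]);
}

// Godunov upwind gradient magnitude with WENO5 one-sided differences.
// speed_sign > 0 selects the stencil for an expanding front (F > 0).
// [[Rcpp::export]]
NumericVector cpp_weno_gradmag(NumericVector phi, IntegerVector dim, double speed_sign) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(phi.size());
  const double* p = phi.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double g2 = 0.0;
        for (int ax = 0; ax < 3; ++ax) {
          double dm, dp;
          weno_pair(p, x, y, z, nx, ny, nz, ax, dm, dp);
          double a, b;
          if (speed_sign >= 0) { a = std::max(dm, 0.0); b = std::min(dp, 0.0); }
          else                 { a = std::min(dm, 0.0); b = std::max(dp, 0.0); }
          g2 += std::max(a*a, b*b);
        }
        out[idx3(x, y, z, nx, ny)] = std::sqrt(g2);
      }
  return out;
}

// Central-difference gradient magnitude.
// [[Rcpp::export]]
NumericVector cpp_central_gradmag(NumericVector phi, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(phi.size());
  const double* p = phi.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double gx = 0.5 * (phi_at(p, x+1,y,z,nx,ny,nz) - phi_at(p, x-1,y,z,nx,ny,nz));
        double gy = 0.5 * (phi_at(p, x,y+1,z,nx,ny,nz) - phi_at(p, x,y-1,z,nx,ny,nz));
        double gz = 0.5 * (phi_at(p, x,y,z+1,nx,ny,nz) - phi_at(p, x,y,z-1,nx,ny,nz));
        out[idx3(x,y,z,nx,ny)] = std::sqrt(gx*gx + gy*gy + gz*gz);
      }
  return out;
}

// Mean curvature div(grad phi / |grad phi|), central differences,
// epsilon-guarded and clamped to |kappa| <= 1 (one voxel^-1) for stability.
// [[Rcpp::export]]
NumericVector cpp_curvature(NumericVector phi, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(phi.size());
  const double* p = phi.begin();
  const double eps = 1e-8;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double c  = phi_at(p, x, y, z, nx, ny, nz);
        double xp = phi_at(p, x+1,y,z,nx,ny,nz), xm = phi_at(p, x-1,y,z,nx,ny,nz);
        double yp = phi_at(p, x,y+1,z,nx,ny,nz), ym = phi_at(p, x,y-1,z,nx,ny,nz);
        double zp = phi_at(p, x,y,z+1,nx,ny,nz), zm = phi_at(p, x,y,z-1,nx,ny,nz);
        double fx = 0.5*(xp - xm), fy = 0.5*(yp - ym), fz = 0.5*(zp - zm);
        double fxx = xp - 2*c + xm, fyy = yp - 2*c + ym, fzz = zp - 2*c + zm;
        double fxy = 0.25*(phi_at(p,x+1,y+1,z,nx,ny,nz) - phi_at(p,x-1,y+1,z,nx,ny,nz)
                         - phi_at(p,x+1,y-1,z,nx,ny,nz) + phi_at(p,x-1,y-1,z,nx,ny,nz));
        double fxz = 0.25*(phi_at(p,x+1,y,z+1,nx,ny,nz) - phi_at(p,x-1,y,z+1,nx,ny,nz)
                         - phi_at(p,x+1,y,z-1,nx,ny,nz) + phi_at(p,x-1,y,z-1,nx,ny,nz));
        double fyz = 0.25*(phi_at(p,x,y+1,z+1,nx,ny,nz) - phi_at(p,x,y-1,z+1,nx,ny,nz)
                         - phi_at(p,x,y+1,z-1,nx,ny,nz) + phi_at(p,x,y-1,z-1,nx,ny,nz));
        double g2 = fx*fx + fy*fy + fz*fz;
        double k = 0.0;
        if (g2 > eps) {
          k = (fxx*(fy*fy + fz*fz) + fyy*(fx*fx + fz*fz) + fzz*(fx*fx + fy*fy)
               - 2.0*(fx*fy*fxy + fx*fz*fxz + fy*fz*fyz)) / std::pow(g2, 1.5);
          if (k > 1.0) k = 1.0;
          if (k < -1.0) k = -1.0;
        }
        out[idx3(x,y,z,nx,ny)] = k;
      }
  return out;
}

// Sussman PDE reinitialization toward a signed distance function. The sign of
// the input field is preserved exactly (flipped voxels are clamped back).
// [[Rcpp::export]]
NumericVector cpp_reinit(NumericVector phi0, IntegerVector dim, int iters) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  NumericVector cur = clone(phi0);
  NumericVector nxt(n);
  const double dt = 0.5, h = 1.0;
  std::vector<double> S(n);
  for (long i = 0; i < n; ++i)
    S[i] = phi0[i] / std::sqrt(phi0[i]*phi0[i] + h*h);
  for (int it = 0; it < iters; ++it) {
    const double* p = cur.begin();
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          long i = idx3(x, y, z, nx, ny);
          double c = p[i];
          double dm[3], dp[3];
          dm[0] = c - phi_at(p, x-1,y,z,nx,ny,nz); dp[0] = phi_at(p, x+1,y,z,nx,ny,nz) - c;
          dm[1] = c - phi_at(p, x,y-1,z,nx,ny,nz); dp[1] = phi_at(p, x,y+1,z,nx,ny,nz) - c;
          dm[2] = c - phi_at(p, x,y,z-1,nx,ny,nz); dp[2] = phi_at(p, x,y,z+1,nx,ny,nz) - c;
          double g2 = 0.0;
          if (S[i] > 0) {
            for (int ax = 0; ax < 3; ++ax) {
              double a = std::max(dm[ax], 0.0), b = std::min(dp[ax], 0.0);
              g2 += std::max(a*a, b*b);
            }
          } else {
            for (int ax = 0; ax < 3; ++ax) {
              double a = std::min(dm[ax], 0.0), b = std::max(dp[ax], 0.0);
              g2 += std::max(a*a, b*b);
            }
          }
          nxt[i] = c - dt * S[i] * (std::sqrt(g2) - 1.0);
        }
    // sign preservation clamp
    for (long i = 0; i < n; ++i) {
      if (phi0[i] < 0 && nxt[i] >= 0) nxt[i] = -1e-8;
      else if (phi0[i] > 0 && nxt[i] <= 0) nxt[i] = 1e-8;
      else if (phi0[i] == 0) nxt[i] = 0.0;
    }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
  }
  return cur;
}

// Similarity speed field. Donor voxels are inside voxels (phi < 0) with an
// outside 6-neighbor; their speed follows the gated neighbor sum and is then
// extended to all narrow-band voxels by nearest-donor breadth-first fill.
// [[Rcpp::export]]
NumericVector cpp_speed_field(NumericVector phi, IntegerVector dim,
                              NumericVector fa, NumericMatrix pdd,
                              NumericVector tens,
                              double pddx_t, double collin_t, double fa_t,
                              double f_t, double ncos, double band) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  NumericVector F(n);
  const double* p = phi.begin();
  const double* t = tens.begin();

  // 26-neighborhood offsets and their unit vectors
  int offs[26][3]; double uoff[26][3]; int noff = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        double nrm = std::sqrt((double)(dx*dx + dy*dy + dz*dz));
        offs[noff][0] = dx; offs[noff][1] = dy; offs[noff][2] = dz;
        uoff[noff][0] = dx/nrm; uoff[noff][1] = dy/nrm; uoff[noff][2] = dz/nrm;
        ++noff;
      }

  std::vector<char> isdonor(n, 0);
  std::queue<long> q;
  std::vector<double> trD(n);
  for (long i = 0; i < n; ++i) trD[i] = t[i] + t[i + 2*n] + t[i + 5*n];

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long i = idx3(x, y, z, nx, ny);
        if (p[i] >= 0) continue;
        bool surf =
          phi_at(p,x+1,y,z,nx,ny,nz) >= 0 || phi_at(p,x-1,y,z,nx,ny,nz) >= 0 ||
          phi_at(p,x,y+1,z,nx,ny,nz) >= 0 || phi_at(p,x,y-1,z,nx,ny,nz) >= 0 ||
          phi_at(p,x,y,z+1,nx,ny,nz) >= 0 || phi_at(p,x,y,z-1,nx,ny,nz) >= 0;
        if (!surf) continue;
        isdonor[i] = 1;
        // outward normal from central differences (phi < 0 inside)
        double gx = 0.5*(phi_at(p,x+1,y,z,nx,ny,nz) - phi_at(p,x-1,y,z,nx,ny,nz));
        double gy = 0.5*(phi_at(p,x,y+1,z,nx,ny,nz) - phi_at(p,x,y-1,z,nx,ny,nz));
        double gz = 0.5*(phi_at(p,x,y,z+1,nx,ny,nz) - phi_at(p,x,y,z-1,nx,ny,nz));
        double gm = std::sqrt(gx*gx + gy*gy + gz*gz);
        if (gm < 1e-8) { F[i] = 0.0; q.push(i); continue; }
        gx /= gm; gy /= gm; gz /= gm;
        double prx = pdd(i,0), pry = pdd(i,1), prz = pdd(i,2);
        bool pdd_r_def = (prx != 0.0 || pry != 0.0 || prz != 0.0);
        double far = fa[i];
        double acc = 0.0;
        for (int k = 0; k < noff; ++k) {
          if (uoff[k][0]*gx + uoff[k][1]*gy + uoff[k][2]*gz <= ncos) continue;
          int xn = x + offs[k][0], yn = y + offs[k][1], zn = z + offs[k][2];
          if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz) continue;
          long j = idx3(xn, yn, zn, nx, ny);
          if (!pdd_r_def) continue;
          double pnx = pdd(j,0), pny = pdd(j,1), pnz = pdd(j,2);
          if (pnx == 0.0 && pny == 0.0 && pnz == 0.0) continue;
          double dot = std::fabs(prx*pnx + pry*pny + prz*pnz);
          if (!(dot > collin_t)) continue;
          if (!(fa[j] > fa_t)) continue;
          if (!(std::fabs(prx) > pddx_t)) continue;
          double den = trD[i] * trD[j];
          if (den < 1e-20) continue;
          double num = t[i]*t[j] + t[i+2*n]*t[j+2*n] + t[i+5*n]*t[j+5*n]
            + 2.0*(t[i+n]*t[j+n] + t[i+3*n]*t[j+3*n] + t[i+4*n]*t[j+4*n]);
          acc += far * fa[j] * (num / den);
        }
        if (acc <= f_t) acc = 0.0;
        F[i] = acc;
        if (acc > 0) q.push(i);  // zero-speed donors contribute no extension
      }

  // Nearest-donor extension through the narrow band (6-connectivity BFS).
  // The front may only be advected into voxels that can themselves support
  // propagation, so outside voxels receive speed only if they pass the
  // voxel-level admissibility gates (FA and |PDD_x| above threshold).
  std::vector<char> visited(n, 0);
  for (long i = 0; i < n; ++i) visited[i] = isdonor[i];
  const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    long i = q.front(); q.pop();
    int z = i / ((long)nx*ny);
    int rem = i - (long)z*nx*ny;
    int y = rem / nx, x = rem % nx;
    for (int k = 0; k < 6; ++k) {
      int xn = x + face[k][0], yn = y + face[k][1], zn = z + face[k][2];
      if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz) continue;
      long j = idx3(xn, yn, zn, nx, ny);
      if (visited[j]) continue;
      if (std::fabs(p[j]) > band) continue;
      if (p[j] >= 0) {
        bool admissible = fa[j] > fa_t && std::fabs(pdd(j,0)) > pddx_t;
        if (!admissible) continue;
      }
      visited[j] = 1;
      F[j] = F[i];
      q.push(j);
    }
  }
  return F;
}

// Band-restricted explicit evolution step:
// phi <- phi - dt (F |grad phi|_weno - w kappa |grad phi|_central)
// with dt from the CFL bound 0.5 / max(F + 6 w max|kappa|).
// curv_mode 0: curvature acts on the whole band (generic level-set step);
// curv_mode 1: curvature acts only where F > 0, so smoothing regularizes
// the moving front but cannot advance a stalled one.
// [[Rcpp::export]]
List cpp_evolve_step(NumericVector phi, IntegerVector dim, NumericVector F,
                     double w, double band, int curv_mode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  const double* p = phi.begin();
  std::vector<long> active;
  active.reserve(1 << 16);
  double maxF = 0.0;
  for (long i = 0; i < n; ++i) {
    if (F[i] > maxF) maxF = F[i];
    bool act = F[i] > 0 ||
      (w > 0 && curv_mode == 0 && std::fabs(p[i]) <= band);
    if (act) active.push_back(i);
  }
  NumericVector kap;
  double maxk = 0.0;
  if (w > 0) {
    kap = cpp_curvature(phi, dim);
    for (long i : active) if (std::fabs(kap[i]) > maxk) maxk = std::fabs(kap[i]);
  }
  double denom = maxF + 6.0 * w * maxk;
  if (denom < 1e-12) return List::create(_["phi"] = clone(phi), _["dt"] = 0.0);
  double dt = 0.5 / denom;
  NumericVector out = clone(phi);
  for (long i : active) {
    int z = i / ((long)nx*ny);
    int rem = i - (long)z*nx*ny;
    int y = rem / nx, x = rem % nx;
    double upd = 0.0;
    if (F[i] > 0) {
      double g2 = 0.0;
      for (int ax = 0; ax < 3; ++ax) {
        double dm, dp;
        weno_pair(p, x, y, z, nx, ny, nz, ax, dm, dp);
        double a = std::max(dm, 0.0), b = std::min(dp, 0.0);
        g2 += std::max(a*a, b*b);
      }
      upd += F[i] * std::sqrt(g2);
    }
    if (w > 0) {
      double gx = 0.5 * (phi_at(p, x+1,y,z,nx,ny,nz) - phi_at(p, x-1,y,z,nx,ny,nz));
      double gy = 0.5 * (phi_at(p, x,y+1,z,nx,ny,nz) - phi_at(p, x,y-1,z,nx,ny,nz));
      double gz = 0.5 * (phi_at(p, x,y,z+1,nx,ny,nz) - phi_at(p, x,y,z-1,nx,ny,nz));
      upd -= w * kap[i] * std::sqrt(gx*gx + gy*gy + gz*gz);
    }
    out[i] = p[i] - dt * upd;
  }
  return List::create(_["phi"] = out, _["dt"] = dt);
}

// Component-wise trilinear resampling of a k-component volume onto a new grid.
// Voxel i (0-based) is centered at i * voxel_size along each axis.
// [[Rcpp::export]]
NumericVector cpp_trilinear_resample(NumericVector values, IntegerVector dimIn,
                                     NumericVector voxIn, IntegerVector dimOut,
                                     NumericVector voxOut, int ncomp) {
  int nxi = dimIn[0], nyi = dimIn[1], nzi = dimIn[2];
  int nxo = dimOut[0], nyo = dimOut[1], nzo = dimOut[2];
  long ni = (long)nxi * nyi * nzi;
  long no = (long)nxo * nyo * nzo;
  NumericVector out((R_xlen_t)(no * ncomp));
  const double* v = values.begin();
  for (int z = 0; z < nzo; ++z)
    for (int y = 0; y < nyo; ++y)
      for (int x = 0; x < nxo; ++x) {
        double fx = x * voxOut[0] / voxIn[0];
        double fy = y * voxOut[1] / voxIn[1];
        double fz = z * voxOut[2] / voxIn[2];
        fx = std::min(std::max(fx, 0.0), (double)(nxi - 1));
        fy = std::min(std::max(fy, 0.0), (double)(nyi - 1));
        fz = std::min(std::max(fz, 0.0), (double)(nzi - 1));
        int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
        int x1 = std::min(x0 + 1, nxi - 1);
        int y1 = std::min(y0 + 1, nyi - 1);
        int z1 = std::min(z0 + 1, nzi - 1);
        double wx = fx - x0, wy = fy - y0, wz = fz - z0;
        long o = idx3(x, y, z, nxo, nyo);
        for (int c = 0; c < ncomp; ++c) {
          const double* vc = v + (long)c * ni;
          double c00 = vc[idx3(x0,y0,z0,nxi,nyi)]*(1-wx) + vc[idx3(x1,y0,z0,nxi,nyi)]*wx;
          double c10 = vc[idx3(x0,y1,z0,nxi,nyi)]*(1-wx) + vc[idx3(x1,y1,z0,nxi,nyi)]*wx;
          double c01 = vc[idx3(x0,y0,z1,nxi,nyi)]*(1-wx) + vc[idx3(x1,y0,z1,nxi,nyi)]*wx;
          double c11 = vc[idx3(x0,y1,z1,nxi,nyi)]*(1-wx) + vc[idx3(x1,y1,z1,nxi,nyi)]*wx;
          double c0 = c00*(1-wy) + c10*wy;
          double c1 = c01*(1-wy) + c11*wy;
          out[o + (long)c * no] = c0*(1-wz) + c1*wz;
        }
      }
  return out;
}

// Chebyshev dilation of a binary mask by `iters` voxels (26-connectivity).
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim, int iters) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  std::vector<char> cur(n), nxt(n);
  for (long i = 0; i < n; ++i) cur[i] = mask[i];
  for (int it = 0; it < iters; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          long i = idx3(x, y, z, nx, ny);
          char m = cur[i];
          for (int dz = -1; dz <= 1 && !m; ++dz)
            for (int dy = -1; dy <= 1 && !m; ++dy)
              for (int dx = -1; dx <= 1 && !m; ++dx) {
                int xn = x+dx, yn = y+dy, zn = z+dz;
                if (xn < 0 || xn >= nx || yn < 0 || yn >= ny || zn < 0 || zn >= nz) continue;
                if (cur[idx3(xn, yn, zn, nx, ny)]) m = 1;
              }
          nxt[i] = m;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = cur[i] != 0;
  return out;
}

// Rigid rotation of the tensor field inside a region: each output voxel whose
// inverse-rotated coordinate falls in `region` takes the nearest-neighbor
// input tensor reoriented as R T R^T. Other voxels are untouched.
// [[Rcpp::export]]
List cpp_rotate_region(NumericVector tens, IntegerVector dim, LogicalVector region,
                       NumericMatrix R, NumericVector center) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  NumericVector out = clone(tens);
  LogicalVector rotated(n);
  const double* t = tens.begin();
  double* o = out.begin();
  arma::mat33 Rm, T, Tp;
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) Rm(a,b) = R(a,b);
  arma::mat33 Rt = Rm.t();
  bool oob = false;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double px = x - center[0], py = y - center[1], pz = z - center[2];
        double ux = Rt(0,0)*px + Rt(0,1)*py + Rt(0,2)*pz + center[0];
        double uy = Rt(1,0)*px + Rt(1,1)*py + Rt(1,2)*pz + center[1];
        double uz = Rt(2,0)*px + Rt(2,1)*py + Rt(2,2)*pz + center[2];
        int xs = (int)std::lround(ux), ys = (int)std::lround(uy), zs = (int)std::lround(uz);
        if (xs < 0 || xs >= nx || ys < 0 || ys >= ny || zs < 0 || zs >= nz) continue;
        long j = idx3(xs, ys, zs, nx, ny);
        if (!region[j]) continue;
        tens_to_mat(t, n, j, T);
        Tp = Rm * T * Rt;
        long i = idx3(x, y, z, nx, ny);
        mat_to_tens(Tp, o, n, i);
        rotated[i] = true;
      }
  // forward check: does any region voxel rotate out of the grid?
  for (int z = 0; z < nz && !oob; ++z)
    for (int y = 0; y < ny && !oob; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!region[idx3(x, y, z, nx, ny)]) continue;
        double px = x - center[0], py = y - center[1], pz = z - center[2];
        double vx = Rm(0,0)*px + Rm(0,1)*py + Rm(0,2)*pz + center[0];
        double vy = Rm(1,0)*px + Rm(1,1)*py + Rm(1,2)*pz + center[1];
        double vz = Rm(2,0)*px + Rm(2,1)*py + Rm(2,2)*pz + center[2];
        if (vx < -0.5 || vx > nx - 0.5 || vy < -0.5 || vy > ny - 0.5 ||
            vz < -0.5 || vz > nz - 0.5) { oob = true; break; }
      }
  return List::create(_["tensors"] = out, _["rotated"] = rotated,
                      _["out_of_bounds"] = oob);
}

// Nearest-neighbor pullback of a scalar/label volume under a rigid rotation
// about `center`; out-of-grid samples take `fill`.
// [[Rcpp::export]]
NumericVector cpp_rotate_volume_nn(NumericVector vol, IntegerVector dim,
                                   NumericMatrix R, NumericVector center, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)((long)nx * ny * nz));
  arma::mat33 Rm;
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) Rm(a,b) = R(a,b);
  arma::mat33 Rt = Rm.t();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double px = x - center[0], py = y - center[1], pz = z - center[2];
        double ux = Rt(0,0)*px + Rt(0,1)*py + Rt(0,2)*pz + center[0];
        double uy = Rt(1,0)*px + Rt(1,1)*py + Rt(1,2)*pz + center[1];
        double uz = Rt(2,0)*px + Rt(2,1)*py + Rt(2,2)*pz + center[2];
        int xs = (int)std::lround(ux), ys = (int)std::lround(uy), zs = (int)std::lround(uz);
        long i = idx3(x, y, z, nx, ny);
        if (xs < 0 || xs >= nx || ys < 0 || ys >= ny || zs < 0 || zs >= nz)
          out[i] = fill;
        else
          out[i] = vol[idx3(xs, ys, zs, nx, ny)];
      }
  return out;
}
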