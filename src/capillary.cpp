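// Axisymmetric two-phase incompressible flow with a conservative level-set
// interface, on a uniform staggered (MAC) r-z grid.
//
// Cells (i,j): centres at r=(i+0.5)h, z=(j+0.5)h, i=0..Nr-1, j=0..Nz-1.
// ur at radial faces (i,j), i=0..Nr (r=i*h); uz at axial faces (i,j),
// j=0..Nz (z=j*h).  phi in [0,1] is the water volume fraction; the 0.5
// contour is the interface.  Solid gel cells are masked out; the reservoir
// bottom (j=0) is a pressure inlet (p=0, water inflow), the pore top a
// pressure outlet (p=0) unless the domain is closed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// smoothing passes applied to phi before evaluating interface normals and
// curvature (the transported field itself stays sharp)
static const int KAPPA_SMOOTH = 3;

struct Grid {
  int Nr, Nz;
  double h;
  std::vector<int> mask;   // 1 fluid, 0 solid
  bool open_top, open_bottom;
  double slip;             // Navier slip length (m)
  int jD;                  // first axial cell index inside the pore section
  int iRp;                 // number of radial cells across the pore
  inline int id(int i, int j) const { return i + j * Nr; }
  inline bool fluid(int i, int j) const {
    if (i < 0 || i >= Nr || j < 0 || j >= Nz) return false;
    return mask[id(i, j)] != 0;
  }
};

struct Fluids {
  double rho_w, rho_a, mu_w, mu_a, sigma, g;
  double costh, cotth;
};

struct State {
  std::vector<double> phi, p, ur, uz;
  double t, eps, gamma;
};

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}
static inline double minmod(double a, double b) {
  if (a * b <= 0.0) return 0.0;
  return std::fabs(a) < std::fabs(b) ? a : b;
}
static inline double mixr(const Fluids& f, double phi) {
  return f.rho_a + (f.rho_w - f.rho_a) * phi;
}
static inline double mixm(const Fluids& f, double phi) {
  return f.mu_a + (f.mu_w - f.mu_a) * phi;
}

// phi fetch with mirror/zero-gradient fallbacks; solid neighbours return the
// nearest fluid value (contact-angle ghosts are applied explicitly where the
// wall direction is known).
static double phiAt(const Grid& g, const std::vector<double>& phi,
                    int i, int j) {
  if (i < 0) i = 0;
  if (i >= g.Nr) i = g.Nr - 1;
  if (j < 0) return g.open_bottom ? 1.0 : phi[g.id(i, 0)];
  if (j >= g.Nz) j = g.Nz - 1;
  if (!g.fluid(i, j)) {
    // nearest fluid cell in the same row/column
    for (int k = 1; k < g.Nr; ++k) {
      if (g.fluid(i - k, j)) return phi[g.id(i - k, j)];
      if (g.fluid(i + k, j)) return phi[g.id(i + k, j)];
    }
    return 0.0;
  }
  return phi[g.id(i, j)];
}

// central tangential derivatives at a fluid cell
static inline double dphidz(const Grid& g, const std::vector<double>& phi,
                            int i, int j) {
  return (phiAt(g, phi, i, j + 1) - phiAt(g, phi, i, j - 1)) / (2.0 * g.h);
}
static inline double dphidr(const Grid& g, const std::vector<double>& phi,
                            int i, int j) {
  return (phiAt(g, phi, i + 1, j) - phiAt(g, phi, i - 1, j)) / (2.0 * g.h);
}

// one Jacobi smoothing pass of phi (for normal/curvature evaluation only;
// transport always uses the sharp field).  Wall/boundary neighbours fall
// back to the centre value (zero-gradient).
static void smoothPhi(const Grid& g, const std::vector<double>& phi,
                      std::vector<double>& out, int passes) {
  out = phi;
  if (passes <= 0) return;
  std::vector<double> tmp(phi.size());
  for (int p = 0; p < passes; ++p) {
    for (int j = 0; j < g.Nz; ++j)
      for (int i = 0; i < g.Nr; ++i) {
        int c = g.id(i, j);
        if (!g.fluid(i, j)) { tmp[c] = out[c]; continue; }
        double cc = out[c];
        double w = g.fluid(i - 1, j) ? out[g.id(i - 1, j)] : cc;
        double e = g.fluid(i + 1, j) ? out[g.id(i + 1, j)] : cc;
        double so = (j > 0 && g.fluid(i, j - 1)) ? out[g.id(i, j - 1)] :
          (j == 0 && g.open_bottom ? 1.0 : cc);
        double no = (j < g.Nz - 1 && g.fluid(i, j + 1)) ? out[g.id(i, j + 1)] : cc;
        tmp[c] = 0.5 * cc + 0.125 * (w + e + so + no);
      }
    out.swap(tmp);
  }
}

// Face-centred interface normals.  Wall faces use the contact-angle ghost:
// outward wall normal n_w, grad(phi).n_w = cot(theta)*|grad_t phi|.
static void faceNormals(const Grid& g, const Fluids& f,
                        const std::vector<double>& phi,
                        std::vector<double>& nrf, std::vector<double>& gzf,
                        std::vector<double>& nzf, std::vector<double>& grf) {
  const int Nr = g.Nr, Nz = g.Nz;
  const double h = g.h;
  // radial faces: nrf (normal r-component), gzf stores |grad| at the face
  for (int j = 0; j < Nz; ++j) {
    for (int i = 0; i <= Nr; ++i) {
      int k = i + j * (Nr + 1);
      nrf[k] = 0.0; gzf[k] = 0.0;
      if (i == 0) continue;                       // axis: nr = 0
      bool fl = g.fluid(i - 1, j), fr = g.fluid(i, j);
      double gr, gz;
      if (fl && fr) {
        gr = (phi[g.id(i, j)] - phi[g.id(i - 1, j)]) / h;
        gz = 0.5 * (dphidz(g, phi, i - 1, j) + dphidz(g, phi, i, j));
      } else if (fl && !fr) {                     // wall on +r side
        gz = dphidz(g, phi, i - 1, j);
        gr = f.cotth * std::fabs(gz);
      } else if (!fl && fr) {                     // wall on -r side
        gz = dphidz(g, phi, i, j);
        gr = -f.cotth * std::fabs(gz);
      } else {
        continue;
      }
      double mag = std::sqrt(gr * gr + gz * gz);
      if (mag > 1e-12) { nrf[k] = gr / mag; gzf[k] = mag; }
    }
  }
  // axial faces: nzf, grf stores |grad| at the face
  for (int j = 0; j <= Nz; ++j) {
    for (int i = 0; i < Nr; ++i) {
      int k = i + j * Nr;
      nzf[k] = 0.0; grf[k] = 0.0;
      bool fb = g.fluid(i, j - 1), ft = g.fluid(i, j);
      double gr, gz;
      if (j == 0) {
        if (!ft) continue;
        gz = (phi[g.id(i, 0)] - (g.open_bottom ? 1.0 : phi[g.id(i, 0)])) / h;
        gr = dphidr(g, phi, i, 0);
      } else if (j == Nz) {
        if (!fb) continue;
        gz = 0.0; gr = dphidr(g, phi, i, Nz - 1);  // zero-gradient outlet
      } else if (fb && ft) {
        gz = (phi[g.id(i, j)] - phi[g.id(i, j - 1)]) / h;
        gr = 0.5 * (dphidr(g, phi, i, j - 1) + dphidr(g, phi, i, j));
      } else if (fb && !ft) {                     // solid above (gel underside)
        gr = dphidr(g, phi, i, j - 1);
        gz = f.cotth * std::fabs(gr);
      } else if (!fb && ft) {                     // solid below
        gr = dphidr(g, phi, i, j);
        gz = -f.cotth * std::fabs(gr);
      } else {
        continue;
      }
      double mag = std::sqrt(gr * gr + gz * gz);
      if (mag > 1e-12) { nzf[k] = gz / mag; grf[k] = mag; }
    }
  }
}

// cell curvature kappa = -div(n) from face normals (axisymmetric)
static void cellCurvature(const Grid& g, const std::vector<double>& nrf,
                          const std::vector<double>& nzf,
                          std::vector<double>& kap) {
  const int Nr = g.Nr, Nz = g.Nz;
  const double h = g.h;
  for (int j = 0; j < Nz; ++j) {
    for (int i = 0; i < Nr; ++i) {
      int c = g.id(i, j);
      kap[c] = 0.0;
      if (!g.fluid(i, j)) continue;
      double rc = (i + 0.5) * h, rl = i * h, rr = (i + 1) * h;
      double divn =
        (rr * nrf[(i + 1) + j * (Nr + 1)] - rl * nrf[i + j * (Nr + 1)]) /
          (rc * h) +
        (nzf[i + (j + 1) * Nr] - nzf[i + j * Nr]) / h;
      kap[c] = -divn;
    }
  }
}

// One conservative level-set step: advection (MUSCL-minmod upwind) plus
// Olsson-Kreiss reinitialisation gamma*div(eps*grad(phi) - phi(1-phi)n).
static void levelsetStep(const Grid& g, const Fluids& f, State& s, double dt,
                         const std::vector<double>& nrf,
                         const std::vector<double>& nzf) {
  const int Nr = g.Nr, Nz = g.Nz;
  const double h = g.h, eps = s.eps, gam = s.gamma;
  std::vector<double> dphi(Nr * Nz, 0.0);
  const std::vector<double>& phi = s.phi;

  // radial faces
  for (int j = 0; j < Nz; ++j) {
    for (int i = 1; i <= Nr; ++i) {
      bool fl = g.fluid(i - 1, j), fr = (i < Nr) && g.fluid(i, j);
      if (!fl && !fr) continue;
      double rf = i * h;
      double flux = 0.0;  // advective + reinit, per unit face area
      if (fl && fr) {
        double u = s.ur[i + j * (Nr + 1)];
        double pl = phi[g.id(i - 1, j)], pr = phi[g.id(i, j)];
        double pf;
        if (u >= 0.0) {
          double pll = phiAt(g, phi, i - 2, j);
          pf = pl + 0.5 * minmod(pl - pll, pr - pl);
        } else {
          double prr = phiAt(g, phi, i + 1, j);
          pf = pr - 0.5 * minmod(pr - pl, prr - pr);
        }
        flux = u * pf;
        double pm = 0.5 * (pl + pr);
        double reinit = eps * (pr - pl) / h -
          pm * (1.0 - pm) * nrf[i + j * (Nr + 1)];
        flux -= gam * reinit;
      } else {
        // wall face: no flux at all (exact conservation).  The contact
        // angle acts through the ghost-based wall-face normals entering
        // the curvature (wall adhesion force) and the compression
        // directions of interior faces.
        continue;
      }
      if (fl) { double rc = (i - 0.5) * h; dphi[g.id(i - 1, j)] -= rf * flux / (rc * h); }
      if (fr) { double rc = (i + 0.5) * h; dphi[g.id(i, j)]     += rf * flux / (rc * h); }
    }
  }

  // axial faces
  for (int j = 0; j <= Nz; ++j) {
    for (int i = 0; i < Nr; ++i) {
      bool fb = g.fluid(i, j - 1), ft = g.fluid(i, j);
      if (!fb && !ft) continue;
      double flux = 0.0;
      if (fb && ft) {
        double u = s.uz[i + j * Nr];
        double pb = phi[g.id(i, j - 1)], pt = phi[g.id(i, j)];
        double pf;
        if (u >= 0.0) {
          double pbb = phiAt(g, phi, i, j - 2);
          pf = pb + 0.5 * minmod(pb - pbb, pt - pb);
        } else {
          double ptt = phiAt(g, phi, i, j + 1);
          pf = pt - 0.5 * minmod(pt - pb, ptt - pt);
        }
        flux = u * pf;
        double pm = 0.5 * (pb + pt);
        flux -= gam * (eps * (pt - pb) / h - pm * (1.0 - pm) * nzf[i + j * Nr]);
      } else if (j == 0 && ft && g.open_bottom) {
        double u = s.uz[i];                       // inlet: water inflow
        flux = u * (u >= 0.0 ? 1.0 : phi[g.id(i, 0)]);
      } else if (j == Nz && fb && g.open_top) {
        double u = s.uz[i + Nz * Nr];             // outlet: air backflow
        flux = u * (u >= 0.0 ? phi[g.id(i, Nz - 1)] : 0.0);
      } else {
        continue;
      }
      if (fb) dphi[g.id(i, j - 1)] -= flux / h;
      if (ft) dphi[g.id(i, j)]     += flux / h;
    }
  }

  for (int j = 0; j < Nz; ++j)
    for (int i = 0; i < Nr; ++i)
      if (g.fluid(i, j)) {
        int c = g.id(i, j);
        s.phi[c] = clamp01(s.phi[c] + dt * dphi[c]);
      }
}

// slip ghost factor for a tangential velocity mirrored across a wall:
// u_ghost = sfac * u_adjacent, Navier slip length beta.
static inline double slipFac(const Grid& g) {
  return (g.slip - 0.5 * g.h) / (g.slip + 0.5 * g.h);
}

// tangential-velocity fetches with wall/axis/boundary ghosts
static double getUz(const Grid& g, const std::vector<double>& uz,
                    int i, int j) {
  const int Nr = g.Nr, Nz = g.Nz;
  if (j < 0) j = 0;
  if (j > Nz) j = Nz;
  if (i < 0) return uz[0 + j * Nr];               // axis mirror
  if (i >= Nr) {                                   // outer wall ghost
    return slipFac(g) * uz[(Nr - 1) + j * Nr];
  }
  bool fb = g.fluid(i, j - 1), ft = g.fluid(i, j);
  if (j == 0) { fb = g.open_bottom && g.fluid(i, 0); ft = g.fluid(i, 0); }
  if (j == Nz) { fb = g.fluid(i, Nz - 1); ft = g.open_top && fb; }
  if (fb || ft) return uz[i + j * Nr];
  // face fully in solid: ghost of the nearest fluid face in r
  for (int k = 1; k < Nr; ++k) {
    int il = i - k, ir = i + k;
    if (il >= 0) {
      bool b = g.fluid(il, std::max(0, j - 1)) || g.fluid(il, std::min(Nz - 1, j));
      if (b) return slipFac(g) * uz[il + j * Nr];
    }
    if (ir < Nr) {
      bool b = g.fluid(ir, std::max(0, j - 1)) || g.fluid(ir, std::min(Nz - 1, j));
      if (b) return slipFac(g) * uz[ir + j * Nr];
    }
  }
  return 0.0;
}

static double getUr(const Grid& g, const std::vector<double>& ur,
                    int i, int j) {
  const int Nr = g.Nr, Nz = g.Nz;
  if (i < 0) return -ur[1 + std::max(0, std::min(Nz - 1, j)) * (Nr + 1)];
  if (i > Nr) return 0.0;
  if (j < 0) return ur[i];                         // zero-gradient at inlet
  if (j >= Nz) return ur[i + (Nz - 1) * (Nr + 1)]; // zero-gradient at outlet
  bool fl = g.fluid(i - 1, j), fr = g.fluid(i, j);
  if (i == 0) return 0.0;
  if (i == Nr) return 0.0;
  if (fl || fr) return ur[i + j * (Nr + 1)];
  // face fully in solid: slip ghost of the nearest fluid face in z
  for (int k = 1; k < Nz; ++k) {
    int jl = j - k, jr = j + k;
    if (jl >= 0 && (g.fluid(i - 1, jl) || g.fluid(i, jl)))
      return slipFac(g) * ur[i + jl * (Nr + 1)];
    if (jr < Nz && (g.fluid(i - 1, jr) || g.fluid(i, jr)))
      return slipFac(g) * ur[i + jr * (Nr + 1)];
  }
  return 0.0;
}

// corner viscosity: average over adjacent fluid cells
static double muCorner(const Grid& g, const Fluids& f,
                       const std::vector<double>& phi, int i, int j) {
  double s = 0.0; int n = 0;
  for (int dj = -1; dj <= 0; ++dj)
    for (int di = -1; di <= 0; ++di) {
      int ii = i + di, jj = j + dj;
      if (ii >= 0 && ii < g.Nr && jj >= 0 && jj < g.Nz && g.fluid(ii, jj)) {
        s += mixm(f, phi[g.id(ii, jj)]); ++n;
      }
    }
  return n > 0 ? s / n : f.mu_a;
}

// Explicit momentum predictor, returns ustar in (urs, uzs).
static void momentumPredictor(const Grid& g, const Fluids& f, const State& s,
                              double dt,
                              const std::vector<double>& kap,
                              std::vector<double>& urs,
                              std::vector<double>& uzs) {
  const int Nr = g.Nr, Nz = g.Nz;
  const double h = g.h;
  const std::vector<double>& phi = s.phi;
  const std::vector<double>& ur = s.ur;
  const std::vector<double>& uz = s.uz;
  urs = ur; uzs = uz;

  // radial momentum at interior radial faces
  for (int j = 0; j < Nz; ++j) {
    for (int i = 1; i < Nr; ++i) {
      if (!(g.fluid(i - 1, j) && g.fluid(i, j))) continue;
      int k = i + j * (Nr + 1);
      double rf = i * h;
      double pl = phi[g.id(i - 1, j)], pr = phi[g.id(i, j)];
      double pf = 0.5 * (pl + pr);
      double rho = mixr(f, pf), mu = mixm(f, pf);
      double u = ur[k];
      // convection (first-order upwind)
      double urL = getUr(g, ur, i - 1, j), urR = getUr(g, ur, i + 1, j);
      double urD = getUr(g, ur, i, j - 1), urU = getUr(g, ur, i, j + 1);
      double wz = 0.25 * (getUz(g, uz, i - 1, j) + getUz(g, uz, i - 1, j + 1) +
                          getUz(g, uz, i, j) + getUz(g, uz, i, j + 1));
      double conv = u * (u >= 0 ? (u - urL) : (urR - u)) / h +
                    wz * (wz >= 0 ? (u - urD) : (urU - u)) / h;
      // viscous: (1/r) d/dr (r mu du/dr) + d/dz (mu du/dz) - mu u/r^2
      double mcl = mixm(f, pl), mcr = mixm(f, pr);
      double rcl = (i - 0.5) * h, rcr = (i + 0.5) * h;
      double visc =
        (rcr * mcr * (urR - u) - rcl * mcl * (u - urL)) / (rf * h * h) +
        (muCorner(g, f, phi, i, j + 1) * (urU - u) -
         muCorner(g, f, phi, i, j) * (u - urD)) / (h * h) -
        mu * u / (rf * rf);
      // surface tension (CSF): sigma * kappa * 6 phi(1-phi) dphi/dr
      double kf = 0.5 * (kap[g.id(i - 1, j)] + kap[g.id(i, j)]);
      double fst = f.sigma * kf * 6.0 * pf * (1.0 - pf) * (pr - pl) / h;
      urs[k] = u + dt * (-conv + (visc + fst) / rho);
    }
  }

  // axial momentum at interior axial faces
  for (int j = 1; j < Nz; ++j) {
    for (int i = 0; i < Nr; ++i) {
      if (!(g.fluid(i, j - 1) && g.fluid(i, j))) continue;
      int k = i + j * Nr;
      double rc = (i + 0.5) * h;
      double pb = phi[g.id(i, j - 1)], pt = phi[g.id(i, j)];
      double pf = 0.5 * (pb + pt);
      double rho = mixr(f, pf), mu_unused = mixm(f, pf); (void)mu_unused;
      double w = uz[k];
      double uzD = getUz(g, uz, i, j - 1), uzU = getUz(g, uz, i, j + 1);
      double uzL = getUz(g, uz, i - 1, j), uzR = getUz(g, uz, i + 1, j);
      double wr = 0.25 * (getUr(g, ur, i, j - 1) + getUr(g, ur, i + 1, j - 1) +
                          getUr(g, ur, i, j) + getUr(g, ur, i + 1, j));
      double conv = wr * (wr >= 0 ? (w - uzL) : (uzR - w)) / h +
                    w * (w >= 0 ? (w - uzD) : (uzU - w)) / h;
      double mcb = mixm(f, pb), mct = mixm(f, pt);
      double rfl = i * h, rfr = (i + 1) * h;
      double visc =
        (rfr * muCorner(g, f, phi, i + 1, j) * (uzR - w) -
         rfl * muCorner(g, f, phi, i, j) * (w - uzL)) / (rc * h * h) +
        (mct * (uzU - w) - mcb * (w - uzD)) / (h * h);
      double kf = 0.5 * (kap[g.id(i, j - 1)] + kap[g.id(i, j)]);
      double fst = f.sigma * kf * 6.0 * pf * (1.0 - pf) * (pt - pb) / h;
      uzs[k] = w + dt * (-conv + (visc + fst) / rho - f.g);
    }
  }

  // open boundary faces: gravity only; projection supplies the pressure part
  if (g.open_bottom) {
    for (int i = 0; i < Nr; ++i)
      if (g.fluid(i, 0)) uzs[i] = uz[i] + dt * (-f.g);
  }
  if (g.open_top) {
    for (int i = 0; i < Nr; ++i)
      if (g.fluid(i, Nz - 1)) uzs[i + Nz * Nr] = uz[i + Nz * Nr] + dt * (-f.g);
  }
}

// Variable-coefficient pressure Poisson by Jacobi-preconditioned CG.
// Solves -div((1/rho) grad p) = -div(ustar)/dt; Dirichlet p=0 at open
// boundaries, zero-flux at walls.  Returns iterations used, or -1.
static int pressureSolve(const Grid& g, const Fluids& f, State& s,
                         const std::vector<double>& urs,
                         const std::vector<double>& uzs,
                         double dt, double div_rtol, double uref,
                         int maxit) {
  const int Nr = g.Nr, Nz = g.Nz, N = Nr * Nz;
  const double h = g.h;
  const std::vector<double>& phi = s.phi;
  double umax_star = 0.0;
  for (double v : urs) umax_star = std::max(umax_star, std::fabs(v));
  for (double v : uzs) umax_star = std::max(umax_star, std::fabs(v));

  // face mobilities (1/rho) with axisymmetric area factors
  std::vector<double> ar((Nr + 1) * Nz, 0.0), az(Nr * (Nz + 1), 0.0);
  for (int j = 0; j < Nz; ++j)
    for (int i = 1; i < Nr; ++i)
      if (g.fluid(i - 1, j) && g.fluid(i, j)) {
        double pf = 0.5 * (phi[g.id(i - 1, j)] + phi[g.id(i, j)]);
        ar[i + j * (Nr + 1)] = (i * h) / mixr(f, pf);
      }
  for (int j = 1; j < Nz; ++j)
    for (int i = 0; i < Nr; ++i)
      if (g.fluid(i, j - 1) && g.fluid(i, j)) {
        double pf = 0.5 * (phi[g.id(i, j - 1)] + phi[g.id(i, j)]);
        az[i + j * Nr] = 1.0 / mixr(f, pf);
      }
  // Dirichlet boundary faces (half-cell distance -> factor 2)
  std::vector<double> abot(Nr, 0.0), atop(Nr, 0.0);
  if (g.open_bottom)
    for (int i = 0; i < Nr; ++i)
      if (g.fluid(i, 0)) abot[i] = 2.0 / mixr(f, phi[g.id(i, 0)]);
  if (g.open_top)
    for (int i = 0; i < Nr; ++i)
      if (g.fluid(i, Nz - 1)) atop[i] = 2.0 / mixr(f, phi[g.id(i, Nz - 1)]);

  // Volume-weighted (symmetric) system: each cell equation is multiplied by
  // its centre radius rc/h, so face coefficients are shared between
  // neighbours and the operator is SPD (CG-compatible).
  // rhs b = rc * div(ustar)/dt (per cell).
  std::vector<double> b(N, 0.0), diag(N, 1.0), rcv(N, 1.0);
  double bmax = 0.0;
  for (int j = 0; j < Nz; ++j)
    for (int i = 0; i < Nr; ++i) {
      if (!g.fluid(i, j)) continue;
      int c = g.id(i, j);
      double rc = (i + 0.5);
      rcv[c] = rc;
      double div =
        ((i + 1) * h * urs[(i + 1) + j * (Nr + 1)] -
         i * h * urs[i + j * (Nr + 1)]) / (rc * h * h) +
        (uzs[i + (j + 1) * Nr] - uzs[i + j * Nr]) / h;
      b[c] = rc * div / dt;
      double d = (ar[(i + 1) + j * (Nr + 1)] + ar[i + j * (Nr + 1)]) / (h * h * h) +
                 rc * (az[i + (j + 1) * Nr] + az[i + j * Nr]) / (h * h);
      if (j == 0) d += rc * abot[i] / (h * h);
      if (j == Nz - 1) d += rc * atop[i] / (h * h);
      diag[c] = d > 0 ? d : 1.0;
      bmax = std::max(bmax, std::fabs(b[c]) / rc);
    }
  // required residual tolerance: remaining max cell divergence after the
  // correction must be below div_rtol * max|u| / h
  double tol = div_rtol * std::max(std::max(umax_star, uref), 1e-9) / h / dt;

  // pure-Neumann system (closed domain): p defined up to a constant and b
  // must be compatible; remove the nullspace component
  bool has_dirichlet = false;
  for (int i = 0; i < Nr; ++i)
    if (abot[i] > 0.0 || atop[i] > 0.0) { has_dirichlet = true; break; }
  int nfluid = 0;
  for (int c = 0; c < N; ++c) if (g.mask[c]) ++nfluid;
  auto demean = [&](std::vector<double>& v) {
    double m = 0.0;
    for (int c = 0; c < N; ++c) if (g.mask[c]) m += v[c];
    m /= std::max(nfluid, 1);
    for (int c = 0; c < N; ++c) if (g.mask[c]) v[c] -= m;
  };
  if (!has_dirichlet) demean(b);
  if (bmax <= tol) {  // already divergence-free enough; keep previous p
    return 0;
  }

  // assembled 5-point coefficients: A x|_c = diag_c x_c - aW_c x_west
  // - aW_east x_east - aS_c x_south - aS_north x_north  (SPD)
  std::vector<double> aW(N, 0.0), aS(N, 0.0);
  for (int j = 0; j < Nz; ++j)
    for (int i = 0; i < Nr; ++i) {
      int c = g.id(i, j);
      if (!g.fluid(i, j)) continue;
      if (i > 0 && g.fluid(i - 1, j))
        aW[c] = ar[i + j * (Nr + 1)] / (h * h * h);
      if (j > 0 && g.fluid(i, j - 1))
        aS[c] = (i + 0.5) * az[i + j * Nr] / (h * h);
    }
  auto applyA = [&](const std::vector<double>& x, std::vector<double>& y) {
    for (int j = 0; j < Nz; ++j)
      for (int i = 0; i < Nr; ++i) {
        int c = g.id(i, j);
        if (!g.fluid(i, j)) { y[c] = 0.0; continue; }
        double acc = diag[c] * x[c];
        if (aW[c] > 0.0) acc -= aW[c] * x[c - 1];
        if (i + 1 < Nr && aW[c + 1] > 0.0) acc -= aW[c + 1] * x[c + 1];
        if (aS[c] > 0.0) acc -= aS[c] * x[c - Nr];
        if (j + 1 < Nz && aS[c + Nr] > 0.0) acc -= aS[c + Nr] * x[c + Nr];
        y[c] = acc;
      }
  };

  // relaxed modified incomplete Cholesky MIC(0) diagonal: dropped
  // fill-ins are lumped into the diagonal (eta = 0.97), which roughly
  // squares the effective mesh-size exponent of plain IC for Poisson
  const double eta = 0.97;
  std::vector<double> icd(N, 1.0);
  for (int j = 0; j < Nz; ++j)
    for (int i = 0; i < Nr; ++i) {
      int c = g.id(i, j);
      if (!g.fluid(i, j)) continue;
      double d = diag[c];
      if (aW[c] > 0.0) {
        double aN_w = (j + 1 < Nz) ? aS[c - 1 + Nr] : 0.0;
        d -= aW[c] * (aW[c] + eta * aN_w) / icd[c - 1];
      }
      if (aS[c] > 0.0) {
        double aE_s = (i + 1 < Nr) ? aW[c - Nr + 1] : 0.0;
        d -= aS[c] * (aS[c] + eta * aE_s) / icd[c - Nr];
      }
      icd[c] = d > 1e-30 ? d : diag[c];
    }
  auto applyM = [&](const std::vector<double>& r_, std::vector<double>& z_) {
    // z = (L D^-1 L^T)^-1 r with L = lower(A) + D
    for (int j = 0; j < Nz; ++j)
      for (int i = 0; i < Nr; ++i) {
        int c = g.id(i, j);
        if (!g.fluid(i, j)) { z_[c] = 0.0; continue; }
        double v = r_[c];
        if (aW[c] > 0.0) v += aW[c] * z_[c - 1];
        if (aS[c] > 0.0) v += aS[c] * z_[c - Nr];
        z_[c] = v / icd[c];
      }
    for (int j = Nz - 1; j >= 0; --j)
      for (int i = Nr - 1; i >= 0; --i) {
        int c = g.id(i, j);
        if (!g.fluid(i, j)) continue;
        double v = 0.0;
        if (i + 1 < Nr && aW[c + 1] > 0.0) v += aW[c + 1] * z_[c + 1];
        if (j + 1 < Nz && aS[c + Nr] > 0.0) v += aS[c + Nr] * z_[c + Nr];
        z_[c] += v / icd[c];
      }
  };

  // CG with b_eff = -b, warm start from s.p
  std::vector<double> x = s.p, r(N, 0.0), z(N, 0.0), q(N, 0.0), Ax(N, 0.0);
  if (!has_dirichlet) demean(x);  // keep the free gauge constant at zero
  applyA(x, Ax);
  double rmax = 0.0, rz = 0.0;
  for (int c = 0; c < N; ++c) r[c] = -b[c] - Ax[c];
  if (!has_dirichlet) demean(r);
  for (int c = 0; c < N; ++c)
    if (g.mask[c]) rmax = std::max(rmax, std::fabs(r[c]) / rcv[c]);
  if (rmax <= tol) { s.p = x; return 0; }
  applyM(r, z);
  for (int c = 0; c < N; ++c) rz += r[c] * z[c];
  std::vector<double> d = z;
  int it = 0;
  for (; it < maxit; ++it) {
    applyA(d, q);
    double dq = 0.0;
    for (int c = 0; c < N; ++c) dq += d[c] * q[c];
    if (dq <= 0.0) break;
    double alpha = rz / dq;
    for (int c = 0; c < N; ++c) {
      x[c] += alpha * d[c];
      r[c] -= alpha * q[c];
    }
    if (!has_dirichlet && (it % 20 == 19)) demean(r);
    rmax = 0.0;
    for (int c = 0; c < N; ++c)
      if (g.mask[c]) rmax = std::max(rmax, std::fabs(r[c]) / rcv[c]);
    if (rmax <= tol) { ++it; break; }
    applyM(r, z);
    double rz2 = 0.0;
    for (int c = 0; c < N; ++c) rz2 += r[c] * z[c];
    double beta = rz2 / rz;
    rz = rz2;
    for (int c = 0; c < N; ++c) d[c] = z[c] + beta * d[c];
  }
  if (rmax > tol) return -1;
  if (!has_dirichlet) demean(x);
  s.p = x;

  // velocity correction
  for (int j = 0; j < Nz; ++j)
    for (int i = 1; i < Nr; ++i) {
      int k = i + j * (Nr + 1);
      if (g.fluid(i - 1, j) && g.fluid(i, j)) {
        double pf = 0.5 * (phi[g.id(i - 1, j)] + phi[g.id(i, j)]);
        s.ur[k] = urs[k] - dt / mixr(f, pf) *
          (x[g.id(i, j)] - x[g.id(i - 1, j)]) / h;
      } else {
        s.ur[k] = 0.0;
      }
    }
  for (int j = 0; j < Nz; ++j) s.ur[0 + j * (Nr + 1)] = 0.0;
  for (int j = 1; j < Nz; ++j)
    for (int i = 0; i < Nr; ++i) {
      int k = i + j * Nr;
      if (g.fluid(i, j - 1) && g.fluid(i, j)) {
        double pf = 0.5 * (phi[g.id(i, j - 1)] + phi[g.id(i, j)]);
        s.uz[k] = uzs[k] - dt / mixr(f, pf) *
          (x[g.id(i, j)] - x[g.id(i, j - 1)]) / h;
      } else {
        s.uz[k] = 0.0;
      }
    }
  for (int i = 0; i < Nr; ++i) {
    s.uz[i] = (g.open_bottom && g.fluid(i, 0)) ?
      uzs[i] - dt / mixr(f, phi[g.id(i, 0)]) * (x[g.id(i, 0)] - 0.0) / (0.5 * h)
      : 0.0;
    int k = i + Nz * Nr;
    s.uz[k] = (g.open_top && g.fluid(i, Nz - 1)) ?
      uzs[k] - dt / mixr(f, phi[g.id(i, Nz - 1)]) *
        (0.0 - x[g.id(i, Nz - 1)]) / (0.5 * h)
      : 0.0;
  }
  return it;
}

// maximum speed over faces inside or near the interface band, the
// relevant scale for the reinitialisation velocity gamma
static double interfaceSpeed(const Grid& g, const State& s) {
  const int Nr = g.Nr, Nz = g.Nz;
  double m = 0.0;
  for (int j = 0; j < Nz; ++j)
    for (int i = 1; i < Nr; ++i) {
      if (!(g.fluid(i - 1, j) && g.fluid(i, j))) continue;
      double pf = 0.5 * (s.phi[g.id(i - 1, j)] + s.phi[g.id(i, j)]);
      if (pf > 0.02 && pf < 0.98)
        m = std::max(m, std::fabs(s.ur[i + j * (Nr + 1)]));
    }
  for (int j = 1; j < Nz; ++j)
    for (int i = 0; i < Nr; ++i) {
      if (!(g.fluid(i, j - 1) && g.fluid(i, j))) continue;
      double pf = 0.5 * (s.phi[g.id(i, j - 1)] + s.phi[g.id(i, j)]);
      if (pf > 0.02 && pf < 0.98)
        m = std::max(m, std::fabs(s.uz[i + j * Nr]));
    }
  return m;
}

static double maxSpeed(const Grid& g, const State& s) {
  double m = 0.0;
  for (double v : s.ur) m = std::max(m, std::fabs(v));
  for (double v : s.uz) m = std::max(m, std::fabs(v));
  return m;
}

// ---- R interface helpers -------------------------------------------------

static Grid gridFromList(const List& gl) {
  Grid g;
  g.Nr = as<int>(gl["Nr"]); g.Nz = as<int>(gl["Nz"]);
  g.h = as<double>(gl["h"]);
  IntegerMatrix m = gl["mask"];
  g.mask.assign(m.begin(), m.end());
  g.open_top = as<bool>(gl["open_top"]);
  g.open_bottom = as<bool>(gl["open_bottom"]);
  g.slip = as<double>(gl["slip"]);
  g.jD = as<int>(gl["jD"]);
  g.iRp = as<int>(gl["iRp"]);
  return g;
}

static Fluids fluidsFromList(const List& fl) {
  Fluids f;
  f.rho_w = as<double>(fl["rho_water"]); f.rho_a = as<double>(fl["rho_air"]);
  f.mu_w = as<double>(fl["mu_water"]); f.mu_a = as<double>(fl["mu_air"]);
  f.sigma = as<double>(fl["sigma"]); f.g = as<double>(fl["gravity"]);
  double th = as<double>(fl["contact_angle"]) * M_PI / 180.0;
  f.costh = std::cos(th);
  f.cotth = std::cos(th) / std::sin(th);
  return f;
}

// [[Rcpp::export]]
List cpp_mixture_fields(List grid, List fluids, NumericMatrix phi_) {
  Grid g = gridFromList(grid);
  Fluids f = fluidsFromList(fluids);
  std::vector<double> phi(phi_.begin(), phi_.end());
  int N = g.Nr * g.Nz;
  std::vector<double> nrf((g.Nr + 1) * g.Nz), gzf((g.Nr + 1) * g.Nz),
    nzf(g.Nr * (g.Nz + 1)), grf(g.Nr * (g.Nz + 1)), kap(N), phis;
  smoothPhi(g, phi, phis, KAPPA_SMOOTH);
  faceNormals(g, f, phis, nrf, gzf, nzf, grf);
  cellCurvature(g, nrf, nzf, kap);
  NumericMatrix rho(g.Nr, g.Nz), mu(g.Nr, g.Nz), del(g.Nr, g.Nz),
    nr(g.Nr, g.Nz), nz(g.Nr, g.Nz), kp(g.Nr, g.Nz);
  for (int j = 0; j < g.Nz; ++j)
    for (int i = 0; i < g.Nr; ++i) {
      int c = g.id(i, j);
      double ph = phi[c];
      rho(i, j) = mixr(f, ph);
      mu(i, j) = mixm(f, ph);
      double gr = g.fluid(i, j) ? dphidr(g, phi, i, j) : 0.0;
      double gz = g.fluid(i, j) ? dphidz(g, phi, i, j) : 0.0;
      double mag = std::sqrt(gr * gr + gz * gz);
      del(i, j) = 6.0 * std::fabs(ph * (1.0 - ph)) * mag;
      nr(i, j) = mag > 1e-12 ? gr / mag : 0.0;
      nz(i, j) = mag > 1e-12 ? gz / mag : 0.0;
      kp(i, j) = kap[c];
    }
  return List::create(_["rho"] = rho, _["mu"] = mu, _["delta"] = del,
                      _["normal_r"] = nr, _["normal_z"] = nz,
                      _["kappa"] = kp);
}

// [[Rcpp::export]]
List cpp_surface_tension(List grid, List fluids, NumericMatrix phi_) {
  Grid g = gridFromList(grid);
  Fluids f = fluidsFromList(fluids);
  std::vector<double> phi(phi_.begin(), phi_.end());
  int N = g.Nr * g.Nz;
  std::vector<double> nrf((g.Nr + 1) * g.Nz), gzf((g.Nr + 1) * g.Nz),
    nzf(g.Nr * (g.Nz + 1)), grf(g.Nr * (g.Nz + 1)), kap(N), phis;
  smoothPhi(g, phi, phis, KAPPA_SMOOTH);
  faceNormals(g, f, phis, nrf, gzf, nzf, grf);
  cellCurvature(g, nrf, nzf, kap);
  NumericMatrix Fr(g.Nr + 1, g.Nz), Fz(g.Nr, g.Nz + 1);
  for (int j = 0; j < g.Nz; ++j)
    for (int i = 1; i < g.Nr; ++i)
      if (g.fluid(i - 1, j) && g.fluid(i, j)) {
        double pl = phi[g.id(i - 1, j)], pr = phi[g.id(i, j)];
        double pf = 0.5 * (pl + pr);
        double kf = 0.5 * (kap[g.id(i - 1, j)] + kap[g.id(i, j)]);
        Fr(i, j) = f.sigma * kf * 6.0 * pf * (1.0 - pf) * (pr - pl) / g.h;
      }
  for (int j = 1; j < g.Nz; ++j)
    for (int i = 0; i < g.Nr; ++i)
      if (g.fluid(i, j - 1) && g.fluid(i, j)) {
        double pb = phi[g.id(i, j - 1)], pt = phi[g.id(i, j)];
        double pf = 0.5 * (pb + pt);
        double kf = 0.5 * (kap[g.id(i, j - 1)] + kap[g.id(i, j)]);
        Fz(i, j) = f.sigma * kf * 6.0 * pf * (1.0 - pf) * (pt - pb) / g.h;
      }
  return List::create(_["Fr"] = Fr, _["Fz"] = Fz);
}

// [[Rcpp::export]]
NumericMatrix cpp_levelset_step(List grid, List fluids, NumericMatrix phi_,
                                NumericMatrix ur_, NumericMatrix uz_,
                                double dt, double eps, double gamma) {
  Grid g = gridFromList(grid);
  Fluids f = fluidsFromList(fluids);
  State s;
  s.phi.assign(phi_.begin(), phi_.end());
  s.ur.assign(ur_.begin(), ur_.end());
  s.uz.assign(uz_.begin(), uz_.end());
  s.eps = eps; s.gamma = gamma;
  std::vector<double> nrf((g.Nr + 1) * g.Nz), gzf((g.Nr + 1) * g.Nz),
    nzf(g.Nr * (g.Nz + 1)), grf(g.Nr * (g.Nz + 1)), phis;
  smoothPhi(g, s.phi, phis, KAPPA_SMOOTH);
  faceNormals(g, f, phis, nrf, gzf, nzf, grf);
  levelsetStep(g, f, s, dt, nrf, nzf);
  NumericMatrix out(g.Nr, g.Nz);
  std::copy(s.phi.begin(), s.phi.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_flow_step(List grid, List fluids, NumericMatrix phi_,
                   NumericMatrix ur_, NumericMatrix uz_, NumericMatrix p_,
                   double dt, double div_rtol, int maxit) {
  Grid g = gridFromList(grid);
  Fluids f = fluidsFromList(fluids);
  State s;
  s.phi.assign(phi_.begin(), phi_.end());
  s.ur.assign(ur_.begin(), ur_.end());
  s.uz.assign(uz_.begin(), uz_.end());
  s.p.assign(p_.begin(), p_.end());
  int N = g.Nr * g.Nz;
  std::vector<double> nrf((g.Nr + 1) * g.Nz), gzf((g.Nr + 1) * g.Nz),
    nzf(g.Nr * (g.Nz + 1)), grf(g.Nr * (g.Nz + 1)), kap(N), phis;
  smoothPhi(g, s.phi, phis, KAPPA_SMOOTH);
  faceNormals(g, f, phis, nrf, gzf, nzf, grf);
  cellCurvature(g, nrf, nzf, kap);
  std::vector<double> urs, uzs;
  momentumPredictor(g, f, s, dt, kap, urs, uzs);
  double uref = maxSpeed(g, s);
  int it = pressureSolve(g, f, s, urs, uzs, dt, div_rtol, uref, maxit);
  if (it < 0) stop("pressure projection failed to converge (CG stalled)");
  NumericMatrix urn(g.Nr + 1, g.Nz), uzn(g.Nr, g.Nz + 1), pn(g.Nr, g.Nz);
  std::copy(s.ur.begin(), s.ur.end(), urn.begin());
  std::copy(s.uz.begin(), s.uz.end(), uzn.begin());
  std::copy(s.p.begin(), s.p.end(), pn.begin());
  return List::create(_["ur"] = urn, _["uz"] = uzn, _["p"] = pn,
                      _["cg_iters"] = it);
}

static double fillFraction(const Grid& g, const std::vector<double>& phi) {
  double num = 0.0, den = 0.0;
  for (int j = g.jD; j < g.Nz; ++j)
    for (int i = 0; i < g.iRp; ++i)
      if (g.fluid(i, j)) {
        double rc = (i + 0.5);
        num += phi[g.id(i, j)] * rc;
        den += rc;
      }
  return den > 0 ? num / den : 0.0;
}

static double contactHeight(const Grid& g, const std::vector<double>& phi) {
  // phi = 0.5 crossing along the wall-adjacent pore column, measured from
  // the pore inlet (z = jD * h); returns the highest crossing.
  int i = g.iRp - 1;
  if (i < 0) return 0.0;
  double best = 0.0;
  bool all_wet = true;
  for (int j = g.jD; j < g.Nz; ++j) {
    if (!g.fluid(i, j)) break;
    double pc = phi[g.id(i, j)];
    if (pc < 0.5) all_wet = false;
    double pn = (j + 1 < g.Nz && g.fluid(i, j + 1)) ? phi[g.id(i, j + 1)] : pc;
    if (pc >= 0.5 && pn < 0.5) {
      double zc = (j - g.jD + 0.5) * g.h;
      best = std::max(best, zc + g.h * (pc - 0.5) / std::max(pc - pn, 1e-12));
    }
  }
  if (all_wet) best = (g.Nz - g.jD) * g.h;
  return best;
}

static double waterVolume(const Grid& g, const std::vector<double>& phi) {
  double v = 0.0;
  for (int j = 0; j < g.Nz; ++j)
    for (int i = 0; i < g.Nr; ++i)
      if (g.fluid(i, j)) v += phi[g.id(i, j)] * (i + 0.5);
  return v * 2.0 * M_PI * g.h * g.h * g.h;  // m^3 (times h for radius scale)
}

// Full coupled run.  Records per-step diagnostics every `rec_stride` steps
// and snapshots (phi, p, ur, uz) every `snap_dt` seconds.
// [[Rcpp::export]]
List cpp_run(List grid, List fluids, NumericMatrix phi_, NumericMatrix ur_,
             NumericMatrix uz_, NumericMatrix p_, double t0, double t_end,
             double eps, double gamma0, double cfl, double div_rtol,
             int maxit, int rec_stride, double snap_dt, double fill_stop,
             int max_steps) {
  Grid g = gridFromList(grid);
  Fluids f = fluidsFromList(fluids);
  State s;
  s.phi.assign(phi_.begin(), phi_.end());
  s.ur.assign(ur_.begin(), ur_.end());
  s.uz.assign(uz_.begin(), uz_.end());
  s.p.assign(p_.begin(), p_.end());
  s.t = t0; s.eps = eps; s.gamma = gamma0;
  const int N = g.Nr * g.Nz;
  const double h = g.h;

  const double nu_max = std::max(f.mu_w / f.rho_w, f.mu_a / f.rho_a);
  const double dt_visc = h * h / (6.0 * nu_max);
  const double dt_cap =
    std::sqrt((f.rho_w + f.rho_a) * 0.5 * h * h * h / (4.0 * M_PI * f.sigma));

  std::vector<double> nrf((g.Nr + 1) * g.Nz), gzf((g.Nr + 1) * g.Nz),
    nzf(g.Nr * (g.Nz + 1)), grf(g.Nr * (g.Nz + 1)), kap(N), urs, uzs, phis;
  std::vector<double> p_old = s.p, p_save(N);

  std::vector<double> rec_t, rec_fill, rec_ch, rec_umax, rec_vol;
  List snaps;
  std::vector<double> snap_times;
  double next_snap = t0;
  double fill_time = NA_REAL;
  std::string status = "t_end";
  int step = 0;
  long total_cg = 0;

  auto takeSnap = [&]() {
    NumericMatrix ph(g.Nr, g.Nz), pp(g.Nr, g.Nz), uu(g.Nr + 1, g.Nz),
      ww(g.Nr, g.Nz + 1);
    std::copy(s.phi.begin(), s.phi.end(), ph.begin());
    std::copy(s.p.begin(), s.p.end(), pp.begin());
    std::copy(s.ur.begin(), s.ur.end(), uu.begin());
    std::copy(s.uz.begin(), s.uz.end(), ww.begin());
    snaps.push_back(List::create(_["t"] = s.t, _["phi"] = ph, _["p"] = pp,
                                 _["ur"] = uu, _["uz"] = ww));
    snap_times.push_back(s.t);
  };

  auto record = [&]() {
    rec_t.push_back(s.t);
    rec_fill.push_back(fillFraction(g, s.phi));
    rec_ch.push_back(contactHeight(g, s.phi));
    rec_umax.push_back(maxSpeed(g, s));
    rec_vol.push_back(waterVolume(g, s.phi));
  };

  record();
  takeSnap();
  next_snap = t0 + snap_dt;

  while (s.t < t_end && step < max_steps) {
    double umax = maxSpeed(g, s);
    s.gamma = std::max(s.gamma, interfaceSpeed(g, s));
    double dt = cfl * std::min(
        std::min(dt_visc, dt_cap),
        std::min(h / std::max(umax, 1e-6),
                 0.5 * h / std::max(s.gamma, 1e-6)));
    dt = std::min(dt, t_end - s.t + 1e-30);

    // 1. interface transport on u^n
    smoothPhi(g, s.phi, phis, KAPPA_SMOOTH);
    faceNormals(g, f, phis, nrf, gzf, nzf, grf);
    levelsetStep(g, f, s, dt, nrf, nzf);

    // 2. momentum + projection on updated phi
    smoothPhi(g, s.phi, phis, KAPPA_SMOOTH);
    faceNormals(g, f, phis, nrf, gzf, nzf, grf);
    cellCurvature(g, nrf, nzf, kap);
    momentumPredictor(g, f, s, dt, kap, urs, uzs);
    // linear extrapolation of the pressure as warm start
    p_save = s.p;
    for (int c = 0; c < N; ++c) s.p[c] += s.p[c] - p_old[c];
    int it = pressureSolve(g, f, s, urs, uzs, dt, div_rtol, s.gamma, maxit);
    if (it < 0) { status = "projection_failed"; break; }
    p_old = p_save;
    total_cg += it;

    s.t += dt;
    ++step;

    if (step % 25 == 0) {
      bool bad = false;
      for (int c = 0; c < N; ++c)
        if (!std::isfinite(s.phi[c]) || !std::isfinite(s.p[c])) { bad = true; break; }
      if (!bad)
        for (double v : s.uz) if (!std::isfinite(v)) { bad = true; break; }
      if (bad) { status = "nan"; break; }
      Rcpp::checkUserInterrupt();
    }

    if (step % rec_stride == 0) record();
    double fill = fillFraction(g, s.phi);
    if (ISNA(fill_time) && fill >= fill_stop) {
      fill_time = s.t;
      record();
      takeSnap();
      status = "filled";
      break;
    }
    if (s.t >= next_snap - 1e-15) { takeSnap(); next_snap += snap_dt; }
  }
  if (step >= max_steps && status == "t_end" && s.t < t_end)
    status = "max_steps";
  if (status == "t_end") { record(); takeSnap(); }

  NumericMatrix ph(g.Nr, g.Nz), pp(g.Nr, g.Nz), uu(g.Nr + 1, g.Nz),
    ww(g.Nr, g.Nz + 1);
  std::copy(s.phi.begin(), s.phi.end(), ph.begin());
  std::copy(s.p.begin(), s.p.end(), pp.begin());
  std::copy(s.ur.begin(), s.ur.end(), uu.begin());
  std::copy(s.uz.begin(), s.uz.end(), ww.begin());

  return List::create(
    _["t"] = s.t, _["n_steps"] = step, _["status"] = status,
    _["total_cg_iters"] = (double)total_cg,
    _["fill_time"] = fill_time, _["gamma"] = s.gamma,
    _["phi"] = ph, _["p"] = pp, _["ur"] = uu, _["uz"] = ww,
    _["trace"] = List::create(_["times"] = rec_t, _["fill_fraction"] = rec_fill,
                              _["contact_point_height"] = rec_ch,
                              _["umax"] = rec_umax,
                              _["water_volume"] = rec_vol),
    _["snapshots"] = snaps);
}

// [[Rcpp::export]]
List cpp_diagnostics(List grid, NumericMatrix phi_) {
  Grid g = gridFromList(grid);
  std::vector<double> phi(phi_.begin(), phi_.end());
  return List::create(_["fill_fraction"] = fillFraction(g, phi),
                      _["contact_point_height"] = contactHeight(g, phi),
                      _["water_volume"] = waterVolume(g, phi));
}
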