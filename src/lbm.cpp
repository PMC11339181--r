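#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// D3Q19 BGK kernel on a sparse fluid-node list, with
//  - halfway bounce-back at solid links,
//  - equilibrium velocity boundaries (inlet / flux-controlled outlets),
//  - equilibrium pressure boundary (reference-density outlet),
//  - Guo forcing for the Darcy-Forchheimer porous body force, with the
//    velocity in the friction term solved implicitly (the force depends on
//    the velocity it corrects).
//
// All quantities are in lattice units; unit conversion lives on the R side.

static const int ex[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int ey[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int ez[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const double wq[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36};
static const int opp[19] = {0, 2,1, 4,3, 6,5, 8,7, 10,9, 12,11, 14,13, 16,15, 18,17};

static inline void feq_all(double rho, double ux, double uy, double uz, double *fe) {
  const double usq = 1.5 * (ux * ux + uy * uy + uz * uz);
  for (int q = 0; q < 19; ++q) {
    const double eu = 3.0 * (ex[q] * ux + ey[q] * uy + ez[q] * uz);
    fe[q] = wq[q] * rho * (1.0 + eu + 0.5 * eu * eu - usq);
  }
}

// node_type: 0 interior, 1 porous, 2 inlet, 3 velocity outlet, 4 pressure outlet
// neigh(i,q): node index streaming INTO direction q of node i (the node at
//             x_i - e_q), or -1 when that voxel is solid (bounce-back link)
// [[Rcpp::export]]
List cpp_lbm_run(IntegerMatrix neigh, IntegerVector node_type,
                 NumericMatrix u_bc, IntegerVector bc_ref,
                 NumericVector alpha, NumericVector beta,
                 double tau, int n_steps, NumericVector scale,
                 IntegerVector export_steps,
                 int check_every, double conv_tol, double mach_limit,
                 Nullable<NumericMatrix> u_init,
                 Nullable<NumericMatrix> link_frac,
                 IntegerVector ctrl_group, NumericVector ctrl_frac,
                 IntegerVector plane_idx, IntegerVector plane_group,
                 NumericMatrix plane_nrm, int verbose) {
  const int n = neigh.nrow();
  const double omega = 1.0 / tau;
  const double gfac = 1.0 - 0.5 * omega;
  std::vector<double> f(static_cast<size_t>(n) * 19), fnew(static_cast<size_t>(n) * 19);
  std::vector<double> ux(n, 0.0), uy(n, 0.0), uz(n, 0.0), rho(n, 1.0);
  if (u_init.isNotNull()) {
    NumericMatrix ui(u_init);
    for (int i = 0; i < n; ++i) { ux[i] = ui(i,0); uy[i] = ui(i,1); uz[i] = ui(i,2); }
  }
  const bool bouzidi = link_frac.isNotNull();
  NumericMatrix lf = bouzidi ? NumericMatrix(link_frac) : NumericMatrix(1, 1);

  // flux controller for the velocity-imposed (Murray) outlets: their imposed
  // velocity scale is trimmed every ctrl_every steps so the realized flux
  // through an interior measurement plane matches the target fraction of the
  // realized inlet flux (plane_group 0)
  const int n_groups = ctrl_frac.size();
  std::vector<double> fac(n_groups, 1.0);
  const int ctrl_every = 100;
  for (int i = 0; i < n; ++i) feq_all(1.0, ux[i], uy[i], uz[i], &f[static_cast<size_t>(i) * 19]);

  std::vector<double> uprev_x(ux), uprev_y(uy), uprev_z(uz);
  const double u_cap = mach_limit / std::sqrt(3.0);   // |u|_lb at the Mach limit
  List exports;
  std::vector<int> exp_steps(export_steps.begin(), export_steps.end());
  size_t exp_next = 0;
  bool converged = false, unstable = false;
  int steps_done = 0;
  double resid = NA_REAL, max_u = 0.0;

  for (int t = 0; t < n_steps; ++t) {
    const double sc = scale[t];
    double step_max_u = 0.0;
    for (int i = 0; i < n; ++i) {
      double fi[19];
      const int *nb = &neigh(0, 0); // column-major: neigh(i,q) = nb[q*n + i]
      const size_t fi19 = static_cast<size_t>(i) * 19;
      for (int q = 0; q < 19; ++q) {
        const int j = nb[static_cast<size_t>(q) * n + i];
        if (j >= 0) {
          fi[q] = f[static_cast<size_t>(j) * 19 + q];
        } else if (!bouzidi) {
          fi[q] = f[fi19 + opp[q]];               // halfway bounce-back
        } else {
          // interpolated (Bouzidi) bounce-back at the sub-voxel wall position
          const double s = lf(i, q);
          if (s < 0.5) {
            const int j2 = nb[static_cast<size_t>(opp[q]) * n + i]; // node at x + e_q
            fi[q] = (j2 >= 0)
              ? 2.0 * s * f[fi19 + opp[q]] + (1.0 - 2.0 * s) * f[static_cast<size_t>(j2) * 19 + opp[q]]
              : f[fi19 + opp[q]];
          } else {
            const double inv2s = 0.5 / s;
            fi[q] = inv2s * f[fi19 + opp[q]] + (1.0 - inv2s) * f[fi19 + q];
          }
        }
      }
      const int ty = node_type[i];
      double r = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
      for (int q = 0; q < 19; ++q) {
        r += fi[q];
        mx += fi[q] * ex[q]; my += fi[q] * ey[q]; mz += fi[q] * ez[q];
      }
      double vx, vy, vz, Fx = 0.0, Fy = 0.0, Fz = 0.0;
      if (ty == 2 || ty == 3) {
        // prescribed-velocity boundary; density taken from the adjacent
        // interior node (the node's own streamed mass is lossy at the cap)
        const int ref = bc_ref[i];
        const double rho_b = (ref >= 0) ? rho[ref] : 1.0;
        double scl = sc;
        if (ty == 3 && ctrl_group[i] > 0) scl *= fac[ctrl_group[i] - 1];
        vx = u_bc(i, 0) * scl; vy = u_bc(i, 1) * scl; vz = u_bc(i, 2) * scl;
        feq_all(rho_b, vx, vy, vz, &fnew[fi19]);
        r = rho_b;
      } else if (ty == 4) {
        // reference-pressure boundary; velocity from the interior neighbor
        const int ref = bc_ref[i];
        if (ref >= 0) { vx = ux[ref]; vy = uy[ref]; vz = uz[ref]; }
        else { vx = mx / r; vy = my / r; vz = mz / r; }
        feq_all(1.0, vx, vy, vz, &fnew[fi19]);
        r = 1.0;
      } else {
        if (ty == 1 && (alpha[i] > 0.0 || beta[i] > 0.0)) {
          // implicit friction: rho*u + (alpha + beta*|u|)*u/2 = m
          const double M = std::sqrt(mx * mx + my * my + mz * mz);
          const double A = r + 0.5 * alpha[i];
          double umag;
          if (beta[i] > 0.0 && M > 0.0) {
            umag = (-A + std::sqrt(A * A + 2.0 * beta[i] * M)) / beta[i];
          } else {
            umag = M / A;
          }
          const double fac = (M > 0.0) ? umag / M : 0.0;
          vx = mx * fac; vy = my * fac; vz = mz * fac;
          const double drag = alpha[i] + beta[i] * umag;
          Fx = -drag * vx; Fy = -drag * vy; Fz = -drag * vz;
        } else {
          vx = mx / r; vy = my / r; vz = mz / r;
        }
        const double usq = 1.5 * (vx * vx + vy * vy + vz * vz);
        for (int q = 0; q < 19; ++q) {
          const double eu3 = 3.0 * (ex[q] * vx + ey[q] * vy + ez[q] * vz);
          const double fe = wq[q] * r * (1.0 + eu3 + 0.5 * eu3 * eu3 - usq);
          double S = 0.0;
          if (ty == 1) {
            // Guo forcing source term
            const double cFx = 3.0 * (ex[q] - vx) + eu3 * 3.0 * ex[q];
            const double cFy = 3.0 * (ey[q] - vy) + eu3 * 3.0 * ey[q];
            const double cFz = 3.0 * (ez[q] - vz) + eu3 * 3.0 * ez[q];
            S = gfac * wq[q] * (cFx * Fx + cFy * Fy + cFz * Fz);
          }
          fnew[fi19 + q] = fi[q] - omega * (fi[q] - fe) + S;
        }
      }
      ux[i] = vx; uy[i] = vy; uz[i] = vz; rho[i] = r;
      const double um = vx * vx + vy * vy + vz * vz;
      if (um > step_max_u) step_max_u = um;
    }
    f.swap(fnew);
    if (n_groups > 0 && (t + 1) % ctrl_every == 0) {
      std::vector<double> Q(n_groups + 1, 0.0);
      for (R_xlen_t pp = 0; pp < plane_idx.size(); ++pp) {
        const int i = plane_idx[pp];
        Q[plane_group[pp]] += rho[i] * (ux[i] * plane_nrm(pp, 0) +
                                        uy[i] * plane_nrm(pp, 1) +
                                        uz[i] * plane_nrm(pp, 2));
      }
      for (int g = 0; g < n_groups; ++g) {
        const double target = -Q[0] * ctrl_frac[g];   // inlet flux is inward
        if (std::fabs(Q[g + 1]) > 1e-300 && target > 0.0) {
          double adj = std::sqrt(target / Q[g + 1]);
          adj = std::min(1.25, std::max(0.8, adj));
          fac[g] *= adj;
        }
      }
    }
    steps_done = t + 1;
    max_u = std::sqrt(step_max_u);
    if (!std::isfinite(max_u) || max_u > u_cap) { unstable = true; break; }

    if (exp_next < exp_steps.size() && t == exp_steps[exp_next]) {
      NumericMatrix snap(n, 4);          // u and density
      for (int i = 0; i < n; ++i) {
        snap(i,0) = ux[i]; snap(i,1) = uy[i]; snap(i,2) = uz[i]; snap(i,3) = rho[i];
      }
      exports.push_back(snap);
      ++exp_next;
    }
    if (conv_tol > 0.0 && check_every > 0 && (t + 1) % check_every == 0) {
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        const double dx = ux[i] - uprev_x[i], dy = uy[i] - uprev_y[i], dz = uz[i] - uprev_z[i];
        num += dx * dx + dy * dy + dz * dz;
        den += ux[i] * ux[i] + uy[i] * uy[i] + uz[i] * uz[i];
        uprev_x[i] = ux[i]; uprev_y[i] = uy[i]; uprev_z[i] = uz[i];
      }
      resid = (den > 0.0) ? std::sqrt(num / den) / check_every : NA_REAL;
      if (verbose) Rcpp::Rcout << "step " << t + 1 << " resid " << resid
                               << " max_u " << max_u << "\n";
      if (R_finite(resid) && resid < conv_tol && t > 2 * check_every) {
        converged = true;
        break;
      }
      Rcpp::checkUserInterrupt();
    }
  }
  NumericMatrix u_out(n, 3);
  NumericVector rho_out(n);
  for (int i = 0; i < n; ++i) {
    u_out(i, 0) = ux[i]; u_out(i, 1) = uy[i]; u_out(i, 2) = uz[i];
    rho_out[i] = rho[i];
  }
  return List::create(_["u"] = u_out, _["rho"] = rho_out, _["exports"] = exports,
                      _["steps"] = steps_done, _["converged"] = converged,
                      _["unstable"] = unstable, _["residual"] = resid,
                      _["max_u_lattice"] = max_u);
}
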