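#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Damped relaxation of the braided-stent spring network.
//
// Two linear spring types act on the wire-crossing nodes: surface springs
// along the wires (length contraction / elongation of the braid) and radial
// springs pulling every node towards the device's nominal radius measured
// from the vessel centerline (self-expansion). Integration is semi-implicit
// (symplectic) Euler with adaptive inertial damping: velocities are mixed
// towards the force direction and fully reset whenever a step would raise
// the total elastic energy, so in contact-free phases the elastic energy is
// non-increasing by construction. The braid's axial mode is orders of
// magnitude softer than the wire-stretch modes; the velocity mixing (FIRE
// style) accelerates exactly that stiff-flat regime where plain overdamped
// stepping stalls. Wall and sheath contact are hard projection constraints;
// steps in which a projection fires bypass the energy guard (the wall may
// legitimately do work on the braid).
//
// axis_type 0: straight axis, axis_params = (p0x,p0y,p0z, dx,dy,dz) unit dir
// axis_type 1: circular arc in the z=0 plane, axis_params = (cx,cy,cz, Rb)
// constrained: 0 free, 1 confined to the sheath radius, 2 fixed (grip)

static inline void axis_frame(int axis_type, const double *ap,
                              double x, double y, double z,
                              double &s, double &r, double *rhat) {
  if (axis_type == 0) {
    const double rx = x - ap[0], ry = y - ap[1], rz = z - ap[2];
    s = rx * ap[3] + ry * ap[4] + rz * ap[5];
    double vx = rx - s * ap[3], vy = ry - s * ap[4], vz = rz - s * ap[5];
    r = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (r > 1e-12) { rhat[0] = vx / r; rhat[1] = vy / r; rhat[2] = vz / r; }
    else { rhat[0] = rhat[1] = rhat[2] = 0.0; }
  } else {
    const double px = x - ap[0], py = y - ap[1];
    const double rho = std::sqrt(px * px + py * py);
    const double Rb = ap[3];
    const double fx = ap[0] + px / rho * Rb, fy = ap[1] + py / rho * Rb;
    double vx = x - fx, vy = y - fy, vz = z - ap[2];
    r = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (r > 1e-12) { rhat[0] = vx / r; rhat[1] = vy / r; rhat[2] = vz / r; }
    else { rhat[0] = rhat[1] = rhat[2] = 0.0; }
    s = Rb * std::atan2(px, -py);   // arc length from the axis start
  }
}

struct ForceEval {
  double energy;
};

static ForceEval eval_forces(const std::vector<double> &x, std::vector<double> &F,
                             const IntegerMatrix &springs, const NumericVector &l0,
                             double k_s, double k_r, const NumericVector &r_target,
                             int axis_type, const double *ap, int n, int m) {
  std::fill(F.begin(), F.end(), 0.0);
  double e_el = 0.0;
  for (int sID = 0; sID < m; ++sID) {
    const int i = springs(sID, 0), j = springs(sID, 1);
    double d[3];
    for (int q = 0; q < 3; ++q) d[q] = x[j * 3 + q] - x[i * 3 + q];
    const double L = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (L < 1e-12) continue;
    const double stretch = L - l0[sID];
    const double fmag = k_s * stretch / L;
    for (int q = 0; q < 3; ++q) {
      F[i * 3 + q] += fmag * d[q];
      F[j * 3 + q] -= fmag * d[q];
    }
    e_el += 0.5 * k_s * stretch * stretch;
  }
  double s, r, rhat[3];
  for (int i = 0; i < n; ++i) {
    axis_frame(axis_type, ap, x[i*3], x[i*3+1], x[i*3+2], s, r, rhat);
    const double dr = r_target[i] - r;
    const double fr = k_r * dr;
    for (int q = 0; q < 3; ++q) F[i * 3 + q] += fr * rhat[q];
    e_el += 0.5 * k_r * dr * dr;
  }
  return ForceEval{e_el};
}

// [[Rcpp::export]]
List cpp_spring_relax(NumericMatrix pos0, IntegerMatrix springs, NumericVector l0,
                      double k_s, double k_r, NumericVector r_target,
                      int axis_type, NumericVector axis_params,
                      double r_wall, double r_sheath, IntegerVector constrained,
                      double dt0, double tol, int max_iter, int energy_stride) {
  const int n = pos0.nrow(), m = springs.nrow();
  std::vector<double> x(n * 3), v(n * 3, 0.0), F(n * 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[i * 3 + d] = pos0(i, d);
  const double *ap = axis_params.begin();
  std::vector<double> energy;
  double max_disp = NA_REAL;
  bool converged = false;
  int it = 0;

  // FIRE-style parameters; weak background viscosity bleeds residual
  // contact-oscillation energy, and convergence must be sustained
  double dt = dt0, alpha = 0.1;
  const double dt_max = 20.0 * dt0, dt_min = 0.2 * dt0;
  const double f_inc = 1.1, f_dec = 0.5, alpha0 = 0.1, visc = 0.998;
  int streak = 0, quiet = 0;
  const int quiet_need = 25;
  double e_prev = R_PosInf;

  for (it = 0; it < max_iter; ++it) {
    ForceEval fe = eval_forces(x, F, springs, l0, k_s, k_r, r_target,
                               axis_type, ap, n, m);
    if (energy_stride > 0 && (it % energy_stride == 0)) energy.push_back(fe.energy);

    // energy guard: reset inertia on any uphill move (contact-free steps)
    bool projected_last = false;
    if (fe.energy > e_prev * (1.0 + 1e-12)) {
      std::fill(v.begin(), v.end(), 0.0);
      dt = std::max(dt * f_dec, dt_min);
      alpha = alpha0;
      streak = 0;
    }
    e_prev = fe.energy;

    // velocity mixing towards the force direction
    double vnorm = 0.0, fnorm = 0.0, P = 0.0;
    for (int i = 0; i < n; ++i) {
      if (constrained[i] == 2) continue;
      for (int d = 0; d < 3; ++d) {
        P += v[i*3+d] * F[i*3+d];
        vnorm += v[i*3+d] * v[i*3+d];
        fnorm += F[i*3+d] * F[i*3+d];
      }
    }
    vnorm = std::sqrt(vnorm); fnorm = std::sqrt(fnorm);
    if (P < 0.0) {
      std::fill(v.begin(), v.end(), 0.0);
      dt = std::max(dt * f_dec, dt_min);
      alpha = alpha0;
      streak = 0;
    } else if (fnorm > 1e-300) {
      const double mix = alpha * vnorm / fnorm;
      for (int i = 0; i < n; ++i) {
        if (constrained[i] == 2) continue;
        for (int d = 0; d < 3; ++d)
          v[i*3+d] = (1.0 - alpha) * v[i*3+d] + mix * F[i*3+d];
      }
      if (++streak > 5) { dt = std::min(dt * f_inc, dt_max); alpha *= 0.99; }
    }

    double step_max = 0.0;
    double s, r, rhat[3];
    for (int i = 0; i < n; ++i) {
      if (constrained[i] == 2) continue;
      double disp2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        v[i * 3 + d] = visc * v[i * 3 + d] + dt * F[i * 3 + d];
        x[i * 3 + d] += dt * v[i * 3 + d];
        disp2 += dt * v[i*3+d] * dt * v[i*3+d];
      }
      axis_frame(axis_type, ap, x[i*3], x[i*3+1], x[i*3+2], s, r, rhat);
      double r_lim = -1.0; bool exact = false;
      if (constrained[i] == 1 && r_sheath > 0.0) { r_lim = r_sheath; exact = true; }
      else if (r_wall > 0.0) r_lim = r_wall;
      if (r_lim > 0.0 && (r > r_lim || (exact && std::fabs(r - r_lim) > 1e-12))) {
        const double shift = r_lim - r;
        for (int d = 0; d < 3; ++d) x[i * 3 + d] += shift * rhat[d];
        const double vr = v[i*3]*rhat[0] + v[i*3+1]*rhat[1] + v[i*3+2]*rhat[2];
        if (vr > 0.0 || exact) {
          for (int d = 0; d < 3; ++d) v[i * 3 + d] -= vr * rhat[d];
        }
        projected_last = true;
        e_prev = R_PosInf;               // wall did work: suspend the guard once
      }
      if (disp2 > step_max) step_max = disp2;
    }
    (void)projected_last;
    max_disp = std::sqrt(step_max);
    quiet = (max_disp < tol) ? quiet + 1 : 0;
    if (quiet >= quiet_need) { converged = true; ++it; break; }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  // residual spring force at the final configuration (grip-force readout)
  eval_forces(x, F, springs, l0, k_s, 0.0, r_target, axis_type, ap, n, m);
  NumericMatrix pos_out(n, 3), F_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      pos_out(i, d) = x[i * 3 + d];
      F_out(i, d) = F[i * 3 + d];
    }
  return List::create(_["pos"] = pos_out, _["force"] = F_out,
                      _["iterations"] = it, _["converged"] = converged,
                      _["max_disp"] = max_disp,
                      _["energy"] = NumericVector(energy.begin(), energy.end()));
}
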