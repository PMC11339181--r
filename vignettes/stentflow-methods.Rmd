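---
title: "Models and numerics behind stentflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind stentflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stentflow` simulates braided flow-diverter (FD) treatment of intracranial
aneurysms at desk scale: synthetic vessel/sac geometry, virtual stent
deployment, a measured porous representation of the device, a lattice-
Boltzmann flow solver, and the aneurysmal mean velocity reduction (AMVR)
endpoint with its study-level statistics. This vignette records the models,
their assumptions, and the numerical decisions — including everywhere the
design was genuinely open and what was chosen.

## 1. Synthetic geometry

Patient anatomies are replaced by a parametric family: a spherical sac of
diameter $d_s$ attached over a circular neck of diameter $d_n$ to a straight
or gently curved parent tube of diameter $d_p$ (`make_sidewall_aneurysm()`),
plus a Y bifurcation for multi-outlet tests. The lumen is the union of
closed triangulated components, so watertightness holds by construction and
the analytic neck (ostium) plane is known exactly: with $r_n = d_n/2$ and
$r_p = d_p/2$ the plane sits at distance $t_0 = \sqrt{r_p^2 - r_n^2}$ from
the centerline, its normal pointing from the parent lumen into the sac, and
the sphere centre at $t_0 + \sqrt{r_s^2 - r_n^2}$. Defaults (4-mm parent,
8-mm sac, 4-mm neck) are representative internal-carotid values for a
wide-neck sidewall aneurysm, not reconstructions of any particular patient.

Openings are extended along their outward normals by five local diameters by
default (`extend_openings()`), so inlet/outlet conditions act far from the
sac; study-scale fast mode uses three diameters (section 6). Voxelization
(`voxelize()`) classifies voxel centres by per-component ray parity (a point
is inside the lumen if inside *any* closed component), labels the cap voxel
layers as inlet/outlet, and enforces 6-connectivity from the inlet; the
default spacing is $h = 0.1$ mm with 0.2–0.4 mm as coarse fast mode. Voxel
volume converges to the analytic volume at first order in $h$.

## 2. Braided stent as a spring network

The FD is a diamond braid of $n_w$ wires (half left-, half right-handed)
whose crossings are the nodes of a mass–spring system. Two linear spring
types act, mirroring the two deformation modes of a braid: *surface springs*
along the wires carry the coupling between length and circumference, and a
*radial spring* per node pulls towards the nominal radius measured from the
vessel centerline (self-expansion). Rest lengths equal the nominal-state
node distances, so the force-free state is exactly the nominal device. The
default braid angle is 75° from the device axis (typical for clinical
braided FDs) and the default wire diameter 30 µm.

*Calibration.* Stiffnesses come from tensile force-response data
(`calibrate_stiffness()`): both grips of the braid are clamped, the distal
grip is displaced, and the axial grip force is read at equilibrium. Because
the equilibrium shape depends only on the ratio $k_r/k_s$ while forces scale
with $k_s$, the fit is a 1-D search over the log ratio with the scale solved
in closed form. On noiseless synthetic data the inversion recovers the
generating pair to better than 1%; with 5% force noise, to about 10%. No
manufacturer stiffness values are published for the two device classes, so
the shipped examples calibrate against model-generated samples.

*Deployment.* `deploy()` simulates unsheathing: the braid starts compressed
in a 1-mm virtual sheath (axially elongated per the braid kinematics
$\Delta z(r) = \sqrt{\ell_0^2 - c(r)^2}$, $c(r)$ the half-cell chord) and is
released distal-to-proximal one braid-cell band at a time, the sheathed part
sliding distally as a catheter pull-back would move it. Wall contact is a
hard projection to the lumen radius with removal of the outward velocity
component. Integration is semi-implicit (symplectic) Euler with adaptive
inertial damping: velocities are mixed towards the force direction and reset
whenever a step would raise the elastic energy, so in contact-free phases
the elastic energy is non-increasing *by construction*; during contact the
guard is suspended for the step (the wall legitimately does work on the
braid). This adaptive scheme was adopted after plain overdamped stepping
proved unable to traverse the braid's axial mode, which is orders of
magnitude softer than the wire-stretch modes; for the same reason the
release ends by re-centring that nearly-flat (radius, axial-spacing) mode on
its kinematic value before the final relaxation, which then equilibrates the
stiff modes to a maximum step displacement below $10^{-4}$ mm. Nominal
deployment (4-mm device in a 4-mm tube) reproduces the nominal dimensions
within 1%; a 1-mm oversized device elongates by the braid kinematics
(roughly 2.4× at 75°). Push–pull packing, wire friction and plasticity are
out of scope.

*Metallic surface area.* From the deployed geometry, each braid row
contributes a single-hand coverage $f = (n_w/2)\, d_w / (\pi D \cos\beta)$
with local diameter $D$ and wire angle $\beta$; the crossing families
combine as $\mathrm{MSA} = 1 - (1-f)^2$, area-weighted along the stent and
capped at 1. This reproduces the expected ordering (64-wire > 48-wire
nominally; oversized < nominal) with values near the bench-reported range.

## 3. Porous representation of the deployed device

The deployed FD enters the flow solver as a homogeneous, isotropic porous
layer obeying the Darcy–Forchheimer layer law
$\Delta p = l_c v + q_c v^2$. The 16 shipped scenarios (`hr_scenarios()`)
are bench measurements of two device classes (48-wire, 64-wire) in nominal
and 1-mm-oversized deployment; oversizing opens the braid and lowers $l_c$
by an order of magnitude.

The areal law is converted to a volumetric body force
$\mathbf f = -(\alpha + \beta |\mathbf u|)\,\mathbf u$ with
$\alpha = l_c / t$ and $\beta = q_c / t$ for a layer of thickness $t$
(default one voxel), so integrating across the layer recovers the layer law.
The velocity in the force is the *local (interstitial)* velocity — the bench
definition of $v$ is a superficial ostium-average, and the two agree where
the profile is flat; the distinction is tested explicitly by the porous-plug
check, which compares the core pressure drop across a full-section plug
against the layer law evaluated at the measured core velocity and holds to
5%. `map_stent_to_porous_voxels()` rasterizes the deployed stent surface
into fluid voxels and dilates to the layer thickness; within the study all
scenario differences enter through $(l_c, q_c)$ of this homogeneous layer —
a single representative deployment per geometry defines the layer support,
which is exactly the premise of the measured-porous approach (the
measurement, not the simulated wire pose, encodes the deployment state).

## 4. Lattice-Boltzmann solver

D3Q19, BGK collision, Guo forcing. Blood is Newtonian
($\rho$ = 1055 kg/m³, $\mu$ = 3.4 mPa·s) and walls are rigid.

* **Walls**: interpolated (Bouzidi) bounce-back with sub-voxel wall
  distances computed from the triangle mesh. This was adopted after halfway
  bounce-back plateaued near 3% error on the pipe-flow oracle; with
  interpolation the steady tube profile matches the Poiseuille parabola to
  better than 1–2% of the peak at 15–20 voxels per diameter.
* **Inlet**: parabolic profile on the cap, scaled so the volume flux equals
  the mean velocity times the true cap area; boundary density taken from the
  adjacent interior node (the equilibrium-boundary density would otherwise
  drift). For pulsatile runs the profile is scaled by a periodic waveform.
* **Outlets**: Murray's law ($Q_i \propto d_i^3$). The smallest-diameter
  outlet is the 0 Pa pressure reference; all others are velocity outlets
  whose imposed scale is trimmed every 100 steps by a feedback controller so
  the realized flux through an interior measurement plane matches the target
  fraction of the realized inlet flux (the raw equilibrium boundary leaks a
  few percent on tilted caps). Realized splits match Murray fractions within
  2%, and in/out mass balance holds within 1% (fluxes are measured as
  density-weighted surface integrals on full interior cross-sections, which
  removes the weak-compressibility bias).
* **Porous force**: the friction force depends on the velocity it corrects,
  so the macroscopic velocity is solved implicitly per node (a scalar
  quadratic in $|\mathbf u|$) before the Guo source term is applied.
* **Units and stability**: the time step is the largest allowed by a lattice
  Mach limit of 0.1, with the BGK relaxation time clamped to
  $\tau \in (0.55, 1.2)$; operating points that would need $\tau < 0.55$
  are refused with advice to refine the grid or reduce the inflow. At the
  reference resolution (0.1 mm) the physical time step is of order
  $10^{-4}$ s.
* **Pulsatile mode**: the shipped inflow waveform is a 3-harmonic
  carotid-like curve, numerically normalized to unit cycle mean, systolic
  peak ≈ 1.8× the mean; any two-column CSV can replace it. A run comprises
  precursor warm-up cycles (default 2) and one export cycle with 50 equally
  spaced snapshots, from which cycle-averaged quantities are formed. At low
  Womersley number the cycle mean agrees with the steady solution at the
  cycle-mean inflow within 10%.
* **Steady fast mode**: constant inflow, convergence when the per-step
  relative velocity residual falls below $10^{-6}$; posttreatment solves
  warm-start from the previous converged field.

The area-to-flow scaling `inlet_mean_velocity_from_area()` uses
$Q = a A^b$ with defaults ($a = 3267$ SI, $b = 1.84$) chosen to give
≈ 0.25 m/s on a 4-mm inlet — a documented stand-in, configurable.

## 5. Endpoint

`detect_ostium_plane()` separates the sac: parametric geometries pass their
analytic plane through; otherwise a geometric fallback fits the parent
cylinder (principal axis, wall-voxel radius) and the sac sphere (algebraic
fit to the bulge's wall voxels, half-voxel surface correction) and solves
the cylinder–sphere neck circle for the plane — accurate to about a tenth
of a voxel and well under 1° on the synthetic family. It assumes a
near-spherical sac on a near-cylindrical parent; full Voronoi-based neck
detection for real anatomies is out of scope. STAV is the mean velocity
*magnitude* over sac voxels and export instants (the magnitude-first
convention of the AMVR literature), and
$\mathrm{AMVR} = (\mathrm{STAV}_{pre} - \mathrm{STAV}_{FD}) /
\mathrm{STAV}_{pre}$.

## 6. Study runner and the fast-mode operating point

`run_study()` enumerates one pretreatment run per geometry plus the 16
scenarios (5 geometries would give the full 80 + 5 design), computes AMVR
per run, and `study_report()` fits the power law $AMVR = a\,l_c^{\,b}$ by
ordinary least squares in log–log space ($R^2$ reported in log space; a
nonlinear refinement is available but the log-space fit is the default
because it is standard and reproducible). Group statistics use Welch's
unequal-variance two-sided t-test between device classes within each
deployment class — chosen because it reproduces both published cohort
p-values (0.0258 nominal, 0.517 oversized) from the printed group summaries
with group sizes inferred from the scenario-by-geometry design (20/15
nominal, 20/25 oversized). The 35% AMVR occlusion surrogate is applied
inclusively (AMVR ≥ 0.35 passes; the boundary convention is not otherwise
specified anywhere).

**Fast mode** (`study_fast_config()`) is the desk-scale operating point used
by the tests and the acceptance script: $h = 0.3$ mm, three-diameter opening
extensions, steady cycle-mean inflow at $\bar v = 5$ mm/s, i.e. a
creeping-flow regime (Re ≈ 6 instead of the physiological ≈ 300). The Mach
and $\tau$ constraints of section 4 make the physiological velocity
infeasible at coarse resolution, and AMVR — a velocity *ratio* governed by
the resistance of the porous layer — is robust to this rescaling: the
monotone AMVR–$l_c$ relation, the power-law fit quality ($R^2 \geq 0.91$ on
the reference geometry) and all group orderings (nominal > oversized,
64-wire > 48-wire nominally) are preserved. Absolute AMVR levels, however,
are *not* comparable to patient-scale values: convective inflow-jet
penetration is weaker at low Re, so oversized (low-resistance) scenarios
show smaller absolute reductions than published cohort means. Problem sizes:
the fast-mode study runs ≈ 33,000 fluid voxels per solve, 17 solves in
about 3 minutes on one core; the grid-convergence check (sac STAV within 5%
under halving) passes between 0.2 mm and 0.1 mm.

## 7. What the synthetic setting does and does not show

The generator emulates the geometric essentials (sac over a neck on a
parent vessel, opening extensions, one inlet/≥1 outlets) but not real
anatomical variability: tapered and tortuous parents, irregular sac shapes,
off-plane necks, branch vessels near the neck. Passing tests therefore
demonstrate correctness of the numerical chain and reproduction of the
*relative* device/sizing effects, not patient-specific accuracy.
Per-patient AMVR values from the published five-anatomy cohort are not
reproducible here by design. Other known limitations: Newtonian rheology,
rigid walls, homogeneous isotropic porous layer (no local braid-density
mapping), no thrombosis model, and a single-threaded solver.
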