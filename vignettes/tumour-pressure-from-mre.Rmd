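---
title: "Estimating tumour pressure from MR elastography: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumour pressure from MR elastography: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A growing tumour accumulates fluid and solid pressure and pushes outward on
the surrounding tissue. That finite deformation changes how shear waves
travel through the peritumoural region: an intrinsically isotropic medium
under finite strain presents direction-dependent apparent stiffness to a
propagating wave (circumferentially stiffened, radially softened around a
pressurized sphere). A standard MR elastography (MRE) inversion, which
assumes an undeformed isotropic medium, therefore shows a characteristic
halo of stiffness biases around the inclusion: elevated storage modulus in
the ring transverse to the local propagation direction, reduced values fore
and aft.

`elastopress` turns that artefact into a measurement. If the deformation
field that caused the apparent anisotropy is known up to a single scaling,
the inversion can be corrected for each candidate scaling; the correct
scaling is the one that makes the peritumoural stiffness look homogeneous
again. A closed-form mechanical model then converts the selected scaling
into a total (fluid plus solid) inclusion pressure. The output is a
noninvasive pressure estimate from wave images plus a segmented inclusion.

## Model components

### Inflation kinematics

The deformation family is the incompressible thick-shell inflation of a
sphere. With `r0` the current (imaged) inclusion radius and `R0` the
radius the inclusion would have with all pressure released, the scaling

\[ \alpha = 1 - R_0 / r_0 \]

parametrizes the family: \(\alpha = 0\) is no inflation, \(\alpha \to 1\)
is inflation from a point, \(\alpha < 0\) means the inclusion pulls inward.
Incompressibility ties the reference radius \(R\) to the current radius
\(r\) of any material shell through \(r^3 - R^3 = r_0^3 - R_0^3\), giving
the radial displacement \(\Delta r = r - R\) and a closed-form deformation
gradient: in the local radial frame
\(F = \mathrm{diag}(R^2/r^2,\; r/R,\; r/R)\), with \(\det F = 1\) exactly.
`build_deformation_volume()` evaluates this analytically at every voxel
centre in the current (as-imaged) configuration — MRE images the deformed
state, so \(R\) is recovered from the imaged \(r\). We deliberately do not
differentiate a sampled displacement volume for the spherical family: the
analytic form is exactly incompressible and free of grid error (a
numeric-gradient path, `deformation_gradient_numeric()`, exists for
user-supplied fields of arbitrary shape and as a test oracle).

### Neo-Hookean wave-modification tensors

The medium is modelled as neo-Hookean with intrinsic shear modulus
\(\mu_e\). Linearizing the wave motion about the finitely deformed state
yields a time-harmonic wave equation whose flux is not
\(G^*(\nabla v + \nabla v^T)\) but \(G^* (\mathcal{H}' : \nabla v)\), where
\(\mathcal{H}'\) is a fourth-order tensor built from the deformation
gradient, the (unit-modulus) second Piola–Kirchhoff stress
\(\hat S_e = S_e/\mu_e\) and its derivative \(\nabla_F \hat S_e\):

\[ \mathcal{H}'_{ikml} = \tfrac{1}{J}\big(F_{iq} (\nabla_F \hat S_e)_{qjmn}
   F_{ln} F_{kj} + (\hat S_e)_{nj} \delta_{im} F_{ln} F_{kj}\big), \qquad
   (\mathcal{H}' : A)_{ik} = \mathcal{H}'_{ikml} A_{ml}. \]

Two derivations in this package deserve comment:

* **The stress derivative is computed, not transcribed.** The four-term
  closed form of \(\nabla_F S_e\) used here was re-derived symbolically
  from the stress law and is validated in the test suite against central
  finite differences of `pk2_elastic()` on random unimodular deformation
  gradients (relative error below \(10^{-4}\)). This check is the ground
  truth for the constitutive algebra; any printed variant of the formula
  that fails it is rejected.
* **Normalization.** With the derivative above,
  \(\mathcal{H}'(I) : A = A + A^T - \tfrac{2}{3}\operatorname{tr}(A) I\)
  exactly, so for divergence-free wave fields the modified flux reduces to
  the standard symmetrised gradient with scalar factor 1. No empirical
  normalization constant is needed, and the modified inversion at
  \(\alpha = 0\) equals the standard inversion voxel-for-voxel (this is a
  tested invariant, at \(10^{-10}\) relative).

Viscosity is handled by scaling the full complex gradient with the same
real \(\mathcal{H}'\) — the inversion solves for one scalar complex
\(G^*\), and building a separate viscous tensor would destroy that
robustness property. Deformation-viscosity coupling and the hydrostatic
prestress contribution are neglected throughout (the latter's effect on
the wave operator is small compared with the elastic modification).

### Local weak-form inversion

`reconstruct()` estimates a complex \(G^* = G' + iG''\) per voxel under a
local-homogeneity assumption. In a moving \(7^3\)-voxel window (radius 3,
matching the ROI standoff below) the equation
\(\rho\omega^2 v + \nabla\!\cdot\!(G^* \Phi) + \nabla p = 0\), with
\(\Phi = \mathcal{H}' : \nabla v\), is tested against nine polynomial test
functions \(w_t = \nabla \times (g_t\, e_i)\) whose separable bump factors
\((1-\xi^2)^2\) vanish with their first derivatives on the window boundary.
Because each \(w_t\) is an exact curl, it is divergence-free, and because
it vanishes on the boundary, \(\int \nabla p \cdot w_t = 0\): the pressure
is eliminated analytically and never materialized. One integration by
parts moves the divergence onto the test function, so no second
differences of (noisy) data are ever taken:

\[ \rho \omega^2 \int v \cdot w_t = G^* \int \Phi : \nabla w_t
   \quad\Rightarrow\quad
   G^* = \rho\omega^2 \frac{\sum_t \overline{b_t} a_t}{\sum_t |b_t|^2}. \]

Numerical choices that matter:

* **Gradients.** \(\nabla v\) uses fourth-order central differences
  (second-order central and one-sided at support boundaries). At the
  reference configuration of 12 voxels per wavelength, a second-order
  gradient alone would bias \(G'\) by about 4%; fourth order brings the
  plane-wave bias down to about 0.2%.
* **Quadrature.** Window integrals use exact polynomial-moment weights:
  the analytic test-function factor is integrated exactly against the
  degree-6 interpolant of the data along each axis. A sampled-product
  Simpson rule was measured to bias \(G'\) by about 2% at the reference
  resolution; the moment rule removes that entirely. The divergence-free
  structure survives exactly in the discrete kernels (the trace rows of
  the flux kernel cancel identically), which is what makes the
  \(\alpha = 0\) reduction exact.
* **Validity.** A window is flagged invalid when its quadrature-weighted
  overlap with void/unsupported voxels exceeds 20%, when the flux moments
  are degenerate (near-zero wave amplitude), or when \(G' \le 0\).

### Heterogeneity sweep and pressure conversion

`alpha_sweep()` (wrapped by the `mre_pressure()` fit constructor) builds,
for every candidate \(\alpha\) from \(-0.2\) to \(1\) in steps of 0.01
(the endpoint clamped just below 1 to avoid the point-inflation
singularity), the deformation volume and the corrected reconstruction, and
records the population standard deviation of \(G'\) over a spherical-shell
ROI: inner radius \(r_0 + 3\) voxels (standing off the inclusion edge by
the window radius), width 4 voxels. The minimizing \(\alpha\) — ties
broken toward the smaller, pressure-conservative value — feeds the
closed-form inflating-sphere model

\[ p_{\mathrm{inc}}(\alpha) = 2\mu_e\Big(\tfrac{5}{4} -
   \tfrac{(1-\alpha)^4 + 4(1-\alpha)}{4}\Big), \]

obtained by integrating the radial equilibrium stress of the inflated
incompressible neo-Hookean shell from \(r_0\) to infinity (the test suite
checks the closed form against adaptive quadrature of the integrand at
\(10^{-6}\) relative). The conversion uses the intrinsic, frequency-free
\(\mu_e\); if none is supplied the median far-field background \(G'\) is
substituted with a warning, which conflates storage modulus with intrinsic
stiffness and should be avoided when a measured \(\mu_e\) exists.

Sweep-time reconstruction is restricted to the exact ROI voxels (the
heterogeneity statistic only reads those), with the deformation and tensor
algebra materialized on the window-dilated neighbourhood; the full
bounding-box and whole-volume scopes remain available through
`reconstruct()`.

## The synthetic-data generator

`simulate_waves()` provides the desk-scale stand-in for a cluster FEM
study: it solves the same linearized-about-the-inflated-state wave physics
used by the inversion — flux \(G^*(\mathcal{H}'(F(x)) : \nabla v)\) with
\(F\) from the analytic spherical map — with fourth-order finite
differences, near-incompressibility by penalty
(\(\lambda = 10^4 |G^*|\); the pressure unknown is never formed), and a
void inclusion realized as a (near-)zero-shear fluid-like interior. The
reference configuration is the study condition set: 100 Hz, \(G^* = 1.5 +
0.2i\) kPa, \(\rho = 1000\) kg/m³, a 50 mm cube at 1 mm isotropic
resolution, a 4 mm void sphere, pressures spanning 0–2.5 kPa through
\(\alpha_{\mathrm{true}}\), uniform noise at 0–15% of the maximum ROI
amplitude on all six real wave components, and 3-voxel/\(\sigma = 1\)
Gaussian smoothing after noise.

Choices made where the design was genuinely open, and why:

* **Boundaries.** The solver uses periodic boundaries with an interior
  body-force source slab rather than Dirichlet walls. With walls, the
  FFT-preconditioned iteration must additionally invert a wall-mismatch
  operator amplified by the incompressibility penalty (four orders of
  magnitude stiffer than the wave terms), and the Krylov solve stagnates
  at desk scale; with periodic boundaries the constant-coefficient
  preconditioner is exact and the iteration resolves only the compact
  inclusion perturbation (restarted GMRES; homogeneous solves converge
  in one application, inclusion solves typically in 50–250 iterations).
  Wrapped wave arrivals act as the reflections any finite experiment
  contains; they satisfy the same local wave equation and are handled —
  not merely tolerated — by the inversion.
* **Source taper.** The symbol of a wide central-difference stencil is
  non-monotone and re-crosses the physical wavenumber near the grid
  Nyquist; a sharp-edged source would excite that parasitic propagating
  band. The source slab therefore has a Gaussian profile
  (\(\sigma = 1.5\) voxels), which leaves the parasitic band unexcited,
  and sits on the periodic seam, the point of maximum wrap distance from
  the ROI, because the force support is the one region where the
  homogeneous wave equation (and hence the inversion model) does not hold.
* **Void realization.** Both the shear coefficient and the
  incompressibility penalty ramp smoothly (smoothstep over 1.5 voxels)
  from their background values to 1% of them, with the ramp placed
  strictly *inside* \(r_0\): every voxel the inversion is allowed to read
  (\(r \ge r_0\)) carries exactly the modelled coefficients, the
  transition ring is hidden behind the validity mask, and the interior
  transmits neither shear nor pressure — a (near-)traction-free void,
  which is also the boundary condition the windowed inversion is
  consistent with when its windows clip at the surface. The 1% floor
  (rather than a hard zero) keeps the interior subsystem
  well-conditioned.
* **Forward grid refinement.** For inclusion studies the forward solve
  runs on a 0.5 mm grid and is read out at the 1 mm acquisition
  resolution by stride (point) sampling. At 1 mm the simulated
  near-surface field (the deformation halo varies as \(r^{-3}\), and the
  scattered near field decays over \(\sim r_0/l\)) is visibly
  under-resolved: the shell heterogeneity floor measured on a
  zero-inflation void control drops from about 45 Pa (1 mm forward grid)
  to under 10 Pa (0.5 mm forward grid), and the coarse-grid floor tilts
  the sweep by a few hundredths of \(\alpha\) at small inflations.
  Refining the forward grid — while the inversion always works at 1 mm —
  both fixes that and removes the shared discretization between simulator
  and inversion (the forward solve no longer commits the inverse crime of
  using identical stencils). Large refinable solves are warm-started from
  the stride-2 coarser problem (Fourier zero-padding prolongation) and
  converge in well under a hundred further iterations. Point sampling,
  not block averaging, is the right readout for this inversion: the local
  scheme treats voxel values as point samples, and volume-averaging the
  steep peritumoural stiffness gradients measurably biases the recovered
  inflation upward (the `"average"` readout remains available in
  `downsample_wave()` for studying exactly that effect).

What the generator deliberately does not emulate: nonlinear finite-strain
FEM inflation of non-spherical (bumpy, egg-shaped) inclusions, transducer
and acquisition physics beyond additive uniform noise, phase unwrapping,
and heterogeneous background tissue. Because the simulator embeds the same
\(\mathcal{H}'\) machinery the inversion uses, end-to-end recovery tests
are an inverse-crime check of internal consistency plus discretization and
noise robustness — they do not validate the neo-Hookean linearization
itself against independent finite-strain physics, and passing them bounds
only numerical, not model, error for real data.

## Problem sizes and expected accuracy

The shipped tests and the acceptance script use desk-scale volumes chosen
so a full 121-point \(\alpha\) sweep costs tens of seconds: inclusion
recovery studies simulate on 32–40 mm cubes at 0.5 mm and invert the 1 mm
readout (ROI shell [7, 11) mm, roughly 4100 shell voxels); plane-wave and
zero-pressure controls use 40 mm cubes at 1 mm. Under those conditions,
measured behaviour is: plane-wave \(G'\) recovery within about 0.5% (well
inside the 2% tolerance asserted); noiseless \(\alpha\) recovery within
one grid step at \(\alpha_{\mathrm{true}} \in \{0, 0.2, 0.34\}\) with
pressure errors of 0–5%; and mean pressure error near or below 10% at the
higher pressures with 15% noise.

High inflations are the method's hard regime at this resolution. At
\(\alpha = 0.5\) the exterior surface layer is radially softened by
\((1-\alpha)^4 \approx 6\%\) of \(G'\), so the local radial wavelength
collapses to about 3 mm — three acquisition voxels — and the windows
nearest the inclusion read that layer poorly: at the true scaling the
outer half of the shell reconstructs to within 9–16 Pa while the
innermost ring carries ~100 Pa of readout error, which drags the sweep
minimum down (recovered \(\alpha \approx 0.46\), pressure error about
6%). This mirrors the degradation the original high-pressure load steps
show, and no desk-scale remedy we evaluated (larger domains, harder or
softer void realizations, window filtering, volume-averaged readout)
removes it without introducing a larger bias elsewhere; the limitation is
documented rather than papered over.

## Known limitations

* The deformation family is strictly spherical; non-spherical inclusions
  are handled only insofar as their far field resembles a sphere's.
* \(\mu_e\) must be known (or measured) for an absolute pressure; the
  background-\(G'\) fallback inherits frequency dependence.
* Windows overlapping the void edge bias the shell statistic slightly;
  with very small inclusions (2–3 voxels radius) the standoff consumes
  most of the informative halo and noise robustness degrades.
* The simulator's periodic wrap superposes decayed wave copies; at very
  low attenuation this would approach an undamped resonator, so the loss
  modulus should stay a reasonable fraction of the storage modulus
  (\(G''/G' \approx 0.13\) in the reference configuration).
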