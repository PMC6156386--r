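---
title: "Biventricular strain by hyperelastic warping: model, phantom and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biventricular strain by hyperelastic warping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Regional myocardial strain — how much the wall shortens circumferentially
and longitudinally and thickens radially between end-diastole (ED) and
end-systole (ES) — is a more sensitive marker of ventricular function than
ejection fraction, and is of particular interest in heart failure with
preserved ejection fraction, where global indices can look normal while
the muscle is already impaired.  `warpstrain` quantifies biventricular
strain from a stack of short-axis cine images by *hyperelastic warping*: a
finite-element (FE) model of the biventricular wall is deformed through
the cine frames by image-intensity forces, regularized by a hyperelastic
material energy, and the tracked deformation gradients are converted into
regional Green–Lagrange strain–time curves for the LV free wall, the
septum, and the RV free wall.

## The registration model

A tetrahedral mesh of the wall is built in the **end-systolic**
configuration (the wall is thickest there, so every other frame presents
an intensity gradient inside the initial wall volume, which is what drives
the registration).  With the mapping $\varphi(X) = X + u(X)$ and
deformation gradient $F = \partial\varphi/\partial X$, each frame is
registered by minimizing

$$E(\varphi) \;=\; \int_\Omega W(X, C)\, dV \;+\;
  \int_\Omega \tfrac{\gamma}{2}\,\bigl(R(X) - T(\varphi(X))\bigr)^2\, dV ,$$

where $R$ is the ES template image sampled once on the undeformed mesh,
$T$ the current target frame, $\gamma$ the intensity-penalty factor
(0.005), and $C = F^{\mathsf T} F$.  The classical Neo-Hookean density of
this method is $W = C_1 (I_1 - 3)$ with $I_1 = \operatorname{tr} C$
(exported as `neo_hookean_energy_density()`).  The *assembled* regularizer
uses the stress-free isochoric/volumetric split of the same material,

$$W = C_1\!\left(J^{-2/3} I_1 - 3\right) + \tfrac{\kappa}{2}(J-1)^2 ,
\qquad J = \det F,$$

because the unsplit form carries a nonzero stress at $F = I$ (its minimum
is collapse, not identity), which would contradict the basic requirement
that perfectly matched images with no boundary load leave the mesh at
rest.  The two densities coincide on isochoric deformations.

Because short-axis stacks have little through-plane information at the
base, a longitudinal displacement is prescribed on the base-plane nodes,
with amplitude equal to the mitral annular plane systolic excursion
(MAPSE) and a sine-squared time profile: relative to the ES tracking
origin, $d(t) = \mathrm{MAPSE}\,(1 - \mathrm{phase}(t))$ along the
apex-to-base axis, so the base sits MAPSE above its contracted position at
ED and at zero at ES.  Only the longitudinal component is constrained;
in-plane basal motion remains free.  The phase profile (`cycle_phase()`)
is $\sin^2(\pi t)$ of the normalized cycle time when ES falls at
mid-cycle, with the two half-waves stretched so the maximum always lands
on the ES frame.

### Weighting the two energy terms

On intensities normalized to $[0,1]$, a fully misaligned bright/dark
interface contributes $\gamma/2 \approx 2.5\times10^{-3}$ per mm³ to the
image term, while a physiological deformation ($|E| \sim 0.15$) has an
isochoric elastic density of about $0.13\,C_1$.  The registration is
intensity-driven — the material should smooth the solution, not resist
it — so the default modulus is set three orders of magnitude below parity,
$C_1 = 2\times10^{-5}$, with $\kappa = 5\times10^{-5}$ guarding against
volume collapse (step candidates that invert any element are rejected outright by
the line search as well).  These defaults were calibrated once on the
noise-free synthetic phantom at default resolution; $\gamma = 0.005$ is
the method's established value and is not touched.  Stiffer materials
visibly drag the solution toward rigid translation (the elastic cost of
the true deformation outgrows the image reward); much softer ones let the
mesh crumple into the flat parts of the intensity profile.

### Minimization

Each frame is solved by L-BFGS (memory 8) in a Sobolev metric: descent
directions are preconditioned by $(M + (10\bar h)^2 K)^{-1}$, with $M$ the
lumped mass matrix, $K$ the P1 stiffness and $\bar h$ the mean cell size.
The smoothed metric propagates the basal boundary condition and
long-range image forces through the very soft elastic interior in a few
iterations, while the L-BFGS curvature pairs restore the fine, local
alignment modes.  An Armijo backtracking line search guarantees monotone
energy decrease and rejects element-inverting steps; convergence is a
relative energy decrease below `tol` (default $10^{-6}$, at most `maxit`
= 300 iterations per frame).  Frames are visited in temporal order
starting at ES and wrapping around the cycle, each warm-started from the
previous frame.  The solver is fully deterministic.

The image term is integrated with four quadrature points per tetrahedron
(one point suffices for the elastic term, since P1 elements carry a
constant $F$).  Target frames are presmoothed with a small Gaussian
(default SD 1 voxel in-plane, 0.5 through-plane) and sampled trilinearly;
the spatial gradient used in the force assembly is the *exact* in-cell
derivative of the trilinear interpolant, so the assembled gradient is the
exact derivative of the assembled energy (verified against finite
differences to $10^{-5}$ relative).

## Local directions and the wall partition

Per-element circumferential/longitudinal/radial triads follow the
Laplace–Dirichlet rule-based construction with the myofiber angle fixed
at zero.  Two harmonic fields supply the radial direction: an
epicardial-depth field (both endocardia at 0, epicardium at 1), which is
correct in the free walls, and a transventricular field (LV endocardium 0,
RV endocardium 1), which is correct across the septum, where the depth
field is flat and its gradient turns sideways.  The two gradients are
blended per element by squared magnitude — whichever field varies locally
is the meaningful one — which makes the septal radial direction point from
the LV pool to the RV pool and keeps the triad continuous.  The
longitudinal direction comes from an apicobasal field (base at 1, an apex
node patch — the lowest 2% of nodes along the long axis — at 0),
orthogonalized against the radial direction; $e_C = e_L \times e_R$
completes a right-handed triad.  Elementwise gradients on lattice meshes
are noisy at staircase boundaries, so all fields go through one
volume-weighted cell→node→cell gradient-recovery pass.  On a structured
cylinder shell the triads agree with the analytic cylindrical frame to
better than 2°.

The wall partition solves two "pool proximity" fields (endocardium 0,
epicardium 1, everything else natural) and labels a cell `SEPTUM` when
both are below 0.5 at its centroid — it lies between the two blood pools —
with two robustness passes: septum candidates must form components that
touch both endocardial surfaces (a thick apex cap also reads "far from
the epicardium" on both fields), and satellite fragments of any label are
relabelled by neighbor majority so each region is one connected patch.

## Strain extraction

Tracking references ES, but strain is reported against ED: with $F$ the
tracked per-element gradient at a frame and $F_{ED}$ the gradient at the
ED frame (both w.r.t. ES), the relative gradient is
$F_{rel} = F F_{ED}^{-1}$ and
$E = \tfrac12\!\left(F_{rel}^{\mathsf T} F_{rel} - I\right)$, which is
exactly zero at ED and for any rigid motion.  Normal components are
$\varepsilon_{ii} = e_i \cdot E\, e_i$, and curves are unweighted means
over the elements of each region (a volume-weighted option exists).  Peak
systolic values take the most negative value of $\varepsilon_{CC}$ and
$\varepsilon_{LL}$, and the maximum of $\varepsilon_{RR}$, over the
ED→ES arc by default; a whole-cycle window is available because late
diastolic events (the atrial kick) can shift extrema past ES.  In one
dimension the Green–Lagrange measure is
$\Delta L/L + \tfrac12(\Delta L/L)^2$, slightly smaller than the
engineering strain for shortening and larger for lengthening — worth
remembering when comparing against feature-tracking numbers.

## The synthetic phantom

No imaging data ships with the package; every downstream stage is instead
validated against a deforming biventricular phantom with an analytic,
exactly invertible motion.  The geometry is a thick-walled truncated
prolate ellipsoid (LV) plus an offset, thinner ellipsoid shell clipped
against the LV epicardium (RV crescent), cut by a flat base plane.  The
motion composes two closed-form cylindrical maps: about the LV long axis,
a longitudinal contraction scaled by MAPSE (apex fixed, base moving),
apex-to-base twist, and a piecewise radial profile that redistributes
annulus area — circumferential shortening prescribed at the LV
endocardial equator with the radial thickening that volume conservation
implies — with a smoothstep ramp switching the radial squeeze off toward
the apex; and about the RV centre, a weaker, purely radial squeeze (40%
of the LV shortening amplitude) whose area deficit ramps up across the RV
blood pool, so the RV free wall shortens tangentially and thickens
radially without compressing the septum.  At end-systole the wall
Jacobian is $\sqrt{\lambda_z}$ in the compensated LV zone (≈ 0.92 at the
default MAPSE) and $\lambda_z$ in the outermost zone; with `mapse = 0`
and zero extra thickening the wall motion is exactly volume-preserving,
which is the configuration the incompressibility tests use.

Rendering emulates a short-axis cine acquisition: bright wall (1.0) on
dark background on a 96×96×16 grid of 1.5×1.5×8 mm voxels, 30 frames per
cycle, partial volume by supersampling (2× in-plane, 4× through-plane —
with only two z-subsamples per 8 mm slice the rendered edge coverage
would be quantized in ~4 mm steps), then seeded Gaussian noise (SD 0.05)
and clipping to $[0,1]$.  The phantom deliberately omits papillary
muscles, trabeculation, through-plane anatomy (valves, outflow tracts)
and intensity texture inside the wall; passing its tests therefore
demonstrates correct mechanics and correct plumbing, not robustness to
anatomical complexity or acquisition artifacts.

Ground-truth strain curves evaluate the closed-form deformation gradient
at the cell centroids and push it through *the same* remapping,
projection and averaging code as the tracked pipeline, so discretization
choices cancel in the comparison.

## Meshing

No tetrahedral mesh generator exists in the supporting stack, so the
package meshes implicit solids on a cube lattice (cubes whose centres are
inside, each split into six tetrahedra along a common diagonal — a
conforming Kuhn subdivision), with boundary facets tagged by probing the
region just outside each facet.  At a 4 mm characteristic size the
default phantom yields ≈ 2 800 nodes and ≈ 10 000 cells, the scale at
which such biventricular models are typically discretized.  Lattice
meshes have staircase boundaries; the direction-field recovery pass and
the facet-probe tagging exist precisely to be robust to them.

## Known limitations

* **Longitudinal aperture.** A homogeneous bright wall imaged in 8 mm
  slices carries almost no through-plane information away from edges.
  The basal boundary condition anchors the base and the LV apex cap
  anchors the apex, so LV longitudinal strain is recovered accurately;
  the RV free wall and (less so) the septum, which lack an anchoring
  feature at their lower ends, systematically under-recover longitudinal
  shortening by a few strain-percent.  This is a property of the energy,
  not of the optimizer: re-minimizing from the ground-truth displacement
  returns to the same displaced minimum, with an image mismatch several
  times lower than at the truth.  It is the same out-of-plane weakness
  that motivates imposing the basal excursion in the first place, and it
  is why longitudinal strain from short-axis stacks should be interpreted
  with care.
* The strain reference remap assumes the ED frame itself is tracked well;
  failures there propagate to every frame's strain.
* Region averages mix transmural strain gradients; the phantom's strong
  endo-to-epi gradient makes region means smaller in magnitude than
  midwall values.
* The statistics layer implements the conventional reproducibility tools
  (Bland–Altman with 1.96·SD limits, CV as SD of differences over mean
  pair magnitude, ICC(A,1) with F-based intervals, empirical ROC on
  strain magnitudes with Youden cutoffs, ties resolved toward the lower
  cutoff); alternative CV and ICC conventions exist and are exposed where
  reasonable.

## Problem sizes used by the examples and tests

The full-pipeline validation runs the default phantom (96×96×16 voxels,
30 frames, ≈ 15 000 cells at 3.5 mm); property tests use a reduced
phantom (64×64×12, 10 frames, ≈ 6 000 cells) and small analytic
geometries (slab, cylinder shell, spherical shell).  These sizes keep a
single-core run of the whole suite in the ten-minute range while staying
at the mesh resolution the method is normally used at.
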