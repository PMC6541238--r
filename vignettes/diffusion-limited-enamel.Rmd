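---
title: "Diffusion-limited enamel matrix secretion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-limited enamel matrix secretion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(enamelsim)
```

## The model

Enamel matrix is secreted by a front of ameloblasts that detaches from the
enamel–dentine junction (EDJ) and advances outward. `enamelsim` treats that
front as a moving boundary whose speed is limited by the diffusive supply of
"nutrients" — a stand-in for everything the secreting cells must import.
This is a one-phase Stefan problem with a curvature-regularized interface:

* **Nutrient field.** On the exterior region (everything that is neither
  dentine nor deposited matrix), the concentration `u ≥ 0` obeys
  `du/dt = D ∇²u + f`, with diffusion rate `D` and a constant background
  production `f`. At the start, `u = u_init` on the exterior; the dentine
  acts as an internal nutrient barrier (no flux through the solid). Domain
  sides are no-flux by default. Vertical crown simulations impose `u = 0`
  on the horizontal line `y = base` intersected with the exterior — the
  basal sink, a coarse model of the shorter secretion period near the crown
  cervix.
* **Interface condition.** Interface-adjacent exterior nodes are held at the
  Gibbs–Thomson value `u_Γ = max(0, u* + σ κ)`, where `κ` is the front's
  mean curvature (positive on convex ridges). With `u* = 0`, the front is a
  perfect sink except at convex tips, where the required concentration rises
  with `σ κ`; interfacial tension `σ` therefore damps high-curvature
  protrusions, and lowering it permits crenulation. For a nutrient-consuming
  (sink) interface this `+σκ` coupling is the stabilizing orientation of the
  classical Gibbs–Thomson effect; an alternative `velocity_penalty` mode
  (`V_n` reduced by `σκ` directly) is available behind a switch.
* **Stefan velocity.** The front advances along its outward normal at
  `V_n = (D/λ) ∂u/∂n`, where `λ` is the nutrient mass required per unit
  area of matrix. `V_n` is clamped at zero (deposition is irreversible;
  a flag restores signed classical Stefan motion).

Because ridges project into a larger nutrient catchment and valleys are
screened by their flanks, diffusion-limited growth exaggerates EDJ relief.
Large `f` floods the exterior so supply becomes local and uniform, and the
front approaches the uniform-thickness null model: the morphological
dilation of the EDJ by a fixed-radius disk (`geometric_extrapolation()`).

## Discretization

The domain is the unit square with a structured triangulation (`build_mesh`,
`node_density` nodes per axis, spacing `h = 1/(n-1)`; every quad is split
along the same diagonal, so the P1 stiffness matrix reduces to the 5-point
Laplacian and treats the two diagonal orientations identically). Diffusion
uses lumped-mass implicit Euler; the solid is removed from the system by a
sharp node mask, which makes the cut boundary a natural no-flux boundary.

The front is the zero contour of a signed-distance field `phi` advected with
a first-order Godunov upwind scheme (internal sub-stepping keeps
`max|V_n| dt ≤ h/2`). Numerical choices that matter, all fixed defaults:

* **Interface ring.** The Dirichlet ring is every exterior node with a solid
  4-neighbor, plus diagonal-contact nodes within one spacing of the
  interface. The unconditional axis part keeps the ring hole-free when the
  level set drifts between reinitializations; the distance-gated diagonal
  part keeps the ring one node thin and orientation-symmetric (a ring built
  from mesh edges alone treats the two diagonal orientations differently
  and imprints a visible 45° bias on the front).
* **Flux-conservative velocity.** The raw velocity pattern comes from
  one-sided normal derivatives of `u` on the exterior side. Each step it is
  rescaled so that `λ ∫ V_n ds` equals the nutrient mass actually absorbed
  at the constrained nodes (computed from the discrete reaction, including
  the stencil legs crossing into the solid when `u_Γ > 0`). The gradient
  sets the spatial ridge-versus-valley pattern; the absorbed mass sets the
  magnitude. As a result the bookkeeping identity
  `initial + produced − remaining = λ × deposited area` closes to within a
  few percent over a full run — this is checked, not assumed.
* **Velocity extension and smoothing.** Interface velocities are extended as
  constants along the normal to a band of `band_width = 5` spacings
  (nearest-adjacent-node assignment, cut off beyond 1.5 bands so obstacle
  faces far from the front never acquire speed), after a tangential Gaussian
  smoothing of width `1.5 h` that suppresses staircase noise in the
  one-sided gradients. Curvature is clamped to the grid-resolvable `1/h`;
  degenerate gradients get `κ = 0`.
* **Reinitialization.** Every `reinit_every = 5` steps the signed-distance
  property is restored by relaxing `phi_t = sgn(phi0)(1 − |∇phi|)` with a
  subcell fix that pins the zero crossing (near-interface nodes relax
  toward the subcell distance estimate — contractive even under transient
  sign disagreement). A geometric alternative (exact distance to the
  marching-triangles contour) is available as `method = "contour"` and is
  preferred for static geometry, but is not used in the growth loop: its
  linear interpolation cuts corners in concave features aligned with the
  mesh diagonal and systematically erodes convex fronts.
* **Obstacles.** Registration triangles and braces are static solid regions
  flagged on a node mask: excluded from the diffusion system (hence
  no-flux), never part of the Dirichlet ring (they neither absorb nor seed
  growth), frozen under advection, and dropped from extracted contours and
  all measurements. Fronts merging with each other or welding onto braces
  need no special casing — the level set handles the topology.

## Parameters

All quantities are dimensionless; only ratios matter. Defaults:

| parameter | default | meaning / rationale |
|---|---|---|
| `D` | 0.01 | diffusion rate; sets the screening length `√(D t)` relative to the ~0.1 feature scale so `f = 30` is transport-limited while `f = 160` is production-dominated |
| `lambda` | 5 | nutrient mass per unit deposited area; with the default supply it yields enamel ~0.1 domain units thick over a 150-step run |
| `sigma` | 0.002 | interfacial tension; `σκ` at feature-scale curvature is a few percent of near-front concentrations |
| `u_star` | 0 | reference interface concentration |
| `f` | 30 | background production; 30 / 75 / 160 are the strong / weak / excess reference levels |
| `u_init` | 1 | initial exterior concentration |
| `dt` | 0.001 | fixed time step |
| `node_density` | 129 | nodes per axis ("node density"); `h ≈ 0.0078` |
| `border` | 0.25 | proportional margin around the fitted EDJ |
| `record_every` | 4 | record every fourth front (virtual incremental lines) |

`D`, `λ`, `σ`, and `u_init` are not published quantities; they were fixed
once from the scaling arguments above so that the two regimes the model is
known for — ridge/valley divergence under scarcity, uniform dilation-like
deposition under excess — both appear under the published production levels,
and they are not tuned per experiment thereafter.

## Synthetic shapes and study conditions

The generator (`make_shape`) emulates two families of EDJ sections: closed
cusp cross-sections `r(θ) = size (1 + a cos(kθ))` minus optional Gaussian
notch concavities, and open low-relief vertical crown profiles with steep
lateral walls, closed along the base line before conversion. Optional noise
is band-limited (a few seeded harmonics), never per-vertex white noise, so
interfacial tension is not confounded with sub-mesh roughness. Identical
seeds give byte-identical shapes, and the growth engine itself has no
randomness at all.

Reference experiments used by the tests and by `scripts/acceptance.R` (sizes
chosen as sensible desk-scale study conditions):

* *Regime dichotomy*: 4-lobe cusp, `ridge_amplitude = 0.12`, border 0.35,
  node density 129; diffusion-limited run `f = 30`, 150 steps; excess run
  `f = 160`, 45 steps, compared against the dilation at matched mean
  thickness.
* *Tension sweep*: the same cusp with band-limited noise 0.04 (so tension
  has fine relief to act on), `σ ∈ {0, 0.002, 0.02}`, perimeters compared
  at matched enamel area.
* *Conservation/symmetry*: circular EDJ, border 0.30, 60 steps.
* *Vertical experiments*: wavy steep-walled profile, border 0.18, basal sink
  at `y = 0.24`, braces flanking the crown; complexity compared at matched
  mean occlusal thickness, with measured contours resampled at `2h` before
  box counting so extraction noise does not masquerade as complexity.

What these synthetic conditions do not emulate: real EDJ shape statistics,
scan noise and segmentation artifacts, 3D diffusion (slices are simulated
independently), or enamel maturation — so passing tests demonstrate the
mechanics of the model, not fidelity to any particular specimen.

## Measurements

Thickness progression is measured along labeled probe rays anchored on the
EDJ (ridge and valley landmarks; the outermost front crossing counts, and a
ray that misses the front yields `NA`, not zero). Box-counting dimension
follows the standard protocol: geometric box sizes from 2 px to a quarter of
the (padded) image side, 12 grid origins, contour rotations in 36° steps —
120 estimates per contour; rotation moves the on-pixel set with
supersampling so rotated 1-px outlines stay connected. Surface distances are
dense point-to-segment (2D) or point-to-triangle (3D) scans in both
directions. Slice stacks resample all contours to a common vertex count,
align ring starts, and triangulate between rings.

## Known limitations

* First-order interface treatment: the Dirichlet condition is imposed at
  ring nodes rather than the exact interface position, so fluxes carry an
  `O(h)` staircase error; the tangential smoothing and the flux
  renormalization control its integrated effect but local speeds remain
  grid-textured at the one-node scale.
* The boundary-value tension coupling is weak relative to typical
  concentration scales: `σ` meaningfully shapes fronts with fine relief but
  cannot fully suppress grid-seeded undulations on its own — the smoothing
  radius is the effective short-wavelength regularizer.
* Varying the production `f` alone mostly rescales the front speed once
  growth is production-dominated. At matched deposited thickness the strong
  (`f = 30`) and weak (`f = 75`) diffusion-limited vertical runs therefore
  develop statistically indistinguishable surface complexity in this
  implementation, and a fast excess run measured at a thin matched state
  still carries transient discretization roughness. The complexity contrast
  that survives robustly is between diffusion-limited fronts and the EDJ
  itself; the strict three-way ordering across production levels does not
  reproduce here (see `complexity_experiment()`, which reports whatever the
  runs yield).
* In a square domain with no-flux sides, long starved runs feel the corner
  reservoirs: a perfectly circular EDJ slowly develops a four-fold radius
  modulation. This is real geometry of the bounded problem, not numerics;
  symmetry checks use runs short enough that the effect stays below the
  measurement floor.
* 3D surfaces are stacks of independent 2D solutions; out-of-plane
  diffusion is ignored, as is any cell-level (prism, decussation)
  microstructure and all mineralization kinetics.
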