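---
title: "Models and methods behind vesselflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vesselflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselflow)
```

`vesselflow` is a desk-scale, fully synthetic counterpart to a serpentine
vessel-on-a-chip experiment. This vignette explains the physical models,
the statistical machinery, and the numerical and design choices, in the
order the pipeline runs them: geometry, rheology, flow, synthetic
acquisition, tracking, micro-PIV.

## The device and its free parameters

The physical device constrains three geometric quantities: a rectangular
cross-section of 200 µm (width w) by 50 µm (height h), and a total
serpentine path length of roughly 200 mm. Limb length, limb count, and
bend radius are not documented, so they are package design parameters:
the default `build_serpentine()` uses 34 limbs of 5 mm joined by 180°
bends of 300 µm centerline radius, which lands within 1% of 200 mm. All
printed-scale results the package reproduces — wall shear stress,
constriction speed-up, bend asymmetry, velocity profiles — are *local*
quantities, so the simulation scenes use a reduced two-limb serpentine
(1.6 mm limbs, 250 µm bends; 1.0 mm limbs for the hemorrhage scene) that
keeps the sparse linear solves in the tens of seconds on one core.

Defects are deliberately minimal: a clot is a sharp-edged rectangular
occlusion attached to one wall, parameterized by the blocked width
fraction (`spanwise_extent`, default 0.5) and its extent along the flow
(`clot_length`, default 200 µm — one channel width, enough for the
constricted flow to develop). A hemorrhage is a rectangular aperture of
`gap_length` (20 µm, the experimental scale) through the solid wall
between two adjacent limbs. Richer shapes would change nothing the
package asserts: the constriction hydraulics depend on the blocked
fraction, the bleed on the aperture's hydraulic resistance.

## Rheology

Whole blood uses the four-parameter Carreau law
$$\eta(\dot\gamma) = \eta_\infty + (\eta_0-\eta_\infty)
\left[1+(\lambda\dot\gamma)^2\right]^{(n-1)/2}$$
with η₀ = 0.056 Pa s, η∞ = 0.0035 Pa s, λ = 3.313 s, n = 0.3568 — the
parameter set used for the device simulations. The law is finite at zero
shear, so no regularization is needed; `eta0 == etaInf` collapses it to a
Newtonian fluid exactly, which the solver tests exploit.

Two fluid facts are kept verbatim from the experimental record even
though they deserve a flag: serum density is 906 kg m⁻³ (below water,
physiologically unusual), and two water viscosities circulate (1 cP and
0.653 mPa s). The package defaults to 1.0 mPa s because only that value
is consistent with the reported ≈0.1 Pa wall shear stress at
0.5 µL min⁻¹ through this cross-section; the alternative is exposed as
the `water_0653` preset, and the built-in target checks demonstrate that
the 0.1 Pa anchor rejects it.

## Depth-averaged flow model

At these scales the Reynolds number is tiny (v̄ ≈ 0.83 mm s⁻¹ at
0.5 µL min⁻¹, Re ≈ 10⁻²), so the package solves steady Stokes flow. The
shallow geometry (h ≪ channel extent) motivates a depth-averaged
two-dimensional formulation — Stokes–Brinkman:
$$\nabla\cdot(\eta\nabla \mathbf v) - \frac{12\eta}{h^2}\mathbf v
 = \nabla p,\qquad \nabla\cdot\mathbf v = 0 .$$
The 12η/h² drag is the exact closure for a parabolic out-of-plane
profile; the retained in-plane viscous term restores no-slip at the side
walls, which a plain Hele-Shaw model cannot represent. How good is this?
Depth-averaging the exact rectangular-duct series (w/h = 4) and comparing
with the Brinkman profile at equal flow rate gives a centerline deficit
of about 1.4%: that is the intrinsic model error, and the package's
acceptance checks bound solver-vs-series centerline error at 2%
(discretization adds a few tenths of a percent at 2.5 µm cells).

Discretization is a marker-and-cell staggered grid: velocities on cell
faces, pressure at cell centers, so continuity is enforced cell-wise and
flux is conserved to solver precision (the tests check 0.5%; the measured
error is at machine precision on straight sections). The fixed flow rate
enters as a source distributed over the first column of inlet cells with
the analytic Brinkman spanwise shape, which shortens the entrance
development; the outlet is a band of zero-pressure cells that absorbs the
flux. Both treatments distort the flow within roughly one channel width
of the ends, which is why every measurement function that pools over the
path (`field_profile()`, `scattering_angles()`) excludes end regions by
default.

For Carreau fluids the cell viscosity is updated from a local
characteristic shear rate
$\dot\gamma = \sqrt{\dot\gamma_{\rm in\mbox{-}plane}^2 + 12|\mathbf v|^2/h^2}$
(the depth-wise term dominates in these shallow channels) by Picard
iteration with relaxation 0.5, convergence when the largest relative
viscosity update falls below 10⁻⁶, capped at 200 iterations; the scene
solves converge in ~30. The sparse saddle system is solved directly
(sparse LU via Matrix); rows are pre-scaled (pressure in units of
η·velocity/Δx) so all coefficients are O(1).

Problem sizes: the analytic-comparison channel is 800 µm at 2.5 µm cells
(~34k cells), the baseline/thrombus scenes 10 µm cells (~17k), the
hemorrhage scene 5 µm cells (~45k) so the 20 µm gap spans four cells.
These were chosen as the coarsest grids whose refinement changes the
centerline speed by under 1% (a tested property).

## What the synthetic data emulates — and what it does not

The generator produces the two raw-data modalities of the experiment:
fluorescent 0.75 µm tracer beads, and label-free RBC texture.

*Trajectories.* Particles advect with the local depth-averaged velocity
per 2 ms frame (explicit Euler; at ~2 µm steps against ≥150 µm flow
features the integration error is negligible, and the deterministic
streamline-following test bounds lateral drift at well under a pixel).
Bead–RBC collisions are a Poisson process whose rate scales linearly with
hematocrit (default 45%, the adult whole-blood value; the rate constant
is 500 s⁻¹ at 45%), and each collision deflects the step direction by a
zero-mean Gaussian angle. The Gaussian is the minimal symmetric choice
given that only a mean ± SD of |φ| is known for the real system. The
deflection scale is calibrated (`calibrate_deflection_sd()`) so the
realized per-step mean |angle| is 1.2° — the whole-blood measurement at
0.5 µL min⁻¹, used here as a calibration anchor, not as a prediction.
Walls either reflect (the step's along-flow component is kept) or absorb;
wall-gap cells can capture particles with a small per-step probability,
emulating the few-percent trapping seen in bleed voids (a model-dependent
number, deliberately not asserted anywhere).

*Images.* Beads render as 2D Gaussian spots (σ = 2 px at 1 µm/px); RBC
texture is band-limited speckle (Gaussian-filtered white noise, ~6 µm
grain — the RBC scale) advected semi-Lagrangianly by the flow so that
consecutive frames differ by exactly the local displacement field;
additive Gaussian camera noise tops it off, and intensities are written
as 16-bit TIFF. Rendering is pure: a scene spec plus seed reproduces
byte-identical stacks.

What this does *not* emulate: deformable or discretely resolved RBCs
(the speckle is a texture, not cells), hematocrit-dependent viscosity
coupling, phase-contrast optics (halos), shot noise, depth-of-field
(particles never defocus), or out-of-plane motion. Consequently, passing
tests show that the *measurement chain* is unbiased on flows of the
modeled kind — they do not certify performance on real images, where
defocus and optical artifacts add error modes the generator lacks.

## Trajectory statistics

The per-track mean speed is the average of instantaneous speeds over
consecutive frames, ⟨v⟩ = Σᵢ vᵢ/(n−1) with vᵢ = δᵢ/Δt and
δ = √(Δx²+Δy²). The scattering angle of a step is
φᵢ = asin(|Δxᵢ|/δᵢ), with the lateral displacement Δxᵢ measured
perpendicular to the *local* centerline tangent — interpolated
bilinearly from the grid's tangent maps, because nearest-cell tangents
are quantized and measurably inflate angles inside bends. The absolute
value makes φ̄ a positive scale parameter, matching how the experimental
means are reported. Angles pool over the central 50% of the width
(`central_fraction`), mirroring the experimental practice of analyzing
beads flowing near the channel center, and exclude steps within one
channel width of the inlet/outlet (see above).

The wall-interaction length uses L = (w/2)/tan(φ̄). At ~1° the
difference between tan and sin parameterizations is below 0.03% — far
under the two-significant-figure precision of the quantity — but tan is
the geometrically exact choice for a straight-line excursion, so it is
used and recorded here.

Angle-recovery experiments (tests and the acceptance script) run at
Q = 5 µL min⁻¹ on a straight channel: per-step displacements of ~17 µm
make subpixel centroid noise (≲0.02 px at the bright, low-noise optics
used there) a subdominant contribution to the measured angles. The
deflection scale itself is flow-independent, so the 1.2° anchor is
unchanged; this is purely a measurement-baseline choice.

## Micro-PIV

Displacements come from zero-normalized cross-correlation template
matching: a 32 px interrogation window from frame A is matched at every
placement inside a 64 px search region of frame B (direct evaluation in
C++ with summed-area tables for the patch statistics), the peak is
refined by a three-point parabolic fit per axis, and displacement ×
pixel size / Δt gives velocity. A perfect correlation peak (exactly 1)
means an integer displacement and skips refinement, so integer-shifted
patterns are recovered exactly. Window validity requires a non-flat
template; the SNR is the first-to-second peak ratio with a 2 px
exclusion zone, filtered at 1.5 by default. A 3×3 neighbourhood median
test replaces outlier vectors (deviation > 2 px) and flags them as
interpolated. Defaults (32/64 px, 50% overlap) resolve the 200 µm
channel with ≥4 windows at 1 µm/px; the experimental plugin settings are
undocumented, so these are declared choices, not inferences. For the
constricted (100 µm) thrombus lumen the package uses 75% overlap — the
denser window grid samples the narrow jet evenly — and ensemble-averages
6 consecutive frame pairs, which is what steady flow permits. In that
ensemble protocol the per-pair SNR floor is relaxed to 1.1: strong shear
across a window broadens the correlation peak, which lowers the
first-to-second-peak ratio without displacing the peak, and the
ensemble mean plus the spatial median test take over the validation role
(the ensemble vectors inside the jet track the simulated field closely,
which the comparison utilities verify).

Magnitude maps are min–max normalized per scene before export, matching
the normalized vector-magnitude representation of such data; the
physical velocities are in the CSV export (the TIFF raster is written as
32-bit float in [0, 1]).

## Degenerate inputs and tie-breaks

Rasterization refuses pixels coarser than w/10, gaps finer than 4 cells,
or constrictions finer than 4 cells; disconnected fluid masks are
errors. Blank frames detect to an empty table; saturated frames warn.
Detection centroids closer than `min_separation` merge mass-weighted,
with a merge count reported. Linking is greedy mutual-nearest-neighbour
with ties broken by distance then index, so it is deterministic;
displacements beyond `max_disp` terminate tracks. Zero-length steps are
excluded from angle summaries and counted. A zero mean angle makes the
interaction length infinite, reported as `Inf` with a warning, not an
error.

## Known limitations

* The flow model is 2D depth-averaged: it cannot represent out-of-plane
  secondary flows in bends (negligible at Re ≈ 10⁻²) or the
  three-dimensional flow around a clot that does not span the full
  height. Near side walls the Brinkman boundary-layer shape deviates
  from the true duct solution by a few percent.
* Bead inertia and finite bead size are ignored (0.75 µm beads at these
  speeds have Stokes numbers ≪ 1), so margination physics is not
  represented — collisions are statistical, not mechanical.
* The bleed transit speed depends on the designed wall thickness and gap
  placement, which the physical device does not document; the package's
  hemorrhage scene is therefore a scenario of the right scale, not a
  calibrated replica, and its speed is reported as a descriptive output
  only.
* PIV near walls is biased low because windows straddle the static
  solid; measurement functions exclude window centers closer than half a
  window to a wall.
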