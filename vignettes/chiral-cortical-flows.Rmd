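---
title: "Measuring and modelling chiral cortical flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling chiral cortical flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralflow)
```

This vignette is the package's account of the science it implements:
the measurement conventions, the models and their assumptions, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test suite does
not itself compute.

## The measurement frame and the chiral statistics

Every division is analysed in a right-handed orthonormal frame fixed by
the cytokinetic ring: `e_x` is orthogonal to the ring and points toward
the cell pole lying in the direction of the embryo's anteroposterior
axis, `e_y` is parallel to the ring, and `e_z = e_x × e_y` points out of
the image toward the viewer. Internally the image y-axis points *up*
(matrix row 1 is the bottom row), which is what keeps `(e_x, e_y, e_z)`
right-handed with that `e_z`; data loaded from conventional row-down
formats must be flipped once on load. The `viewing_side` recorded in a
`division_frame` documents which side of the embryo was imaged, because
observing the same cell from the other side mirrors the image and flips
the signs of both rotational statistics.

With `v̄₁`, `v̄₂` the ROI-averaged velocities in the half opposite to and
toward the `e_x` pole respectively,

* `v_c = e_z · (e_x × v̄₂ − e_x × v̄₁)` — counter-rotation; for in-plane
  vectors this is exactly the difference of `e_y`-components. `v_c > 0`
  means the flow looks clockwise when viewed from the cytokinetic plane
  toward each pole (left-handed); `v_c < 0` is right-handed.
* `v_r = e_z · (e_x × v̄₁ + e_x × v̄₂)` — whole-cell (net) rotation.
* `v_contr = e_x · (v̄₂ − v̄₁)` — contractile flow; negative when both
  halves flow into the ring.

The ROI-2-on-the-`e_x`-side assignment is a convention: it is the one
for which ring-directed flow makes `v_contr` negative. Three exact
identities pin the sign structure down and are enforced as tests: a
mirror flip (`y → −y`) negates `v_c` and `v_r` and preserves `v_contr`;
swapping the ROI labels negates `v_c` and `v_contr` and preserves
`v_r`; and the planar reduction of `v_c` holds for every input pair.

ROI geometry follows the published measurement: inner boundary 1 µm
from the ring (keeps the saturating ring signal out of the correlation
windows), outer boundary scaled with cell size (10, 8.5, 6, 6.5, 6.5,
6.5 µm for P0, AB, P1, ABa, ABp, EMS; ~4 µm for the later small
cells), width equal to the visible ring length, and a 21 s averaging
window starting at the user-annotated onset of furrow ingression
(~10% ingression — annotation, not auto-detection, because the ring is
identified by eye). The 95% error of the mean uses the Student-t
quantile; embryo-level exclusions (lost focus, whole-cell rotation
during the window) are flags on the result, never silent rejections.

## PIV: settings, sub-pixel estimation, and one numerical trap

`compute_piv()` is a three-step multi-pass (64 → 32 → 16 px windows,
final step 8 px) FFT cross-correlation engine with a three-point
Gaussian sub-pixel fit and local-median outlier replacement (threshold
2× the local MAD plus a 0.2 px floor so uniform flow does not flag
everything). Window deformation between passes is approximated by
integer window shifting, which is sufficient at the ≤1 px/frame
displacements the 3 s frame interval produces.

One numerical detail matters more than all the others: the raw circular
cross-correlation of mean-subtracted windows carries a triangular
overlap factor `(w − |lag|)` per dimension. Left uncorrected, this
tilts the three correlation samples used by the sub-pixel fit and
produces ~0.08 px peak locking toward integer displacements — a 17%
bias on a 0.5 px/frame flow, which is exactly the regime of a
2 µm/min velocity component at 0.2 µm/px and 3 s. The estimator
therefore rescales each of the three samples by its own overlap before
fitting. The translation tests hold the whole engine to a
< 0.1 px median error across 0.25–3 px displacements.

## The synthetic stated world

The flow-movie generator advects ~800 Gaussian speckles (emulating
cortical myosin foci) with the composite field

```
v_x(x) = (v_contr/2)·s(x),   v_y(x) = v_r/2 + (v_c/2)·s(x),
s(x) = tanh((x − ring_x)/0.5 µm),
```

so the prescribed `(v_c, v_r, v_contr)` are recovered *by construction*
when the analysis conventions are right. Defaults are the AB-like
condition: `v_c = −6 µm/min` (right-handed), `v_contr = −4 µm/min`,
`v_r = 0`, a centred ring on a 24 µm axis, 0.2 µm/px, 3 s frames, 8
frames (one 21 s window). Velocity noise (default σ = 0.5 µm/min) is a
spatially correlated random field added to the *displacements*, not the
intensities, so PIV is exercised against genuine flow variability;
uncorrelated image noise is added separately. Particles are advected
exactly (Lagrangian positions, re-rendered each frame, toroidal
wrap-around) rather than by repeated image warping: repeated
interpolation blurs texture cumulatively, whereas exact advection keeps
the texture statistics stationary and the ground truth exact.

What the generators do *not* emulate — photobleaching, z-drift,
optical sectioning, 3-D cortex geometry, cell-shape change during
ingression — bounds what a green round-trip test establishes: the
*analysis chain* is correct and unbiased at realistic SNR, not that PIV
is robust to every imaging pathology.

The spindle generator integrates prescribed skew-rate and
elongation-rate profiles (trapezoidal rule) for two Gaussian poles with
Poisson photon and Gaussian camera noise; defaults (8 µm initial
separation, 1.5 µm/min elongation, 0.5 °/min skew, 3 s frames,
0.4 µm PSF) are typical of labelled tubulin imaging of an AB division.
It refuses trajectories that leave the field of view or bring the poles
within `2·psf_sigma` — the regime where detection is inherently
ambiguous is an error, not a silent degradation.

## Myosin profiles

The step-plus-Gaussian model is implemented exactly as printed: the erf
argument is `(x − x_r)/w` (no √2) and the Gaussian variance is `w²` —
both widths share the single parameter `w`. The myosin ratio uses only
the outer 20% segments of the normalised axis so the bright ring cannot
leak into it; it is scale-invariant by construction.

Fitting uses `nls` (port) with deterministic data-driven starts:
plateaus from the outer segment means, `x_r` from the profile argmax,
`w = 0.05`, and the ring weight from the excess mass above the implied
step. Bounds (`w ∈ [0.005, 0.3]`, `x_r ∈ [0.1, 0.9]`, intensities ≥ 0)
keep the ring term identifiable on finite windows. Non-convergence
returns the starting values with a flag and a warning — never silently.
Because the starts are equivariant under axis reversal, so is the whole
fit: reversing a profile maps `(I_A, I_P, x_r) → (I_P, I_A, 1 − x_r)`
to numerical precision, which the tests assert.

## The thin-film active chiral fluid model

The cortex is treated as a two-dimensional active fluid film on the
cell surface. Myosin generates an active torque density `χ·c(x)` that
tends to rotate the cortex locally; gradients of that torque drive
azimuthal flow `v(x)`, resisted by viscosity `η` and substrate friction
`γ`. On a surface of revolution with meridian radius `r(x)` the force
balance solved is

```
η (1/r²) d/dx [ r³ d/dx (v/r) ]  −  γ(x) v  =  χ dc/dx,
```

with zero tangential shear (`d(v/r)/dx = 0`) at the poles. On a flat
strip this is `η v″ − γ v = χ c′`, the familiar one-dimensional active
chiral film balance, and the hydrodynamic length `ℓ = √(η/γ)` sets the
decay of flow away from its sources. Only shapes and ratios are
compared to data, so `χ` is a free (signed) amplitude; `χ < 0` gives
right-handed counter-rotation for a ring-peaked profile.

**Why the curvature term is there.** The one-dimensional operator
`η(1/r)(r v′)′` admits finite azimuthal slip at the poles, and with
stress-free ends it *amplifies* flow near a pole: in that model an
off-centre ring predicts a *larger* counter-rotation, inverting the
qualitative physics. The full surface-of-revolution operator constrains
`v ~ r` toward the poles (a point on the axis cannot move
azimuthally), and with it an off-centre ring produces weaker
counter-rotation, as observed. The two coincide identically wherever
`r` is constant, so the flat-strip limit is unchanged.

**The asymmetry sweep and its normalisation.** `sweep_asymmetry()`
evaluates `|v_c^pred| = |v(x_r + d) − v(x_r − d)|` (`d = 4.5 µm`, the
ring-to-ROI distance) over myosin ratios and ring positions, using
Eq.-5-shaped torque profiles *at fixed total myosin*: `I_A = √ratio`,
`I_P = 1/√ratio`, profile normalised to mean 1. The constraint is not
cosmetic. The model is linear in `c`, and the response to the step
asymmetry is exactly even about a centred ring — it contributes net
rotation, not counter-rotation — so at any fixed ring amplitude the
predicted `v_c` would be *independent* of the ratio. Fixing the total
myosin makes the sweep a statement about distribution *shape* at
constant overall contractility: a more asymmetric step claims a larger
share of the budget, the normalised ring gradient shrinks, and
`|v_c^pred|` falls. That is also the physically meaningful comparison —
overall contractility (which falls as development proceeds) is a
separate, known axis of variation.

Defaults for the sweep geometry are an ellipsoid with `L = 24 µm`,
equatorial radius 8 µm and `ℓ = L/4 = 6 µm` — an AB-scale cell with a
hydrodynamic length in the same ℓ/L regime as published cortical-flow
fits. In this configuration (and robustly around it; at `ℓ ≳ L/2` the
pole proximity effect overturns it) the model reproduces all three
qualitative predictions the tests assert: maximal `|v_c^pred|` at
(ratio 1, ring 0.5), monotone decrease along both asymmetry axes, and
greater sensitivity to the ratio than to the ring position when each is
rescaled to its observed range (ratio 1→2, ring 0.5→0.6). The
sensitivity comparison uses finite differences over those ranges
because both first derivatives vanish at the symmetric point.

**Numerics.** Cell-centred finite volumes in the angular variable
`u = v/r` make the stress-free condition an exact zero-flux boundary;
the tridiagonal system is solved directly (Matrix). The scheme is
second-order (verified by a grid-refinement oracle, error ratio ≈ 4 per
halving) and the `ℓ → 0` limit matches the closed form
`v = −(χ/γ) c′` within 1% at `ℓ = L/100` on a resolved grid. The
ellipsoid is truncated 2% of `L` from each pole to avoid the coordinate
singularity. Myosin gradients are taken by centred differences with
step `10⁻⁵` of the normalised axis.

**Fitting flow profiles.** `fit_flow_profile()` fits (ℓ, amplitude) to
a nine-section transverse-flow profile. The amplitude enters linearly
and is profiled out; ℓ is found by golden-section search on a log
scale over `[0.02 L, 2 L]`. A flat residual landscape (relative change
below 10⁻⁴ across ±50% of the fitted ℓ) is flagged non-identifiable.
With 20% noise on nine bins the per-seed spread of ℓ̂ is itself
~10–15%, so recovery claims are Monte-Carlo statements (median over
seeds), not per-realisation guarantees. With uniform viscosity,
left/right hydrodynamic lengths convert to a friction ratio as
`γ_R/γ_L = (ℓ_L/ℓ_R)²`.

## Skew mechanics

The geometric relation is parameter-free: lab-frame y-velocities on the
left and right sides decompose into a rigid rotation `ω` plus a perfect
counter-rotation `v′`, giving `ω = (v_yL + v_yR)/(2R)` and
`v′ = (v_yL − v_yR)/2` at ring-to-ROI distance `R` (4.5 µm for AB). The
torque balance over the eggshell contacts gives
`ω = [(γ_L A_L − γ_R A_R)/(γ_L A_L + γ_R A_R)]·v/R`, with `ω < 0` a
clockwise skew viewed from the left; contributions from the
neighbouring-cell contact and the extra-embryonic fluid are neglected,
as in the source analysis. The two operations share sign conventions
exactly: feeding the torque balance's implied lab velocities
(`ωR ± v`) back through the geometric decomposition returns the same
`ω`, an identity the tests check to 10⁻⁹.

How the measured `v_c` maps onto the torque balance's `v` is not
determined by the printed definitions alone. The package takes
`v = |v′|` when both sides were measured and `v = |v_c|/2` as the
single-side fallback — both equal the body-frame counter-rotation speed
under the geometric decomposition — and records which mapping was used
in the result, so the convention is never implicit. Angles are radians
internally; degrees appear only at the reporting layer.

## Spindle kinematics

Pole detection smooths with a 2 px Gaussian, takes the brightest local
maximum and the next brightest at least half the expected separation
away, and refines both with a three-point Gaussian peak fit (the
smoothed spot is itself Gaussian, so this estimator is unbiased; an
intensity-weighted windowed centroid was tried first and rejected for
window-truncation bias). Tracking links detections nearest-neighbour
with identity preservation, interpolates gaps of up to two frames
linearly (flagged), and flags ambiguous crossings. Frames with fewer
than two separated maxima are excluded and flagged, mirroring how
untrackable embryos are discarded rather than guessed.

Skew angles are unsigned line-to-line angles (≤ 90°) for summaries,
with a signed variant available against a stated viewing direction.
`rate_analysis()` synchronises at anaphase-B onset (an annotation by
default; the optional detector takes the first frame where the smoothed
elongation rate exceeds 0.5 µm/min for three consecutive frames),
smooths angle and elongation with a 5-frame moving average (15 s at 3 s
sampling), estimates rates with a 9-frame sliding least-squares slope,
and takes peak rates inside the 60–120 s post-onset window. The slope
estimator is deliberately a windowed regression rather than a two-point
centred difference: differencing amplifies centroid noise roughly
threefold past the accuracy the peak-rate round-trip tests demand,
while the regression slope is exact on the ramp constructions
(a linear ramp returns its slope regardless of smoothing; a steeper
ramp outside the window is ignored).

## Pipeline and statistics

`run_pipeline()` executes simulate → piv → chirality → myosin → model →
skew → report from one JSON configuration with a single integer seed;
every output carries the seed and a configuration hash, and reruns are
bit-identical. A stage failure halts with the stage named and earlier
outputs retained. Condition comparisons use the two-sided Wilcoxon rank
sum test at 95% confidence (exact for small tie-free samples, midranks
otherwise); the tests validate it against exhaustive enumeration at
n ≤ 6 and its type-I error by simulation.

Image stacks travel as plain-text long CSV plus a JSON calibration
sidecar (`write_image_stack()`/`read_image_stack()`); no binary image
format is required anywhere.

## Known limitations

- PIV window shifting is integer-valued; true linear window deformation
  would matter only for displacements well above the regime simulated
  here.
- The film model is steady-state and one-dimensional in the long-axis
  coordinate: no meridional flow coupling, no cell-shape dynamics, no
  midbody-remnant effects — and it is not expected to describe
  asymmetric (P/EMS-lineage-like) divisions, whose flows involve
  exactly those excluded ingredients.
- The ring-position sensitivity of the sweep depends on the geometry
  regime (`ℓ/L`, ellipsoid aspect); the packaged defaults are stated
  above, and conclusions should not be extrapolated far outside them.
- Spindle tracks are 2-D in a stated projection plane; the 3-D pipeline
  is projection-then-analysis, not simultaneous multi-plane fitting.
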