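---
title: "Flux-conservation tracing of nerve fiber trajectories: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-conservation tracing of nerve fiber trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model and its assumptions

Retinal ganglion cell (RGC) axons leave their somas, bundle into the
nerve fiber layer (NFL), and converge on the optic disc along arcuate
courses around the macula. `nfflux` treats the fiber bundles as field
lines of a two-dimensional flux problem: RGCs act as sources, the disc as
the sink, and the conserved quantity is the perpendicular cross-sectional
area of the fibers — the nerve fiber flux (NFF). A sampling circle of
radius $r$ around the disc center transects all fibers; where a bundle
crosses the circle at skew angle $\beta$ to the radial direction, the
measured NFL thickness overstates the perpendicular section by
$1/\cos\beta$. The flux element in polar coordinates is

$$ d\Phi(r, \theta) = T(r,\theta)\,\cos\beta(r,\theta)\; r\, d\theta, $$

with $T$ in mm and $\Phi$ in mm². Three assumptions carry the method:

1. **Per-fiber conservation.** Each axon plus its glial support keeps an
   approximately constant perpendicular cross-section across the
   peripapillary annulus. This fails in diseased eyes (residual glial
   tissue after axon loss), which is why trajectories are *never traced
   on glaucomatous eyes*; they only receive the healthy template.
2. **Negligible peripapillary RGC origination**, except temporally. In
   the 110°–270° temporal zone the tracks run toward the macula and flux
   is genuinely lost to fiber terminations; the compensation coefficient
   $\gamma$ (below) restores a conserved quantity there.
3. **A shared trajectory anatomy.** Tracks are constrained to the arcuate
   family $\varphi(r) = a + b\,(r-r_0)^{c}$ and healthy eyes are assumed
   similar enough that their average is a meaningful template.

## Coordinate conventions

All analysis happens in one canonical frame: origin at the disc center,
distances in mm, angles in degrees, 0° at the nasal horizontal midline,
180° at the temporal maculopapillary axis (MPA), counterclockwise in
right-eye handedness; left eyes are mirrored about the vertical axis
first. The MPA rotation is applied rigidly to the whole map. The
alternative — rotating only the temporal half so that both the anatomic
horizontal and the MPA are preserved — would introduce a kink at the
hemisphere junction; with a mean MPA angle of ~7° the rigid rotation
displaces the nasal border by the same small angle, and because the two
hemisphere borders are fixed (at exactly 0° and 180°, confining tracks to
their hemisphere so segmentation or centration errors cannot propagate
across the midline), the choice only relabels a sliver of nasal flux.

Angular samples sit at bin centers $(k-\tfrac12)\,360°/1024$, so no bin
straddles a hemisphere border and hemisphere sums are exact.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| ring radii | 21 values, 1.5–3.5 mm (0.1 mm spacing) | mm | analysis annulus; spacing is uniform, only count and range are anatomically fixed |
| angular samples | 1024 per ring | — | matches the upsampled scan resolution |
| tracks | 32 per hemisphere | — | granularity of the equal-flux division |
| $r_0$ | 0.85 | mm | arcuate reference radius = 1.7-mm anchor-circle radius |
| $c$ bounds | (0.05, 5] | — | keeps the exponent fit away from degenerate flat/vertical arcs |
| convergence | max $|\Delta\beta| < 0.01$ | deg | full-grid criterion between successive skew fields |
| max iterations | 50 | — | cap with divergence guard |
| compensation zone | 110°–270° | deg | $\gamma = 1$ outside (hard step; RGC density is negligible there) |
| RGC profile | pit 0.2, peak ring 1.7, decay 1.5 | mm | parametric foveally peaked density; peak 35 000 cells/mm², total ≈ 1.1 M cells |
| magnification | $(AL - 1.82)/(24.46 - 1.82)$ | — | Bennett-style transverse scale from axial length AL |
| anchor circle | 1.7 | mm (diameter) | sector demarcations defined here, propagated outward along the template |
| sector anchors | 0, 60, 100, 140, 180, 220, 260, 300 | deg | Garway-Heath-style division (±40°, ±80°, ±120° from the temporal axis); configurable, recorded in every output |
| normative cutoff | empirical 5th percentile | — | strict inequality; `mean − 1.645·SD` would assume normality a small cohort cannot support |

All of these live in one nested configuration (`nff_default_config()`),
validated recursively with unknown keys rejected by name.

## The iteration, and its numerical choices

The tracer alternates four deterministic steps — flux density, equal-flux
division, arcuate refits, skew-map rebuild — starting from $\beta = 0$.
Numerical decisions, in the order they bite:

* **Equal-flux inversion** uses the piecewise-linear cumulative flux of
  the per-bin densities, so every track's flux equals hemisphere total/32
  to float precision by construction. When a division target lands on a
  zero-density plateau the boundary is placed at the plateau midpoint
  (the unique symmetric choice). Zero hemisphere flux is a hard error: a
  degenerate eye, not a recoverable state.
* **Arcuate fits** profile the exponent: for fixed $c$ the problem is
  linear in $(a, b)$, so $c$ is found by bounded 1-D minimization over
  three overlapping brackets (around 0.5, 1, 2 — exponent fits are
  ill-conditioned for near-radial tracks) plus a polish pass. Constant
  border lines are returned as $b = 0$, $c = 1$ with a `zero_b` flag
  rather than letting the optimizer wander an unidentifiable ridge. The
  borders (not centerlines) are fitted: the division produces borders
  directly, and the centerline is then *defined* as their midpoint, so
  its angle and derivative are exact averages of the two border models.
* **Skew interpolation** is linear in angle between track-centerline
  $\beta$ values within each hemisphere, clamped beyond the outermost
  centerlines. $\beta$ itself is analytic from the fitted model
  ($\tan\beta = r\,d\varphi/dr$), never a ring-to-ring finite difference:
  the model constraint makes the derivative exact and noise-robust. A
  finite-difference oracle agrees to 1e-6° in the tests.
* **Convergence and damping.** The criterion is the full-grid maximum of
  $|\Delta\beta|$, checked from the second iteration (a radial eye
  therefore converges exactly at iteration 2). Near-radial borders can
  have two almost-equally-good exponent fits, and measurement noise can
  make the argmin flip between them, sustaining a sub-degree limit cycle.
  When the delta sequence stops halving over a 3-iteration window, the
  update is under-relaxed (skew field averaged with its predecessor,
  factor halved down to 1/16). This breaks the cycle without moving the
  fixed point; a separate guard stops and flags genuinely diverging runs.
* **Fit accuracy limits.** At this ring design, the anchor angle $a$ is
  an extrapolation from data on [1.5, 3.5] mm down to $r_0 = 0.85$ mm;
  under 0.5° angular noise its single-fit standard deviation is ≈0.75°
  (Cramér–Rao). Single-eye anchor angles are therefore noisy by nature;
  population averaging is what makes the template tight.

## The compensation coefficient γ

The principle is that flux reduction along a temporal track is
proportional to the RGC count integrated over the track's footprint. With
$L_n(r)$ the count from the innermost ring to $r$ and $N_n$ the count out
to the track's outer extent (6 mm along the extrapolated model, a
beyond-map allowance), the fraction of the track's fibers terminated by
$r$ is $L_n(r)/N_n$ and

$$ \gamma_n(r) = \frac{1}{1 - L_n(r)/N_n} $$

exactly restores a conserved quantity under that proportionality. This
functional form is the package's own derivation from the stated
principle; its testable contract is self-consistency — on a synthetic eye
that loses flux according to the same RGC model, the γ-compensated ring
flux is constant across rings to well under 1%. γ is computed once from a
reference healthy trajectory, interpolated between centerlines
(periodically in angle, since the zone spans the 180° border), clamped to
exactly 1 outside 110°–270° (a hard step by default; the density at the
zone edges is already small), and applied only to healthy-eye tracing.
The RGC profile is parametric (quadratic ramp from a 0.2-mm RGC-free pit
to a peak ring, exponential decay outside) rather than digitized
histology, keeping the artifact download-free; only relative density
along tracks matters, since the normalization cancels in $L_n/N_n$.

## Template, sectors, and classification

Healthy trajectories are averaged border-wise *in angle space* at the 21
shared radii and then refit — averaging $(a, b, c)$ directly would
distort trajectories because the parameters are non-linearly coupled. The
per-border angular SD at each radius is retained as the variability
summary. Sector demarcations defined at the 1.7-mm anchor circle are
propagated outward as arcuate lines whose $(b, c)$ are interpolated in
angle between the template's border models; each track joins the sector
containing its centerline's anchor angle, so sector fluxes are exact
sums of track fluxes and the partition is lossless.

Per-track NFF aggregates the 21 ring values by **mean**: each ring
estimates the same conserved flux, so the mean is the natural estimator
and keeps units interpretable (mm² of fiber cross-section). Summing rings
(available as `ring_agg = "sum"`) only rescales by 21; "summing" in the
sector step refers to summing across member tracks. γ is never applied to
test eyes — a diseased macula violates the RGC model that γ encodes.
Classification is strict: a sector exactly at the 5th percentile is
normal.

## What the synthetic generator emulates — and what it does not

The generator builds eyes from a known trajectory family: borders placed
by a uniform + von Mises angular density (narrow tracks at the
superotemporal/inferotemporal bundles, producing the classic double-hump
thickness profile while per-track flux stays equal), arcs confined to the
region beyond ±60° of the nasal midline (nasal trajectories are radial),
a common exponent $c = 1.5$ within each hemisphere so centerlines are
exact arcuate curves, per-eye trajectory variation as a smooth 3-mode
random Fourier perturbation (SD 5° by default, with a guard that halves a
draw which would cross borders), MPA angles from N(6.8°, 3.1°), macular
termination driven by the same RGC footprint integral the compensation
uses, sharp wedge defects quantized to whole angular bins (so a
programmed 0.4× wedge is exactly representable on the sampling grid), and
additive Gaussian thickness noise (2 µm default). Thickness is synthesized
as $T = D/(r\cos\beta)$ with the skew map built by the same machinery the
tracer uses, so noise-free ring flux is conserved to float precision —
the generator is the oracle.

What it deliberately does **not** emulate: OCT speckle and segmentation
error structure, vessel shadows and their thickness artifacts, real
anatomic diversity of trajectory shape beyond the smooth jitter, axial
ILM tilt coupled to real geometry, and any RGC density asymmetry
(nasal/temporal or superior/inferior). Passing tests therefore show the
*algorithm* is correct and self-consistent under realistic magnitudes of
noise and variation — not that the pipeline is robust to every artifact
of real scans.

Two consequences worth knowing. First, per-track NFF uniformity of a
healthy eye holds against a template that matches the eye's trajectory
family; with 5° inter-eye jitter, narrow tracks misalign with the
population template and the per-track CV rises to the 15–20% range. The
defect-quantification checks therefore use trajectory-matched (no-jitter)
references, while template-recovery checks use the jittered cohort —
each property under the conditions where it is the meaningful claim.
Second, the generator's termination schedule is off by default: healthy
per-track uniformity and macular flux loss are mutually exclusive in a
single uncompensated map, and the compensation test enables termination
explicitly.

## Problem sizes

The shipped checks run on sizes chosen to exercise the full pipeline
while staying desk-scale: 20-eye recovery cohorts (clean and 2-µm noise),
a 24-eye jittered normative cohort, a 10-eye trajectory-matched
reference, 100-profile division oracles, and 100-seed fit Monte Carlos.
Cartesian maps default to 320 × 320 px (25-µm pitch); the polar fast path
(`output = "polar"`) generates the canonical annulus directly and is used
wherever the Cartesian resampling step itself is not under test.

## Known limitations

* Trajectories are constrained to a single-power arcuate family; real
  bundles with inflection (e.g. near the raphe) are outside the model.
* The normative machinery has no age or demographic stratification.
* Extrapolation beyond 4 mm is refused by default: trajectory errors
  amplify with radius, and near ±60° the fiber field diverges.
* The sector anchor angles ship as an editable, documented default; the
  canonical disc-rim demarcations vary across instruments and studies,
  and every output records the anchors used.
* γ rests on a literature-shaped, radially symmetric RGC profile; it is
  a population prior, not a per-eye measurement.
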