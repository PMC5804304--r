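# nfflux — nerve fiber flux analysis for wide-field peripapillary OCT

`nfflux` quantifies retinal nerve fibers over their arcuate courses from
wide-field (8 × 8 mm) peripapillary OCT nerve fiber layer (NFL) thickness
maps. It is aimed at glaucoma imaging researchers who want to move beyond
the fixed 3.4-mm-diameter circumpapillary thickness profile: instead of
comparing thickness at matching pixels, the package traces where the
fibers actually run and accumulates their cross-sectional area along each
bundle.

## The model

A cylindrical OCT section around the optic disc transects every nerve
fiber converging on the disc, but generally at a skew angle β to the
radial direction, which inflates the apparent cross-section by 1/cos β.
The **nerve fiber flux (NFF)** is the perpendicular cross-sectional area,
obtained from the thickness map T(r, θ) in polar coordinates around the
disc center as the flux element

    dΦ(r, θ) = T(r, θ) · cos β(r, θ) · r dθ     [mm²]

In analogy with Gauss' flux theorem — ganglion cells as charges, fibers as
field lines, the disc as a collective sink — the total flux through any
sampling circle is conserved as long as few fibers originate on retinal
ganglion cells (RGC) inside the annulus. `nfflux` exploits this
conservation to *recover the fiber trajectories from the thickness map
alone*:

1. resample the thickness map onto 21 rings (radii 1.5–3.5 mm, 1024
   angular samples), registered so the nasal midline sits at 0° and the
   temporal maculopapillary axis (MPA) at 180°, with left eyes mirrored;
2. divide each hemisphere of every ring into 32 tracks of equal flux
   (starting from β = 0);
3. constrain each of the 64 track border lines to the arcuate model
   φ(r) = a + b·(r − r₀)^c with r₀ = 0.85 mm;
4. rebuild the cos β map from the fitted trajectories
   (tan β = r·dφ/dr) and re-divide the refined flux density;
5. iterate until the skew field changes by less than 0.01° anywhere.

On the temporal side the tracks run into the macula, where fibers
terminate on RGCs and flux is genuinely lost. A compensation coefficient
γ(r, θ) = 1/(1 − fraction of the track's fibers terminated by radius r),
derived from a parametric foveally peaked RGC density profile integrated
along the track footprint, restores conservation inside the 110°–270°
temporal zone (γ = 1 elsewhere); it is applied only when tracing healthy
eyes.

Healthy-eye trajectories are averaged (in angle space, then refit) into a
normative template; its cos β map converts any test eye's thickness into
NFF per track, aggregated into eight Garway-Heath-style sectors (PM, IA,
OA, TF per hemisphere) anchored at the 1.7-mm disc-rim circle and
propagated outward along the average trajectories. Sectors are flagged
abnormal below the normative 5th percentile.

Because no public datasets of wide-field NFL maps with trajectory ground
truth exist, the package ships a first-class synthetic-eye generator
(`generate_eye()`, `generate_cohort()`): thickness maps built from a known
arcuate trajectory family with exactly conserved per-track flux, the
classic double-hump thickness profile, macular RGC termination, wedge
defects, and measurement noise. Every algorithmic claim in the test suite
is checked against this generator's ground truth.

## Worked example

Build a small normative reference, then analyze an eye with a 55%-deep
arcuate wedge defect on tracks 18–23:

```r
library(nfflux)

co        <- generate_cohort(n_healthy = 8, n_glaucoma = 0, seed = 11,
                             jitter_sd = 1, noise_sd_um = 2)
traces    <- lapply(co$healthy, function(e) trace_iterate(e$thickness))
template  <- average_trajectories(lapply(traces, `[[`, "trajectory"))
normative <- build_normative_flux(
  lapply(co$healthy, function(e) nff_per_track(e$thickness, template)))

eye <- generate_eye(synthetic_eye_spec(seed = 99, noise_sd_um = 2,
         defects = list(list(tracks = 18:23, scale = 0.45))),
       output = "polar")
report <- analyze_eye(eye$thickness, template, normative)
report$flux
report$sectors[, c("sector", "flux", "p5", "deviation_pct", "abnormal")]
```

```
flux_table: overall NFF 0.8903 mm^2 (mean over 21 rings)
 TF_sup  OA_sup  IA_sup  PM_sup  PM_inf  IA_inf  OA_inf  TF_inf
0.08722 0.11909 0.11124 0.10302 0.10394 0.16115 0.11735 0.08734

  sector   flux     p5 deviation_pct abnormal
1 TF_sup 0.0872 0.0857        -1.026    FALSE
2 OA_sup 0.1191 0.1128         1.381    FALSE
3 IA_sup 0.1112 0.1540       -31.095     TRUE
4 PM_sup 0.1030 0.0956         0.206    FALSE
5 PM_inf 0.1039 0.1006         1.057    FALSE
6 IA_inf 0.1612 0.1570        -0.186    FALSE
7 OA_inf 0.1173 0.1123        -0.174    FALSE
8 TF_inf 0.0873 0.0874        -0.881     TRUE
```

The wedge lands in the superior inner-arcuate sector: IA_sup reads 31%
below the normative mean and is flagged. TF_inf illustrates the nature of
a percentile cutoff: its flux sits 0.9% below an almost-identical
reference and is flagged by a hair's margin — the deviation column is what
separates a real focal defect from percentile noise. Tracing each healthy
eye converged in ~15 iterations with a final skew change below 0.01°. The
overall NFF of ~0.89 mm² is the total fiber cross-section of this
synthetic eye after the wedge loss (healthy construction: 0.94 mm²).

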