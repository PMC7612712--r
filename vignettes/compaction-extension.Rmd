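---
title: "Methods: compaction-extension morphometrics and track statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compaction-extension morphometrics and track statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compext)
```

# The problem

During mid-to-late somitogenesis the zebrafish presomitic mesoderm (PSM)
keeps elongating along the anterior-posterior (AP) axis while somites are
carved off its anterior end, yet the tissue is not growing: its volume
falls, its cell density rises, and individual cells shrink. The package
quantifies this *compaction-extension* mode of elongation at two scales:

* **tissue scale** — stage-resolved lengths, heights, widths, volumes,
  cell numbers and densities, summarised as trendlines over the somite
  stage `x`, plus a cumulative reconstruction that adds each nascent
  somite back to the PSM so that elongation can be separated from
  segmentation;
* **cell scale** — 3D nuclear tracks analysed in a moving anatomical
  reference frame, yielding neighbourhood-exchange rates (tissue
  fluidity), neighbour-pair angle dynamics (the test for directional
  intercalation), and displacement-versus-position convergence fields in
  the dorsoventral (DV) and mediolateral (ML) axes.

No public raw imaging accompanies the study conditions, so validation
rests on (a) worked examples computed from the published trendline
equations and (b) a synthetic embryo with known ground truth.

# Tissue model in the simulator

`simulate_tissue()` represents one lateral half of the PSM as a straight,
axis-aligned box. At (possibly fractional) stage `s` the box has

* posterior/anterior heights `H_p(s), H_a(s)` and widths `W_p(s), W_a(s)`
  from the four linear cross-section trendlines, blended linearly along
  the normalised AP coordinate `u` in `[0, 1]`;
* volume `V(s)` from the exponential volume trendline;
* length `L(s) = V(s) / ((H_p W_p + H_a W_a)/2)`.

The length is *derived* rather than taken from the published PSM-length
trendline because that equation (−14.1x + 155) goes negative by stage 11
— an evident misprint — while the derived length (≈259 µm at 16SS,
falling to ≈120 µm) is consistent with the volume and cross-section
data and with the ≈0–300 µm AP range over which cell statistics are
plotted. Nothing downstream uses the printed length equation.

Cells carry normalised coordinates `(u, v, w)`; world positions are
`x = b − (1−u)L`, `y = vH(s,u)`, `z = wW(s,u)` with the anterior boundary
`b` fixed between somite events. Because the box dimensions follow the
trendlines, re-evaluating world positions each frame *is* the affine
compaction flow: the tissue converges in DV/ML and the material stretches
along AP exactly as the stage series dictates, and the tailbud tip
retreats posteriorly relative to formed somites. Three further motions
are added:

1. **Motility** — isotropic Gaussian steps with per-axis standard
   deviation `m(u)·sqrt(Δt)`, where `m(u)` falls linearly from
   `motility_posterior` (default 0.4 µm·min^−1/2^) to
   `motility_anterior` (default 0.1). The 4:1 gradient was chosen once so
   that posterior neighbourhoods exchange roughly 2–3× more members than
   anterior ones over 60 min with k = 10, the qualitative fluidity
   pattern; the defaults are not fitted to any printed number.
2. **Somite formation** — every `somite_period` (default 30 min, the
   canonical zebrafish segmentation clock at 28 °C; the frame interval
   defaults to 2 min) the anterior-most slab, of length given by the
   nascent-somite length trendline, is reassigned to a new somite and
   frozen in place. Surviving cells' `u` is rescaled to the shortened
   box and `v, w` are counter-rescaled so world positions are continuous
   across the cut.
3. **Global drift/rotation** — a rigid motion built from keyframes placed
   every 5 frames (random-walk translation and rotation; per-keyframe
   standard deviations `drift_amplitude` = 2 µm and `rotation_amplitude`
   = 2°) and interpolated exactly as `interpolate_frames()` interpolates,
   so normalising the world tracks recovers the tissue-frame tracks to
   machine precision. This stands in for the uncurling, drifting tail;
   the curved geometry itself is not modelled because every statistic is
   computed frame-relatively.

**Cell-count bookkeeping.** The somite slab removes ≈17 % of PSM cells
per event, more than the per-stage decline of the cell-number trendline
(−139/stage), so the simulator adds cells (divisions, placed uniformly)
or removes them (exits, mirroring the observed departure of paraxial
cells to fin mesenchyme late in somitogenesis) at each event to keep the
PSM count on the trendline. Additions and exits are recorded, so the
identity |PSM| + Σ|somites| + |exited| = initial + additions holds at
every frame.

**Simulated span.** The default run covers stages 16–26, the span of the
live-imaging study conditions. This is also where the printed count and
volume trendlines are mutually consistent: the density they imply,
`N(x)/V(x)`, rises monotonically up to stage ≈27 and declines after
(the linear count crosses zero at x = 33.2 while the volume decays
exponentially), so later stages would make density non-monotone — an
artefact of extrapolating the printed fits, not of the tissue. The
directly fitted density trendline (0.000121x + 0.000187) rises ≈80 %
between stages 16 and 30; the count/volume quotient rises ≈74 % over the
same span and ≈106 % over 16–26.

**What the simulator does not emulate.** Mechanics (adhesion, yield
stress, jamming), the curved tail geometry, mitosis as a spatial event
(additions appear at random positions), measurement noise in positions
(tracks are exact unless the detection pipeline is used), anisotropic
cell shapes, and neighbouring tissues beyond exclusion masks. Passing
tests therefore demonstrate that the *statistics* behave correctly on
data with the assumed structure — not that the biology is mechanistically
reproduced.

# Statistical conventions

**Trendline fitting.** Linear by least squares; exponential
`y = b·e^{ax}` by `nls` initialised from the log-linear fit (falling back
to that initialisation if the iteration fails). Both families are scored
with the Gaussian AIC on the original response scale,
`AIC = n·ln(RSS/n) + 2k` with `k = 3` counting both coefficients and the
error variance, so the comparison is fair; ties break to the linear
model. R² is always reported on the original scale.

**Volumes.** Contour stacks integrate shoelace polygon areas with the
trapezoidal rule, `Σ (A_i + A_{i+1})/2 · Δz` — exact for prisms and
second-order accurate for smooth surfaces, matching how sparse manual
contours sample a tissue. Polygons must be simple; self-intersections are
rejected.

**Reference frames.** Keyframed origins interpolate linearly; rotations
interpolate by shortest-arc unit-quaternion slerp. How the original
acquisition software interpolates manually placed frames is not
documented; slerp is the constant-angular-velocity reading of "linear
interpolation" and keeps intermediate axes orthonormal (verified to
1e−6). Axes deviating from orthonormality by <1e−3 are projected to the
nearest rotation; worse input is an error. Sign conventions: +AP
anterior, +DV dorsal, +ML lateral.

**Spot detection.** Single-scale Laplacian-of-Gaussian at
σ = diameter/2.355 per axis in voxel units (anisotropic voxels
supported), strict 26-neighbourhood maxima with plateau ties broken
toward the lower voxel index, sub-voxel refinement by a three-point
quadratic per axis. Blobs closer than about the nominal diameter merge
into one detection — the same behaviour that makes the 4 µm setting the
accurate one for nuclear counting.

**Track linking.** Frame-to-frame globally optimal one-to-one assignment
(a dense Jonker–Volgenant solver in C++) between predicted and observed
positions; prediction is last position plus `ar_damping` × last velocity
× elapsed frames (damping 0.5 by default; the proprietary autoregressive
tracker this approximates is not published, so the damped-velocity class
is the design choice). Candidates beyond `max_distance × (gap+1)` are
forbidden; unmatched ends persist up to `gap_size` frames. Assignment
cost ties break toward the lower track id via an infinitesimal (1e−9)
id-proportional perturbation. Spots are canonically sorted internally, so
the pipeline is invariant to record order. Linking accuracy is scored
over detected endpoints: a link whose endpoint was never detected
measures detection, not linking.

**Neighbourhood exchange.** The default count is *cumulative distinct
entrants*: ids appearing in the k-NN set at any frame of the window that
were absent at its start. The endpoint-difference mode is retained as an
option because a cell can transit a neighbourhood and leave again —
a hand-enumerable 5-cell construction in the tests distinguishes the two.
The candidate cloud keeps somite-frozen cells: a neighbour that
segments into a somite stays in place and must not register as an
exchange. Distance ties break to the lower cell id.

**Pair angles.** The 3D elevation angle of a pair vector
(`pair_elevation_angle()`) is ±90° for AP-parallel separation and 0° for
transverse separation, with the sign carried by the DV component — an
arbitrary but fixed convention. For the intercalation test, however, each
class is measured in its *own* projected parametrization in the AP–DV
plane: the parallel class (|DV angle| < 45°, where the DV angle is
`atan2(DV, AP)`) by changes of the DV angle, the perpendicular class by
changes of the mirrored AP angle. The two parametrizations are exact
mirror images, so under isotropic motion the two change distributions
coincide by symmetry. A single shared angle would compare near-pole with
near-plane pairs, whose changes differ for purely geometric reasons
(folding at ±90°, sign flips across the transverse plane): in numerical
calibration the shared-angle statistic rejects a true null decisively
(D ≈ 0.21–0.26 under pure diffusion), while the mirrored parametrization
is calibrated (type-I ≈ 3–5 % at α = 0.05 over hundreds of seeded
replicates). Pairs are deduplicated as unordered; |angle| = 45° exactly
is excluded.

**The KS comparison.** D is the maximum ECDF difference of the absolute
per-class angle changes; the two-sided p uses the asymptotic Kolmogorov
series with effective sample size `n_a n_b / (n_a + n_b)` — conventional
at the few-hundred-pair scale of these analyses, and cross-checked
against the reference implementation in the tests.

**A finding on tissue extension and the angle statistic.** On the full
compacting tissue the parallel/perpendicular comparison is *not* null
even without any directional intercalation: random steps convect with the
extending tissue, so relative displacements accumulate ≈30 % more
variance along AP than DV over 60 min, tilting pair vectors toward the AP
axis exactly as weak intercalation would (D ≈ 0.10–0.17 at ≈500 pairs
per class, independent of the motility level because the anisotropy is
multiplicative on the noise). The non-directionality *null* is therefore
stated and tested on the construction that actually lacks a directional
signal: `simulate_field_cloud()`, where cells move by isotropic steps
plus the explicit position-dependent DV/ML convergence fields. There the
test is calibrated, and the positive control (actively rotating
nearest-neighbour pairs toward the AP axis at 2°/min) is rejected in
essentially every seed. The practical lesson for real data is that this
statistic conflates tissue-scale extension with cell-scale intercalation
unless the sample size, window and deformation rate are considered
together.

**Convergence fields.** `simulate_convergence_tracks()` draws start
positions uniformly over the posterior-PSM extent and displacements from
the linear field plus Gaussian noise whose variance is set analytically
from the target R²: `var_noise = slope²·var(start)·(1−R²)/R²`. This makes
parameter-recovery tests well-posed: at the published design (n = 1161,
R² = 0.2) the OLS slope has standard error ≈0.006, so recovery within
±0.03 is a 5-sigma statement. The intercept of the weak ML field
(R² = 0.08) has sampling error comparable to its own magnitude and is
accordingly not treated as a recoverable quantity. Within
`simulate_tissue()` the DV/ML convergence is *not* an additive field but
the affine compaction itself; the printed 120-min field slope (−0.1)
understates the compaction the height trendlines imply (≈−0.14 to −0.2
per 120 min in the posterior), and the two printed data sets cannot be
satisfied by one displacement rule, so the explicit field lives in the
dedicated generators used by the recovery and calibration analyses.

# Problem sizes and runtimes

The test suite and analysis scripts use: full default bundles of ≈2400
cells × 151 frames; field clouds of 450 cells × 31 frames (≈300 pairs,
matching the scale of the published pair analysis); 1161-track field
recoveries; 300-cell × 13-frame tracking fixtures with 5 % detection
dropouts; 100-nucleus rendered volumes of 80×80×40 voxels; 1000-replicate
KS calibrations. These sizes keep any single check within seconds while
leaving all statistical conclusions stable across seeds.

# Known limitations

* The simulator's geometry is a straight tapered box; statistics that
  depend on tissue curvature (e.g. true DV axis bending between posterior
  and anterior PSM) are only represented through the supplied local
  reference frames.
* The tracker approximates an unpublished proprietary algorithm by its
  documented behaviour class; identity decisions in dense crossings are
  not expected to match it case by case.
* Exponential trendline fitting with multiplicative noise is performed by
  unweighted least squares on the original scale for comparability with
  the linear family; strongly heteroscedastic data would warrant a
  weighted fit.
* The cumulative paraxial reconstruction evaluates printed trendlines
  outside the stage range some of them were fitted on when run to stage
  32; it reproduces the published net cell-number change but should not
  be extrapolated further.
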