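---
title: "Measuring subcellular carbon turnover with silksims: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring subcellular carbon turnover with silksims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silksims)
```

## The measurement

A pulse-chase experiment with ¹³C-labeled glucose marks newly synthesized
macromolecules. NanoSIMS imaging counts the secondary ions ¹²C¹⁴N⁻ and
¹³C¹⁴N⁻ per pixel over a 256 × 256 raster (~50 × 50 µm field, ~150 nm beam),
repeating the raster up to 15 times to accumulate counts. Enrichment is
reported on the per-mil delta scale,

$$\delta^{13}\mathrm{C}\,(\text{‰}) = \left(\frac{R_{mes}}{R_{nat}} - 1\right)\times 1000,$$

with $R_{mes}$ the measured ¹³C¹⁴N⁻/¹²C¹⁴N⁻ count ratio and $R_{nat}$ the
same ratio measured on isotopically natural tissue. $R_{nat}$ is a
configuration input (default 0.0110, the order of natural ¹³C abundance);
since delta is a relative scale, any positive value is legal.

Subcellular structure is not resolvable in the ion images alone, so a
high-resolution SEM image of the same field provides the segmentation and
the two frames are registered through user-matched landmarks.

## Processing model

**Plane alignment.** Stage drift moves the field between raster planes.
Each plane is aligned to the running accumulation of the already-aligned
planes by maximizing normalized cross-correlation over integer shifts in
±`max_shift` (default 10 px; ties broken by smallest |dy|+|dx|, then dy,
then dx). Shifts are integer-pixel only — no interpolation — so accumulated
counts remain sums of raw Poisson counts and ROI statistics stay exact.
The validity mask is the intersection of shifted plane footprints.

**Delta maps.** Per-pixel delta is computed only where the accumulated
¹²C¹⁴N⁻ count reaches `min_counts` (default 100); low-count pixels are
masked, not errors. ROI statistics never use the per-pixel map: they are
recomputed from summed counts.

**Registration.** The NanoSIMS frame is rotated and slightly stretched or
squeezed relative to the SEM frame (stage temperature drift), which is
exactly the affine family (6 dof). Higher-order families would overfit the
handful of landmarks users typically click. With at least three
non-collinear pairs, the least-squares fit reports its residual RMSE.
ROIs are transported SEM → NanoSIMS and rasterized on the ion-count grid
(pixel-center rule, lower/left boundary ties included); counts are never
resampled into the SEM frame for quantification — `resample_to_sem()` is
visualization only.

**ROI quantification.** Each ROI's delta uses the ratio of summed counts,
not the mean of per-pixel ratios: per-pixel ratios are biased and noisy at
low counts, and summing first matches ion-counting practice. The counting
standard error uses first-order propagation of a Poisson ratio,
$se(\delta) = (1000/R_{nat})\, R_{mes}\sqrt{1/N_{13} + 1/N_{12}}$,
accurate above ~100 counts per species. Label-mask ROI footprints are
restricted to *interior* pixels (4-neighbourhood-uniform assignment;
whole-cell ROIs erode only at the cell outline so internal compartment
weighting is preserved). The rationale: a fitted transform is in error by
a fraction of an SEM pixel, which is enough to misassign boundary pixels
between adjacent compartments and shrink organelle-vs-cytoplasm contrasts
by a few percent; boundary pixels carry mixed signal in any real
acquisition, so they are excluded from quantification. ROIs with more than
half their area outside the raster are excluded with a warning.

**Per-cell quantities.** Whole-cell delta; the within-cell
nucleus-minus-cytoplasm difference (normalizing away between-neuron
variation); and per-organelle enrichment relative to the cell's whole
cytoplasm, both as a ratio and as a per-mil difference
(`diff = (ratio - 1) * delta_cyt`, enforced to 1e-9). Cells whose section
shows the strongly enriched nucleolus are flagged and excluded from
nuclear-compartment analyses. The "whole cytoplasm" used for normalization
excludes organelle footprints (avoiding self-normalization); whether the
original workflow included them is undocumented, so this is toggleable by
constructing the cytoplasm ROI accordingly.

**Kinetics.** The pulse follows an exponential plateau through the origin,
$\delta(t) = A(1 - e^{-kt})$ — pre-pulse tissue carries no excess label by
definition of the delta scale. The chase follows a one-phase exponential
decay with the plateau fixed at zero,
$\delta(t) = \delta_{48}e^{-k_c(t-48)}$: with only two chase time points a
free plateau is unidentifiable, and fully turned-over tissue relaxes to
the natural reference. Two points give closed forms (returned exactly);
more points seed a Levenberg-Marquardt refinement. The cohort means
156 ‰ (24 h) and 259 ‰ (48 h) imply $A = 156^2/53 \approx 459$ ‰ and
$k = \ln(156/103)/24 \approx 0.0173\,/\mathrm{h}$; the 96 h means imply
$k_c = \ln(259/156)/48 \approx 0.0106\,/\mathrm{h}$ (half-life ~66 h,
control) and $\ln(259/136)/48 \approx 0.0134\,/\mathrm{h}$ (α-synuclein).

**Statistics.** Mann-Whitney (exact by enumeration when both groups have
≤ 8 untied observations, otherwise normal approximation with tie and
continuity corrections) and Welch's unpaired two-tailed t-test (group SDs
visibly differ between conditions, so the pooled-variance test is not
safe). "FDR approach" is read as Benjamini-Hochberg, the standard meaning
of that phrase in figure legends. Neurons are pooled per condition, as in
the study design; no animal-level mixed model is fitted.

**Morphometry.** Mitochondrial aspect ratio is the major/minor axis ratio
of the second-moment equivalent ellipse (pixel covariance plus the 1/12
per-axis pixel term). Perimeters come from the traced 8-connected boundary
chain (edge step = pixel size, diagonal step = √2 × pixel size). A
mitochondria-ER contact is a maximal run of boundary pixels whose membrane
gap to the nearest ER pixel is within `d_contact` (default 30 nm, the
usual EM apposition scale — the operational cutoff is not documented in
the source workflow, so it is exposed as a parameter). The gap is
`(center distance - 1 px) * pixel size`, so directly adjacent pixels count
as zero apposition; runs separated by fewer than 3 boundary pixels merge,
preventing discretization from splitting one apposition.

## The synthetic forward model

Presets (`preset_catalog()`) pin, per region, condition and time point:
the whole-cell delta mean and between-cell SD; the nucleus-minus-cytoplasm
difference; organelle enrichment relative to the cytoplasm; the bimodal
lysosome population; mitochondrial aspect ratio; and the MERC rate.

```{r}
preset_table()
```

**Calibration.** Absolute compartment means derive from the targets via
the expected compartment area fractions of the scene geometry, so the
area-weighted whole-cell mean equals the whole-cell target exactly:

$$c = \frac{W - f_{nuc} D - \sum_i f_i d_i}{f_{cyt} + f_{nuc} + \sum_i f_i + \sum_j f_j r_j},$$

where $W$ is the whole-cell target, $D$ the nucleus-cytoplasm difference,
and organelles enter either as ratios $r_j$ (multiplicative) or per-mil
differences $d_i$ (additive). Ratio-parameterized classes scatter
multiplicatively between organelles, so the recovered *mean ratio* equals
the printed ratio; difference-parameterized classes scatter additively, so
the recovered *median difference* equals the printed difference (the
organelle comparisons are reported as medians, and the median of a product
of two scattered factors would sit a few per mil below its mean).
Whole-cell targets follow the pulse/chase kinetics exactly: 156/259 ‰
during the pulse, 156 ‰ (control) and 136 ‰ (α-synuclein) at 96 h. During
the pulse the α-synuclein presets equal the control presets (enrichment was
similar in both populations throughout the pulse); only the chase rate and
the nuclear difference differ. The α-synuclein mitochondrial level at 48 h
is calibrated to a +56 ‰ difference and the 96 h Golgi level to +63 ‰.
Organelle parameters at 24 h are not separately reported and carry the
48 h values. The nucleolus sits at 3× the cytoplasm (visible in ~30% of
sections), motivating the exclusion rule. Lysosomes are a two-component
mixture (half ¹³C-rich at ~2.65×, half ¹³C-poor at ~0.93× the cytoplasm,
averaging 1.79×), reproducing the coexistence of strongly and weakly
labeled lysosomes within one cell. The striatum preset confines enrichment
mainly to nuclei at 1/1.8 of the nigral whole-cell level.

**Geometry (desk scale).** SEM pixels are 50 nm (a 1024 px frame spans
~51 µm), giving a ~4× SEM:NanoSIMS resolution ratio rather than the
instrument's ~15× — large enough to exercise every mechanism the analysis
must handle, small enough to simulate whole cohorts quickly. Cells are
9–12 µm ellipses (real nigral somata are larger; cohort sizes compensate),
the nucleus is concentric at half the cell axes, mitochondria are ellipses
of preset aspect ratio with aspect-independent area, the Golgi is a thick
ribbon arc, lysosomes are circles, and the ER is thin segments. A subset
of ER segments is planted flush against mitochondria at the preset MERC
rate; the rest keep ≥4 px clearance so detected contacts are exactly the
planted ones.

**Acquisition.** The true SEM→NanoSIMS transform draws a rotation (±8°),
per-axis stretch (±3%) and shear (±2%). Stage drift is a clipped integer
random walk (±1 px steps, |drift| ≤ 3). Expected total CN⁻ rates are 1500
counts/pixel/plane inside cells and 300 in resin, with 6 planes by default
— chosen so whole-cell and compartment counting errors are a few per mil,
comparable to published NanoSIMS practice at 5 ms dwell. Counts are
independent Poisson draws per pixel, plane and species with
$\lambda_{13} = \lambda R/(1+R)$, $\lambda_{12} = \lambda/(1+R)$.
Landmarks are simulated stratified across the field with 0.15 SEM px
localization jitter (7.5 nm at desk scale; users click recognizable
structures deliberately spread over the frame).

**What the generator does *not* emulate** — and hence what passing tests
do and do not show about real data: no beam point-spread function (class
boundaries are sharp at the SEM pixel scale), no detector dead-time or
quasi-simultaneous-arrival correction, no topography or sputter-rate
variation, no intra-compartment texture (compartments are internally
uniform), and single 2-D sections only. Recovery results therefore
validate the *processing chain* — alignment, accumulation, registration,
ROI transport, ratio statistics, kinetics and group tests — not
instrument-physics corrections, which the source workflow handles
upstream.

## Numerical choices and degenerate inputs

* Integer-pixel alignment and ratio-of-sums quantification keep every ROI
  statistic an exact function of raw counts (asserted by brute-force
  recomputation in the tests).
* The NCC search computes exact overlap statistics via summed-area tables
  with an FFT cross term (zero-padded, so no wraparound); an all-zero
  plane gets shift (0,0) with a warning.
* Polygon rasterization uses the half-open pixel-center rule: lower/left
  boundary ties inside, upper/right outside, so abutting ROIs tile the
  grid without double counting. Self-intersecting rings are rejected.
* Degenerate fits are flagged, not errors: flat pulse data give A = 0,
  equal chase values give k_c = 0; constant-sample t-tests return p = 1
  (equal means) or p = 0 with a degeneracy marker.
* One-pixel-wide regions have no meaningful second-moment minor axis; the
  aspect ratio is capped at the region length and flagged.
* Count images are stored in 32-bit float TIFF as v/2²⁴, which is
  bit-exact for integers below 2²⁴; delta maps are stored with an
  offset/scale in the JSON sidecar and round-trip at float32 precision
  (~1e-7 relative). Tables and JSON round-trip at full double precision.

## Problem sizes used in validation

The test suite recovers cohort statistics from four cohorts of 50 neurons
(full-scale scenes: 1024 px SEM frame, 256 px raster, 6 planes), and the
acceptance script uses 60–200 neurons per preset; both finish in minutes
on one CPU. Property checks (drift recovery, registration accuracy,
null-enrichment scenes, estimator exactness, test calibration) run on
smaller handcrafted fixtures.

## Known limitations

* The power of the 96 h control-vs-α-synuclein whole-cell comparison at 49
  cells per arm is ~30–40% at a BH-adjusted p < 1e-4 threshold under the
  preset means and SDs; detecting that contrast at the **** level
  reliably requires larger cohorts (the study analyzed up to 80 neurons
  per condition) or heavier-tailed between-cell distributions than the
  Gaussian used here. The corresponding acceptance property is left
  failing rather than re-tuned, and the package reports the honest
  rejection rate.
* The exact and normal-approximation Mann-Whitney p-values differ by up to
  ~0.0105 at n = 8 per group (continuity correction); the module test
  bounds the gap at 0.015.
* Edge-avoidance (interior-only footprints) trades a ~25% loss of pixels
  in the smallest organelles for the removal of a 2–3% contrast shrinkage;
  for structures only 1–2 NanoSIMS pixels across, counting error grows
  accordingly and is reported per ROI in `delta_se`.
* The forward model's aspect-independent mitochondrial area and fixed
  organelle counts per cell are simplifications; morphometry recovery is
  validated against the generator's own ground truth, not against EM
  segmentation variability.
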