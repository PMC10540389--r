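# silksims

Quantifying where and how fast neurons incorporate and turn over
glucose-derived carbon, from correlated SEM + NanoSIMS imaging.

In a stable-isotope pulse-chase experiment, animals drink
¹³C-labeled glucose for 48 h (pulse) and then unlabeled glucose (chase).
NanoSIMS imaging of brain sections counts the secondary ions ¹²C¹⁴N⁻ and
¹³C¹⁴N⁻ per pixel, and the enrichment is expressed on the per-mil delta
scale against tissue with natural isotopic composition:

```
delta13C (permil) = (R_mes / R_nat - 1) * 1000,     R = 13C14N- / 12C14N-
```

Because the NanoSIMS raster is coarser than, rotated against, and slightly
stretched relative to the SEM image of the same field, subcellular
quantification requires: (1) aligning and accumulating the repeated raster
planes (integer-pixel shifts, so Poisson counting statistics survive),
(2) fitting an affine SEM→NanoSIMS transform from user-matched landmarks,
(3) transporting SEM-drawn compartment ROIs (cell body, cytoplasm, nucleus,
nucleolus, mitochondria, Golgi, lysosomes, ER) onto the native ion-count
grid, and (4) computing each ROI's delta from the **ratio of summed counts**
with its Poisson counting error

```
se(delta) = (1000 / R_nat) * R_mes * sqrt(1/N13 + 1/N12).
```

Downstream, the package derives the study's per-cell quantities — whole-cell
enrichment, the nucleus-minus-cytoplasm difference (nucleolus-containing
sections excluded), organelle enrichment normalized to the cell's whole
cytoplasm — fits the pulse kinetics `delta(t) = A(1 - exp(-k t))` and the
chase decay `delta(t) = delta48 * exp(-k_c (t - 48))`, and runs the group
statistics (Mann-Whitney or Welch tests with Benjamini-Hochberg FDR).
A morphometry module measures mitochondrial length-to-width ratios and
mitochondria-ER contact (MERC) frequency per µm of mitochondrial perimeter
on the SEM-frame masks.

Because no public instrument data accompany the study, the package ships a
**calibrated synthetic forward model**: condition/time-point presets
(`preset_catalog()`) place elliptical neurons with nuclei and organelles,
paint a ground-truth delta field calibrated to the reported group values,
and render NanoSIMS stacks through a true affine transform with per-plane
stage drift and Poisson shot noise. The entire analysis chain is validated
by recovering the preset parameters end to end.

## Worked example

```r
library(silksims)
library(dplyr)

preset <- default_preset("snpc-control-48h")   # end of pulse, control side
cohort <- simulate_cohort(preset, n_cells = 10, seed = 1)

group_table(cohort$cells, whole_cell_delta, condition, timepoint_h)
#>   condition timepoint_h     n  mean    sd median   q25   q75
#> 1 control            48    10  273.  69.7   262.  218.  340.

nuc <- nuclear_analysis_set(cohort$cells)      # nucleolus-containing cells excluded
mean(nuc$nuc_minus_cyt)
#> nucleus - cytoplasm (permil): 25.5 +/- 3.7 SE, n = 6

cohort$organelles |>
  group_by(class) |>
  summarize(n = n(), mean_ratio = mean(ratio_to_cytoplasm),
            median_diff = median(diff_from_cytoplasm))
#>   class             n mean_ratio median_diff
#> 1 ER               64       1.24        59.8
#> 2 golgi            30       1.74       169.
#> 3 lysosome        120       1.66        60.3
#> 4 mitochondrion   120       1.32        73.3

fit <- fit_chase(c(48, 96), c(259, 156))       # control cohort means
glance(fit)
#>   model             rss n_points half_life_h
#> 1 one_phase_decay     0        2        65.6
```

The ten simulated neurons average 273 ± 70 ‰ whole-cell enrichment (the
preset targets 259 ‰ with a 48 ‰ between-cell SD, so a 10-cell mean wobbles
by ~15 ‰), the nucleus runs 25 ‰ above the cytoplasm, mitochondria sit at
1.32× and the Golgi at ~1.7× the cytoplasmic level, and the two-point chase
fit gives a whole-cell carbon half-life of ~66 h.

For measured data, the same chain runs from files:
`read_stack()` → `estimate_plane_shifts()` → `accumulate()` → `delta_map()`,
`fit_affine(read_control_points(...))`, `quantify_rois(...)` with ROIs from
`read_rois()` (JSON polygons) or a label-image TIFF — or in one step via
`run_pipeline()` with a YAML config (thin CLI wrapper in `inst/exec/silksims`).

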