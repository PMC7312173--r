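# slidedamage

Large-scale single-cell analysis of two-channel fluorescence whole-slide
scans, for radiobiology and plasma-medicine labs that treat cultured cells at
a localized spot and ask *which cells, in which cell-cycle phase, were
damaged, and where*.

The input is a pair of co-registered channel rasters: **DAPI** (nuclear DNA —
integrated per-nucleus intensity is proportional to DNA content) and
**γH2AX** (phosphorylated histone marking DNA double-strand breaks). From
DAPI alone, every cell on the slide gets a cell-cycle phase; from the ratio
of the two channels, a DNA-damage value. The output is per-nucleus tables and
spatial damage maps centered on the treatment location.

## The method

1. **Segmentation** — Gaussian blur (σ = 1 px) of the DAPI channel, an
   adaptive *log-weighted Otsu* threshold (Otsu's between-class variance on
   the histogram of log(1 + I), per window, blended bilinearly), hole
   filling, and watershed partitioning of overlapping nuclei seeded by
   distance-transform maxima.
2. **Intensity correction** — background surface subtraction, multiplicative
   fast-axis stripe removal, then foreground anchoring: per slow-axis
   position, the two DAPI intensity bands (G1 and G2; G2 cells carry twice
   the G1 DNA content) are located with a mixture fit, smoothed with lowess,
   and mapped affinely so the bands sit at I_DAPI = 1 and 2. The γH2AX
   foreground is flattened by subtracting a surface fitted to the 2nd–4th
   percentile of G1-cell intensities per ~1 mm² block — the undamaged
   subpopulation.
3. **Features** — per nucleus: shape (including 16 Fourier descriptors),
   intensity, 4 radial shell means, 13 Haralick GLCM statistics, and a
   16-element granularity spectrum.
4. **Classification** — a shallow neural network (hidden layers 30 and 10,
   softmax over 5 classes, early stopping) separates interphase from four
   mitotic morphologies; interphase cells are assigned G1/S/G2 by a
   constrained mixture in (area, I_DAPI) space: 7 Gaussians equally spaced on
   the segment joining the G1 and G2 peaks, an 8th on the G1 peak, plus a
   uniform background.
5. **Damage** — damage = clamp(scale · I_γH2AX / I_DAPI, 0, 150) with the
   scale calibrated so the treated cohort's 99.9th percentile maps to 150;
   flow-control median subtracted; the damage ratio DR is the fraction of
   cells with damage > 75. Maps bin cells over an 18-mm disk (default 0.25 mm
   bins) around the treatment center, masking empty or blurry regions.

A ground-truthed synthetic slide generator (`generate_slide()`) emulates
every artifact the pipeline must undo — G2 = 2×G1 DNA content, mitotic
morphologies, γH2AX foci with a radial (or ring-shaped) damage field,
illumination gradients, ×1.2 scan-line stripes, gain drift, local blur,
Poisson–Gaussian noise — so the whole pipeline is testable without any real
slides.

## Worked example

```r
library(slidedamage)

sim <- generate_slide(800, c(G1 = 0.55, S = 0.12, G2 = 0.33),
                      artifacts = artifact_spec(
                        damage = list(mode = "plain", amplitude = 0.8,
                                      decay_um = 250)),
                      confluence = 0.25, seed = 42)
sim$dapi
#> slide_image: DAPI channel, 1633 x 1633 px (0.82 x 0.82 mm), 0.5 um/px, fast axis = cols

lab <- segment_nuclei(sim$dapi, sigma = 1)
lab <- partition_overlaps(lab, sim$dapi)
max(lab)
#> [1] 800

cor <- correct_slide(sim$dapi, sim$gh2ax, lab, block_mm = 0.25)
rec <- cor$records
density_mode <- function(x) { d <- density(x); d$x[which.max(d$y)] }
density_mode(rec$i_dapi[rec$i_dapi < 1.5])   # corrected G1 band position
#> [1] 0.998

scale <- calibrate_damage_scale(rec$i_gh2ax, rec$i_dapi)
rec$damage <- damage_value(rec$i_gh2ax, rec$i_dapi, scale)
damage_ratio(rec$damage, 75)                  # slide-wide DR
#> [1] 0.154

ctr <- sim$truth$treatment_center_um
map <- build_damage_map(rec, c(ctr[2], ctr[1]), diameter_mm = 0.8,
                        bin_mm = 0.1, statistic = "DR")
map_radial_profile(map, n_rings = 4)
#>   r_um value n_bins
#> 1   50 0.278      4
#> 2  150 0.310      8
#> 3  250 0.160     20
#> 4  350 0.088     20
```

Reading the numbers: after correction the G1 DAPI band sits at ≈ 1.0 (so G2
sits at ≈ 2.0 and DNA content is directly readable per nucleus); 15% of cells
on this slide exceed the damage threshold of 75; the DR radial profile decays
away from the treatment center, mirroring the exponential damage field the
generator applied (the innermost rings hold only 4–8 bins, hence their
binomial wobble).

The same run as a config: `run_pipeline("run.yaml")`, or from a shell via the
CLI shim

```sh
Rscript inst/cli/slidedamage run --config run.yaml
# subcommands: simulate segment correct features train-classifier classify damage-map run
```

## Layout

```
R/            synthetic.R segmentation.R correction.R features.R
              classifier.R damage.R slide_io.R tiff.R pipeline.R cli.R
src/          Rcpp raster primitives (labeling, EDT, watershed, morphology)
tests/        testthat suite incl. test-acceptance.R (criteria 1-6)
scripts/      acceptance.R
vignettes/    slidedamage-methods.Rmd  (models, parameters, design notes)
```
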