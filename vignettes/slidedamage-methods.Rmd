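---
title: "slidedamage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slidedamage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A whole-slide fluorescence scan of a coverslip carries two co-registered
channels: DAPI, whose integrated per-nucleus intensity is proportional to DNA
content, and gamma-H2AX, a phosphorylated histone that marks DNA double-strand
breaks. From these two channels alone, `slidedamage` assigns every cell on the
slide a cell-cycle phase (G1/S/G2/M) and a DNA-damage value, and renders the
spatial distribution of damage around a treatment location (for example the
footprint of an atmospheric-pressure plasma jet) as binned damage and
damage-ratio maps.

The pipeline has four stages: (1) nuclei segmentation with
background/foreground intensity correction, (2) per-nucleus feature
extraction, (3) two-step cell-cycle classification, (4) damage quantification
and mapping. Each stage is exposed as ordinary R functions and orchestrated by
`run_pipeline()` from one YAML config.

# Segmentation

The DAPI channel is smoothed with a Gaussian blur (`sigma = 1` px) and
thresholded with a *log-weighted Otsu* threshold: Otsu's between-class-variance
criterion evaluated on the 256-bin histogram of `log(1 + I)`, with the
maximizing bin boundary mapped back to the intensity scale. The log transform
keeps the heavy right tail of fluorescence foregrounds from dominating the
criterion. "Log-weighted" admits a second reading (log-weighted class
probabilities on a linear histogram); we implement Otsu on `log(1+I)` and note
the alternative here.

The threshold is adaptive: one threshold per window (default 1024 px, at
least ten nucleus diameters) blended bilinearly across window centres. A
window only contributes a threshold when its foreground/background contrast
exceeds `contrast_sd` (default 6) background standard deviations; windows of
pure background therefore contribute nothing, and a blank slide yields an
empty label map rather than thresholded noise.

Objects whose area exceeds `area_factor` (1.6) times the modal single-nucleus
area, or whose solidity falls below 0.9, are treated as clumps of overlapping
nuclei. A pluggable centre detector proposes one seed per nucleus — the
default is regional maxima of the h-maxima-transformed, smoothed distance
transform; a user-supplied SALR-style detector can be plugged in via
`center_fun` — and clump pixels are partitioned by a seeded watershed.

**Watershed relief.** The partition assigns each clump pixel to its nearest
centre, which is exactly a watershed on the *negated smoothed distance
transform*; this is the default (`relief_on = "distance"`). A watershed on
inverted DAPI intensity is also available, but on synthetic slides (where
overlapping nuclei render additively, making the junction *brighter* than
either nucleus) the intensity relief floods lopsidedly from whichever seed
first touches the bright bridge. Shape-based declumping is also what
CellProfiler-style pipelines default to.

**Isolated-nucleus area.** On a sparse field the Otsu threshold settles near
3% of the peak intensity, so a segmented isolated nucleus includes the entire
soft intensity skirt that the `sigma = 1` blur spreads ~1.5–2 px beyond the
half-maximum contour, inflating its area by roughly `(1 + 2/r)^2` (25–35% for
r ≈ 13 px). This is a property of any threshold-based segmentation of
soft-edged objects, not an implementation defect; area fidelity on dense
fields is what the 200-nucleus Jaccard test checks.

# Intensity correction

Corrections are applied in a fixed order, and the DAPI foreground is always
corrected before the gamma-H2AX foreground:

1. **Background surface** (per channel): median of background pixels (the
   complement of the dilated segmentation foreground) per 256-px block,
   lightly smoothed and interpolated bilinearly, then subtracted. The
   smoothing of the coarse grid is skipped below 8x8 blocks, where the
   reflecting boundary would visibly flatten slide-edge gradients.
2. **Stripe removal** (per channel): scanner calibration errors multiply
   whole scan lines. Per line, the robust residual background level implies a
   factor `(residual + surface) / surface`; lines deviating from 1 by more
   than `max(0.02, 6 * mad)` are divided by their factor (the un-flattened
   line is divided and the surface re-subtracted, so the correction is exactly
   multiplicative on raw counts). The open question of additive vs
   multiplicative stripe correction is resolved as multiplicative — that is
   the model under which a known synthetic x1.2 stripe is recovered exactly.
   A line's factor is only identifiable when it has a measurable background
   level (default floor: 5 counts); on background-free input the correction
   is the identity.
3. **DAPI band anchoring**: per slow-axis window (equal-count windows,
   default up to 24), the two DAPI bands are located and the per-nucleus
   integrated intensity is mapped affinely per position so that the fitted G1
   curve lands at 1 and the G2 curve at 2 (cells in G2 carry twice the G1
   DNA content). Band centres are estimated by a two-Gaussian-plus-uniform EM
   in the *intensity* domain (the uniform component absorbs S-phase cells and
   debris that would bias the centres inward), then refined to the local
   kernel-density mode within 2.5 sigma — the band's printed "position" is
   its ridge, not the mixture mean. Centres are smoothed against slow-axis
   position with `lowess` (span 0.3 of the slow-axis extent).
4. **gamma-H2AX baseline flattening**: G1 cells (corrected DAPI in
   [0.7, 1.3]) are binned into ~1 mm^2 blocks; per block the baseline is the
   mean of the gamma-H2AX intensities between that block's 2nd and 4th G1
   percentiles — the undamaged subpopulation, valid as long as some cells in
   each block escaped treatment. The baseline is guarded never to exceed the
   block's G1 median (so real, widespread damage is never flattened away),
   interpolated into a smooth surface, subtracted from every nucleus, and
   negative results are clipped to 0 (intensities are physical counts).

**Why intensity-domain EM and fixed iteration counts.** Every step of the
band detector — density-mode seeding, EM updates with a data-range uniform
component, lowess, the affine anchor — is exactly affine-equivariant, so
re-running the correction on corrected records reapplies (approximately) the
identity. A log-domain mixture cannot be equivariant under the affine maps
the correction itself applies. Exact idempotence to 1e-6 is still not
attainable: the lowess smoothing leaves a position-dependent residual (a few
percent under a 0.3-amplitude sinusoidal drift with span 0.3), and a second
pass mops that residual up. The idempotence test therefore asserts the
statistical bound, not 1e-6.

**What the correction does not do.** Pixel rasters are only corrected for
background and stripes; band anchoring and baseline flattening adjust the
*per-nucleus statistics*, which is what every downstream consumer uses. The
spec left open whether pixel values should also be rescaled; per-record
correction is sufficient and keeps the rasters physical.

# Features

Per nucleus, from the DAPI channel: area, perimeter (8-connected boundary
chain length), eccentricity and orientation (central second moments with the
1/12 pixel-variance correction), solidity (convex hull); 16 Fourier
descriptors (boundary resampled to 256 points by arclength, DFT, DC dropped,
magnitudes normalized by the dominant first harmonic — translation, rotation,
scale and start-point invariant); intensity statistics (integrated, mean, sd,
5/25/50/75/95 percent quantiles); 4 radial shell means (equal-width bins of
normalized distance-to-boundary; shell 1 is the outermost); 13 Haralick
statistics (GLCM at distance 1, four offsets, symmetrized, normalized,
averaged; per-region min-max quantization to 64 levels; sum-variance is
centred on the sum-average, the common fix to Haralick's original f7); and a
16-element granularity spectrum (CellProfiler-style iterative erosion with a
radius-1 disk plus reconstruction under the original; element g is the
percentage of starting mean intensity removed at scale g). From the
gamma-H2AX channel: intensity statistics only — integrated gamma-H2AX is
proportional to the number of double-strand breaks.

Degenerate regions have defined limits: a constant region has contrast 0,
angular second moment 1, and correlation 0 by convention. The Haralick
implementation was validated once against scikit-image's
`graycomatrix`/`graycoprops` on a fixed patch; the patch and reference
numbers are frozen in the test suite.

# Cell-cycle classification

**Step 1 — five visual classes.** A shallow neural network (two tanh hidden
layers of sizes 30 and 10, softmax output) separates interphase (class 1)
from prometaphase (2), metaphase (3), early anaphase (4) and late
anaphase/telophase/early G1 (5). Training uses a stratified 0.7/0.15/0.15
train/validation/test split, feature standardization computed on the training
split only, full-batch Adam (learning rate 0.01), and early stopping when the
validation loss fails to improve for 6 consecutive epochs (cap 1000). tanh
matches the classic MATLAB pattern-recognition default the original
formulation used; the training seed fixes both the split and the
initialization, so retraining is bit-reproducible.

**Step 2 — interphase phases.** Interphase cells are modelled in
(area [um^2], corrected I_DAPI) space by a mixture of eight Gaussians plus a
uniform background: seven means constrained equally spaced on the segment
joining the G1 and G2 peaks (endpoints included — the spec left open whether
the seven include the endpoints; endpoints-in is implemented), an eighth mean
fixed on the G1 peak, full 2x2 covariances, and a uniform density of 1/area
of the (5%-padded) data box. The constrained M-step solves the 4-unknown
weighted normal equations for the two endpoints given the current
covariances, then updates covariances given the new means — each substep
maximizes the EM Q-function, so the log-likelihood is non-decreasing every
iteration (asserted in the tests). Component-to-phase mapping: components 1
and 8 (G1 peak) map to G1, components 2–6 to S, component 7 (G2 peak) to G2;
background-dominated records are left unclassified. Components 1 and 8 share
a mean, so only their *summed* weight is identifiable — parameter-recovery
checks compare that sum and the six remaining weights individually.

# Damage quantification

Per nucleus, damage is the ratio of corrected integrated intensities
I_gH2AX / I_DAPI — the fraction of damaged DNA — mapped onto the printed
0–150 scale. The source material never defines that mapping, so the scale is
calibrated per run: the treated cohort's 99.9th ratio percentile maps to 150
(the damage-ratio threshold of 75 then reads as "half of maximal damage"),
and the scale is persisted so that a fixed user-supplied value can be used
for cross-slide comparability. The flow-control cohort's *median* damage is
subtracted (floored at 0) before mapping. The damage ratio (DR) of a cohort
is the fraction of cells whose damage strictly exceeds the threshold
(default 75; ties count as undamaged — the spec left ">" vs ">=" open).

Maps cover a disk (default 18 mm diameter, the coverslip layout) centred on
the treatment location, in square bins (default 0.25 mm, ~72 bins across the
disk); each QC-passing cell contributes to the bin containing its centroid;
per-bin statistics are the mean damage (median available via flag) or the DR,
optionally filtered by phase. Bins outside the disk, without cells, or inside
QC-masked tiles (no cells, or blurry by the variance-of-Laplacian focus
metric normalized by squared tile mean) are rendered missing/white.

# The synthetic-data generator

The generator is first-class, tested code: without any deposited slides, it
is the package's ground truth. It renders soft-edged, radius-modulated
ellipses with lognormal interior speckle (blurred to grain sizes above one
pixel so texture and granularity features are non-degenerate), at defaults
chosen to be realistic for oral epithelial cells scanned at 20x
(0.5 um/px): G1 area 170 um^2 (sd 15), G2 280 um^2, DNA content G1 ~ N(1,
0.05), G2 ~ N(2, 0.10), S uniform on (1, 2); mitotic morphologies follow the
five visual classes — prometaphase and metaphase as condensed bright figures
(~250 um^2, measured DNA ~2.3, metaphase elongated ~3:1), early anaphase as
a dumbbell of touching half-lobes, late anaphase as adjacent pairs of small
condensed halves (~120 um^2, DNA ~1.1). Placement is dart-throwing with a
spatial hash and a minimum centre separation of `sep_frac` times the summed
effective radii (default 0.95, allowing moderate overlap; 1000 retries per
nucleus before an explicit error naming the achieved confluence).

Pre-artifact, each nucleus's DAPI integrates exactly to
`dna_content * dapi_gain` and its gamma-H2AX to
`gh2ax_gain * dna_content * (0.02 + true_damage_fraction)` (2% undamaged
baseline; damage rendered as ~30 foci per unit fraction plus a 20% diffuse
component). Artifacts are applied in a fixed order: multiplicative DAPI
foreground gain drift along the slow axis (default 1 + 0.3 sin over the
slide), additive smooth background surface (fixed low-order polynomial
shapes), x1.2 multiplicative stripes on every 64th scan line (both channels
— a calibration error scales whatever the line reads), optional rectangular
blur regions, and Gaussian noise with variance `0.5 * I + 3^2`
(Poisson-Gaussian in the Gaussian approximation). The per-cell damage field
is either a monotone exponential decay from the treatment centre or a
Gaussian ring (default radius 1 mm — the plasma-jet orifice radius — width
0.3 mm); cells are hit with probability equal to the field and damaged
magnitudes drawn uniformly from [0.25, 1] (a continuous mode without
zero-inflation exists for correlation oracles).

What the generator does *not* emulate: chromatin substructure beyond
speckle, nucleoli, real anaphase bridge geometry, cytoplasmic
autofluorescence, chromatic shifts between channels, or scanner tile seams.
A green test therefore establishes algorithmic correctness on an idealized
but artifact-complete world, not instrument-level realism.

# Numerical and scaling choices

* Coordinates are 0-based (row, col) in documentation, 1-based in R code;
  physical x maps to columns, y to rows; `fast_axis = "cols"` means each row
  is one scan line and the slow axis is the row index.
* TIFF I/O is a minimal built-in baseline reader/writer (uncompressed
  grayscale 8/16-bit unsigned, 32-bit signed labels, 32-bit float), written
  because no TIFF-capable R package is available in the deployment
  environment; 8-bit values are promoted without rescaling, truncated files
  error rather than returning partial rasters.
* EM stopping: band-anchoring EM runs a fixed 150 iterations (equivariance,
  see above); the interphase mixture stops at relative log-likelihood
  improvement < 1e-8 or 300 iterations; covariances carry a ridge of
  (2% of the G1 spread)^2.
* The ring-experiment acceptance run uses 1 um/px on a ~4.5 mm field with a
  4 mm map (18 mm at 0.5 um/px is a 1.3e9-pixel raster); ring radius
  (1 mm), bin size (0.25 mm) and the acceptance band (1.0 +- 0.25 mm) are
  unchanged. Other suite fixtures are similarly scaled down in cell count,
  never in effect size, noise level or threshold.
* One run seed fans out deterministically to all stochastic stages
  (generator, split, initialization); derived seeds stay below 2^31.

# Known limitations

* Stage-1 network inputs are the full feature set; the original Appendix-A
  feature list is not reproduced in the available text, so counts may differ.
* The SALR centre detector itself is out of scope; only its interface exists.
* Intensity-relief watershed is available but not default (see above).
* Damage-scale calibration by a cohort percentile makes the 0–150 scale
  run-relative unless a fixed scale is supplied.
* No pyramid/multi-resolution TIFF, no proprietary scanner containers, no
  GPU path; large slides are handled by tiling, not by out-of-core I/O.
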