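---
title: "Staging cell differentiation from vibrational spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging cell differentiation from vibrational spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibrostage)
```

# Overview

`vibrostage` stages stem-cell differentiation — the reference system is
adipogenesis of adipose-derived mesenchymal stem cells (AD-MSCs) followed at
6 h and days 2, 7 and 14, with negative controls — from two kinds of
vibrational data: FTIR hyperspectral images (focal-plane-array cubes of
absorbance spectra) and single-spot Raman spectra. The pipeline has a fixed
backbone: preprocess each modality with its own chain, reduce images to
ROI-mean spectra, compute band-integration metrics with group statistics,
and classify stages with standard chemometrics (Ward clustering, PCA, PLS
regression). A synthetic-data generator plays the role of the instrument:
it encodes, as per-band amplitude multipliers, the biochemical trajectory
the metrics are designed to detect, which makes every stage of the pipeline
testable against known ground truth.

All computation uses one axis convention: wavenumbers in cm⁻¹, strictly
increasing. Spectral windows are closed intervals `[lo, hi]`; a grid point
belongs to a window iff `lo <= wn <= hi`. Pixel indexing is 0-based and
row-major, ROIs are half-open rectangles. Files stored with descending axes
are reordered on read; plotting may flip, computation never does.

# Preprocessing chains

## Raman

Per spectrum: cosmic-ray removal → degree-3 iterative polynomial baseline →
truncation to 700–3050 cm⁻¹ → rubber-band baseline (10 passes) →
Savitzky–Golay smoothing (9 points, 3rd order) → vector normalization.
Then, across the group: outlier rejection and averaging.

*Cosmic-ray removal* flags channels whose residual against a 3-point running
median exceeds 8 robust-noise units and replaces them by linear
interpolation from unflagged neighbours, iterating until no new flags
appear (so two adjacent spike channels are also caught). The robust noise
scale is the MAD of first differences divided by √2 — the running-median
residuals themselves are zero-inflated (a channel is its own median whenever
it lies between its neighbours) and would bias a direct MAD low. The window
size (3) and threshold (8, the "dynamic factor") are the chain's defaults
and configurable. Limitation, by construction: on near-noiseless spectra the
noise scale collapses to the per-channel signal curvature and very sharp
lines (e.g. the 1007 cm⁻¹ phenylalanine band) can be mistaken for spikes;
the chain therefore exposes `despike = FALSE` for spike-free input such as
noiseless references.

*Polynomial baseline*: iterative least-squares fit of a cubic in which the
working spectrum is clipped to the fit after each pass (points above the
fit are effectively down-weighted), until the clip changes nothing within
1e-8 of the intensity scale (at most 50 passes). This is the standard
fluorescence-background estimator; the converged polynomial is subtracted
from the *original* intensities.

*Rubber-band baseline*: the lower convex envelope (monotone-chain hull) is
interpolated across the axis and subtracted. After the first pass the
envelope of the result is the zero line, so the operation is idempotent; the
output is ≥ −1e-9 everywhere. The pass count (10) follows the chain's
convention; extra passes are no-ops on already-corrected input.

*Vector normalization* subtracts the mean over the normalization region and
scales the whole spectrum to unit Euclidean norm over that region. This
fixed formula is idempotent and invariant to affine transforms of the
input, both of which are tested.

*Outlier rejection* drops spectra whose Pearson correlation with the
point-wise median spectrum falls below 0.95. The median reference and the
0.95 threshold are design choices (the rule needs a fixed, testable form);
the threshold is a config knob and the removed indices are reported.

## FTIR imaging

Per cube: PCA denoising (reconstruction from the leading 13 principal
components of the mean-centred pixel × channel matrix) → crop to
920–3700 cm⁻¹ → Savitzky–Golay smoothing (13 points, 2nd order) → selection
of four ROIs → ROI averaging. Per ROI mean: CO₂-band flattening →
Savitzky–Golay second derivative (13 points, 2nd order) → vector
normalization. Ten cubes per group × 4 ROIs per cube yield 40 mean spectra
per experimental group; the output count is `n_cubes × n_rois` always.

*ROI selection* tiles the image into non-overlapping candidate rectangles —
by default half the cube in each dimension, so a 2 × 2 mosaic of FPA tiles
(1400 μm × 1400 μm at 5.5 μm/pixel) yields four 700 μm × 700 μm candidates
— ranks them by mean pixel signal-to-noise in the amide I region, and keeps
the top `n_rois`. S/N is (peak above the local linear chord in
1620–1680 cm⁻¹) / (sd of the linearly detrended 1800–1900 cm⁻¹ window);
the noise window is a design choice (a signal-free region in cells) and
configurable. Ranking by S/N is the operational reading of "select
high-S/N regions"; uniform random tiling is available via `random = TRUE`.
Ties are broken in a seed-determined order.

*CO₂ flattening* replaces 2200–2400 cm⁻¹ by the straight line joining the
boundary channel values — boundary values are preserved exactly, channels
outside the range bit-exactly.

*Savitzky–Golay* filtering (delegated to `signal::sgolayfilt`, with the
axis-uniformity contract enforced and derivatives scaled by the grid step)
reproduces polynomials up to the filter order exactly in the interior and
handles edges by the off-centre fits of the first/last full window. The
smoothing orders — 9-pt/3rd-order for Raman, 13-pt/2nd-order for IR — are
the chain defaults. Note that a 13-point second-derivative window has an
inherent smoothing bias on bands whose width approaches the window span;
the analytic-Gaussian test uses a 0.5 cm⁻¹ grid where that bias is < 1%.

For PCA/PLSR inputs the terminal IR form is second derivative → offset →
vector normalization; since vector normalization subtracts a mean, the
separate offset step is absorbed into it.

# Band metrics and statistics

Band areas are trapezoids over the closed window — no peak fitting, which
would add model assumptions the pipeline does not need. Three baselines:
raw (`ZERO_BASELINE`), chord-subtracted (`LOCAL_LINEAR`, so a straight-line
segment integrates to zero), and absolute-value (`ABS_ZERO`). IR metrics are
read from vector-normalized second-derivative spectra with absolute-value
integration (second-derivative bands are negative lobes); Raman metrics from
baseline-corrected normalized spectra with chord subtraction. Ratio metrics
whose denominator falls below 1e-12 are flagged undefined rather than
propagating NaN.

The nine-metric panel (see `?metric_panel` for the windows): IR acyl-chain
shortening, triacylglycerols, fatty-acid acylation (1421 cm⁻¹), amide II/I,
DNA; Raman lipid unsaturation (lipidic spectra), phospholipids,
phenylalanine cross-linking, cytochromes (proteinaceous spectra). Group
tests are one-way ANOVA plus Tukey HSD — computed with `stats::aov` /
`stats::TukeyHSD`, which applies the Tukey–Kramer correction under unequal
group sizes — starred at 0.05/0.01/0.001.

# Chemometrics

*HCA*: Euclidean distance, Ward minimum-variance linkage (`ward.D2`, i.e.
the Lance–Williams update on squared distances with heights reported on the
distance scale). Heights are monotone non-decreasing; the test suite checks
the full merge sequence against a brute-force Lance–Williams implementation
on small inputs. The clustering matrix takes the bio-regions 3050–2800 and
1750–920 cm⁻¹: a 1080 cm⁻¹ total span, 1082 closed-interval channels at
1 cm⁻¹ spacing (closed intervals include both endpoints, hence 251 + 831).

*PCA*: SVD of the column-centred matrix, 7 components by default. Loading
signs are fixed deterministically (largest-magnitude element positive) so
score plots reproduce across platforms. Requests beyond the matrix rank are
truncated with a warning. Cross-validated component selection is out of
scope; the component count is fixed.

*PLSR*: NIPALS PLS1 on centred predictors and a 0/1 dummy response —
classification via regression, thresholded at 0.5, is what lets one report
both regression statistics (RMSE, R²) and a true positive rate for the same
model. "Full cross-validation" is read as leave-one-out: it is
deterministic, which matters for reproducible validation statistics
(segment-based schemes would differ in the third decimal and add an RNG
dependency). At full rank NIPALS predictions coincide with ordinary least
squares (tested to 1e-6); under permuted labels the cross-validated R² stays
≤ 0.2 (tested over 20 seeded permutations — note this permutation null is
only stable from a few dozen observations upward; leave-one-out R² at very
small n is erratic). The 80/20 calibration/test split is stratified by class
and seed-controlled, so neither side can lose a class at fixture scale.

*Profile split*: Raman spectra are labelled lipidic vs proteinaceous by the
chord-corrected area ratio A(2840–2870)/A(2920–2940) — lipid CH₂ vs protein
CH₃ stretch — with threshold 1. This band-ratio rule is a documented,
operational surrogate for a PCA-guided assignment; the criterion value is
stored per spectrum so any other threshold can be applied post hoc.

# The synthetic generator

`generate_spectrum` builds intensity = Σ bands (Gaussian by default,
Lorentzian available) × stage multiplier + cubic baseline + additive
Gaussian noise, plus Poisson-count cosmic-ray spikes (Raman) or the
atmospheric CO₂ band at 2350 cm⁻¹ (IR). Axes default to the processing
windows at 1 cm⁻¹ spacing (IR 920–3700, Raman 700–3050). Every draw is a
pure function of (seed, stage, index) via derived substream seeds, so
corpora are reproducible element-wise. `generate_cube` emulates an FPA
image: elliptical cell patches covering a configurable fraction of the grid
carry the stage spectrum, background pixels carry baseline + noise only, so
amide-I S/N separates cell from background pixels; the mask is attached as
ground truth.

Band positions follow the standard assignments for fixed cells; widths and
amplitudes are generator choices: 10–30 cm⁻¹ for broad envelopes, 8 cm⁻¹
Lorentzians for the sharp ring-breathing lines. The CH-stretch bands are
kept at 14 cm⁻¹ so that the fixed 20 cm⁻¹ CH₃ criterion window of the
profile split captures the 2930 band cleanly — with much broader bands the
chord correction strips most of that area and the fixed threshold of 1
cannot separate the profiles.

Stage profiles encode the differentiation trajectory as multipliers around
1 with 30–60% effect sizes: triacylglycerols dip at day 2 and rise past
baseline later; the 1421 cm⁻¹ acyl-conformation band vanishes at day 2
(multiplier 0) and overshoots at days 7/14; DNA and the nucleic-acid bands
peak at day 2; the amide II/I balance shifts at day 2 (β-sheet rise, amide
II and tyrosine drop); Raman lipid unsaturation peaks at day 7; cytochromes
rise from day 7; the phenylalanine cross-link band falls at days 7/14;
negative controls stay flat apart from a gradual CH₃/CH₂ drift and a slow
membrane decline. Where the source observations conflict — the Phe
1038/1007 ratio is described both as rising by day 14 and as gradually
decreasing — the profiles follow the protein-metrics reading (decrease).
Effect sizes are sized so that 40 spectra per group reach Tukey p < 0.05
under the default noise (additive sd 0.02 against band amplitudes of order
0.3–1.5); the end-to-end trend-recovery test asserts exactly this.

What the generator does **not** emulate: detector response, interferometry
and resonance effects, Mie scattering, water-vapour lines, instrument drift,
cell-to-cell biological heterogeneity beyond i.i.d. noise, and any
quantitative match to measured band magnitudes. Passing tests therefore
demonstrate that the pipeline recovers the encoded trends under controlled
conditions — not that real instruments will show these effect sizes.

# Numerical choices and degenerate inputs

- Round-trips: spectrum tables are written at 17 significant digits; cubes
  as float64 blocks by default (float32 supported via the header), so
  write∘read is the identity to 1e-9.
- `estimate_snr` returns `Inf` on noiseless input (detrended noise sd below
  1e-12 of the window scale) rather than dividing by a rounding residue.
- Vector normalization refuses constant regions; rubber-band needs ≥ 3
  points; Savitzky–Golay refuses non-uniform axes (resample first) and
  derivative orders above the polynomial order.
- PCA denoising refuses single-pixel cubes; `n_pcs` is capped by
  min(pixels, channels).
- Tie-breaks that could depend on floating-point order (ROI ranking, PCA
  and PLS loading signs) are fixed by seed or by the largest-element
  convention.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in well under a minute of compute: 40 spectra per
group for trend recovery (the scale at which effect sizes are calibrated),
50 per class × 10 seeds for the classification benchmark, reduced cube
grids (16×16 to 64×64 pixels, coarser axes) wherever a check is
geometry-invariant. The FPA pixel-count checks use full 128×128 and
256×256 grids with a short axis, since the counts do not depend on the
number of channels.

# Known limitations

- The despiking/sharp-line ambiguity described above.
- Absolute metric scales depend on the integration variant (endpoints,
  baseline handling); orderings across groups are the robust quantity, and
  only orderings are asserted.
- The PLS classifier is two-class (dummy regression); no multiclass PLS-DA,
  no variable selection.
- No vendor file readers (OPUS, WITec, Agilent, ENVI); interchange is via
  delimited tables and the JSON+block cube format.
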