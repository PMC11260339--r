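# vibrostage

Vibrational-spectroscopy metrics and chemometrics for staging cell
differentiation.

## The problem

Adipogenesis — the differentiation of adipose-derived mesenchymal stem cells
(AD-MSCs) into fat-storing adipocytes — is conventionally staged with
label-based assays (Oil Red O staining of lipid droplets, immunofluorescence).
FTIR and Raman microscopy see the same biochemistry label-free: an infrared
focal-plane-array (FPA) detector images a cell monolayer as a 128 × 128 grid
of absorbance spectra (16,384 spectra per tile), and single-spot Raman spectra
resolve the lipid, protein, cytochrome and nucleic-acid composition of
individual cells. `vibrostage` implements the full analysis pipeline that
turns such hyperspectral data into differentiation-stage calls, for
spectroscopists and cell biologists who want a tested, scriptable alternative
to point-and-click vendor software — plus a synthetic-data generator that
emulates the stage-dependent band profiles, so the whole pipeline is
exercisable and testable without instrument data.

## What it computes

**Preprocessing.** Raman chain: cosmic-ray removal (running-median residuals,
window 3, dynamic factor 8) → degree-3 iterative polynomial baseline →
truncation to 700–3050 cm⁻¹ → rubber-band (convex hull) baseline, 10
iterations → Savitzky–Golay smoothing (9 pts, 3rd order) → vector
normalization → correlation-based outlier rejection → group mean. IR imaging
chain: PCA denoising (13 components) → crop to 920–3700 cm⁻¹ → 13-pt
smoothing → signal-to-noise-ranked selection of four regions of interest per
image (amide I S/N, 1620–1680 cm⁻¹) → ROI averaging → CO₂-band flattening
(2200–2400 cm⁻¹) → Savitzky–Golay second derivative (13 pts, 2nd order) →
vector normalization. Ten images per group × 4 ROIs give the working scale of
40 mean spectra per experimental group.

**Band metrics.** Integral intensities A(lo–hi) (trapezoid, with
local-linear or absolute-value baseline handling) feed nine staging metrics,
e.g. acyl-chain shortening A(2944–2989)/A(2837–2868), triacylglycerols
A(1727–1761), amide II/amide I A(1482–1595)/A(1609–1708), DNA A(949–990),
Raman lipid unsaturation A(1250–1280)/A(1285–1320) and the cytochrome sum
A(1575–1595)+A(1120–1140)+A(740–760). Group differences are tested by
one-way ANOVA with Tukey HSD at the 0.05/0.01/0.001 levels. Per-pixel band
integrals give chemical maps of lipid/protein/nucleic-acid distribution.

**Chemometrics.** Ward/Euclidean hierarchical clustering of
second-derivative spectra in the bio-regions (3050–2800, 1750–920 cm⁻¹;
1082 channels over a 1080 cm⁻¹ span at 1 cm⁻¹ spacing); mean-centered PCA
(SVD, 7 components); and NIPALS PLS1 regression on a 0/1 dummy response
(10 factors, leave-one-out cross-validation) with held-out classification at
a 0.5 threshold, scored as a true positive rate (TPR). Raman spectra are
split into lipidic vs proteinaceous profiles by the CH₂/CH₃ stretch area
ratio before profile-specific metrics.

## Worked example

Generate two synthetic experimental groups (6 h vs day 2 of differentiation,
40 spectra each), run the IR chain, the metric panel and the statistics:

```r
library(vibrostage)

cfg   <- generator_config(seed = 1, n_per_group = 40, modality = "IR")
h6    <- preprocess_ir_spectra(generate_group("H6", cfg))
d2    <- preprocess_ir_spectra(generate_group("D2", cfg))
cells <- bind_sets(h6, d2)
cells
#> <vib_spectrum_set> IR/SECOND_DERIVATIVE, 80 spectra x 2781 channels, groups: H6, D2

tab <- compute_metrics(cells)
aggregate(value ~ group + metric, tab, mean)
#>    group              metric      value
#> 1     D2         amide_ratio 0.67662943
#> 2     H6         amide_ratio 1.04944379
#> 3     D2                 dna 1.95027055
#> 4     H6                 dna 1.20644922
#> 5     D2        fa_acylation 0.09954861
#> 6     H6        fa_acylation 0.95665248
#> 7     D2 fa_chain_shortening 0.94634389
#> 8     H6 fa_chain_shortening 1.11072779
#> 9     D2                 tag 0.80481619
#> 10    H6                 tag 1.83388914

anova_tukey(tab, "tag")$comparisons
#>    pair     diff p_adj stars
#> 1 H6-D2 1.029073     0   ***
```

The day-2 group shows the expected biochemical signature of triggered
adipogenesis: the triacylglycerol band collapses (0.80 vs 1.83, p < 0.001),
the 1421 cm⁻¹ acyl-conformation metric all but vanishes (0.10 vs 0.96), DNA
rises (replication burst), and the amide II/I ratio drops
(secondary-structure reorganization).

Classification of held-out spectra with the PLS-regression classifier:

```r
res <- classification_experiment(seeds = 1:3, n_per_class = 40)
res[, c("seed", "tpr", "rmsec", "r2c")]
#>   seed tpr        rmsec r2c
#> 1    1 100 5.340399e-06   1
#> 2    2 100 1.224079e-05   1
#> 3    3 100 1.209292e-05   1
```

A small ready-made table of synthetic mean spectra ships with the package:
`read_spectrum_table(system.file("extdata", "synthetic_ir_two_stages.csv",
package = "vibrostage"), modality = "IR")`.

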