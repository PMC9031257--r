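# skinmsi

`skinmsi` is an R package for processing centroided MALDI imaging mass
spectrometry (MSI) data with the goal of discovering lipid markers of skin
micro-anatomical zones — the peripheral and central (necrotic) subzones of
sebaceous glands, and the concentric layers of hair follicles (outer root
sheath, inner root sheath, medulla, keratinized cortex). It is aimed at
imaging-MS and lipidomics analysts who want a scripted, reproducible
alternative to point-and-click MSI suites for this class of study.

## What it does

The package implements the complete analysis chain:

1. **imzML I/O** — read and write imzML 1.1.0 *processed*-mode file pairs
   (`.imzML` XML index + `.ibd` binary), with value-exact round trips.
2. **Peak binning** — pool all per-pixel centroid peaks, sort by m/z, and
   partition by greedy single linkage: a new feature bin opens wherever the
   gap to the previous peak exceeds the tolerance (default 2.5 ppm).
   Representative m/z is the intensity-weighted mean of the bin.
3. **Deisotoping** — remove a peak iff a retained lighter peak sits at
   m/z − k·1.0033548 (k ≤ 3) within tolerance and is at least as intense
   (singly charged species assumed).
4. **Segmentation** — bisecting k-means: repeatedly 2-means-split the
   cluster with the largest within-cluster SSE until k clusters exist.
   Spatial blob masks become regions of interest (ROIs).
5. **Co-localization** — score every feature's ion image against each ROI
   mask by the Pearson correlation
   r = cov(mask, image) / (σ_mask · σ_image) over all pixels; features are
   kept at r ≥ `min_r`, assigned exclusively to their best ROI, and ranked.
6. **Annotation** — adduct-aware accurate-mass matching: for each marker
   m/z, all (lipid record, adduct) pairs with
   |obs − theo| / theo · 10⁶ ≤ 2.5 ppm are reported, sorted by |ppm error|.
   Adducts: [M+H]⁺, [M+Na]⁺, [M+K]⁺, [M+NH4]⁺.
7. **LC–MS cross-validation** — adduct-switch-aware neutral-mass matching
   between platforms (e.g. a potassiated MALDI ion vs the ammoniated LC–MS
   ion of the same diglyceride), diagnostic-fragment counting (acyl RCOOH
   neutral losses; phosphocholine head group at 184.0733), and evidence
   tiers: **identified** (cross-matched + fragments) vs **annotated**
   (cross-matched, insufficient fragments).
8. **Synthetic phantom** — a ground-truthed 10 µm-pixel skin-section
   phantom (epidermis band, two-zone sebaceous gland, four-layer follicle)
   with planted markers, log-normal intensities, ppm jitter, isotope
   partners, background peaks and pixel dropout, plus companion synthetic
   LC–MS tables, so the whole pipeline can be validated self-contained.

## Worked example

```r
library(skinmsi)

## accurate-mass check of the sebaceous-gland central-zone diglyceride
theo <- adduct_mz(monoisotopic_mass(lipid_formula("DG", 36, 1)), "[M+K]+")
#> theoretical [M+K]+ m/z: 661.51678
ppm_error(661.5175, theo)
#> ppm error vs measured 661.5175: +1.08   (within the 2.5 ppm tolerance)

## end-to-end phantom run
cfg <- phantom_config(width = 60, height = 60, background_n = 60, seed = 1)
res <- run_pipeline(pipeline_config(phantom = cfg, seed = 2, out_dir = "run1"))
res$metrics
#> ARI = 0.987, precision = 1.00, recall = 1.00

res$tiers[res$tiers$tier != "unmatched", ]
#>     roi_name feature_mz lipid_name adduct  ppm_error       tier
#> 4        irs    840.588   PC(37:1) [M+K]+  0.0361283  annotated
#> 7 sg_central    661.517   DG(36:1) [M+K]+ -0.0392263 identified
```

The adjusted Rand index (ARI) of 0.987 says the unsupervised segmentation
recovered the phantom's anatomical zones almost perfectly; precision and
recall of 1.0 say the co-localization screen reported exactly the planted
markers, each in its true zone. The diglyceride DG(36:1), planted in the SG
central zone as its potassiated ion, is cross-matched to its ammoniated
LC–MS counterpart with diagnostic acyl losses and reaches tier
*identified*; PC(37:1) cross-matches without fragments and stays
*annotated*. Opaque markers (no lipid record) remain *unmatched* — present
and correctly localized, but without molecular identity.

A thin command-line front end with per-stage subcommands is installed at
`inst/scripts/skinmsi`:

```sh
Rscript inst/scripts/skinmsi all --phantom --seed 5 --out run_cli
```

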