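---
title: "Discovering skin lipid markers from MALDI imaging MS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering skin lipid markers from MALDI imaging MS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinmsi)
```

## The problem

High-resolution MALDI imaging mass spectrometry acquires one centroided
mass spectrum per raster pixel of a tissue section. In skin, the
interesting anatomy is small and concentric: a sebaceous gland has a
peripheral ring of immature sebocytes and a central necrotic core where
ruptured cells release sebum; a hair follicle has outer root sheath, inner
root sheath, medulla and keratinized cortex layers a few pixels across at
10 µm pitch. The analysis task is to find, without supervision, the m/z
features whose spatial distribution delineates these zones, and then to
attach molecular identities to them with an honest statement of the
evidence level.

`skinmsi` implements that chain: ppm binning and deisotoping of per-pixel
peak lists, bisecting k-means segmentation into spatial blob masks,
Pearson mask-to-ion co-localization, adduct-aware accurate-mass lipid
annotation, and cross-platform LC–MS confirmation with identified /
annotated tiers.

## Processing model and assumptions

**Binning.** All peaks from all pixels are pooled and sorted; a new
feature bin starts wherever the gap to the previous peak exceeds the
tolerance (in ppm, relative to the previous peak's m/z). This greedy
single linkage is the simplest deterministic partition consistent with
sub-ppm FTICR mass stability: peaks of the same ion across pixels jitter
by a fraction of a ppm and chain tightly, while distinct lipid species are
many ppm apart. The bin representative is the intensity-weighted mean of
its members, which keeps the axis anchored to the high-signal pixels. The
default tolerance, 2.5 ppm, deliberately matches the identification
tolerance so a binned feature can be carried straight into annotation. In
degenerate pools single linkage can produce representatives out of axis
order; the implementation re-sorts bins in that case so the feature axis
is always strictly increasing.

**Deisotoping.** A peak is removed iff a *retained* lighter peak exists at
m/z − k·1.0033548 Da (k = 1..3) within tolerance and the candidate's
intensity does not exceed that lighter peak's. Scanning in ascending m/z
means a removed isotope can never shield a heavier peak. The rule assumes
singly charged ions (valid for MALDI lipids in positive mode) and is
conservative by construction: the lightest peak of a spectrum, and any
peak more intense than its putative monoisotopic partner, is never
deleted. For lipids below ~1 kDa the M+1/M ratio is ≤ ~0.5 (≈ 0.011 per
carbon), so the intensity condition holds for genuine isotopes.

**Normalization.** Pixel spectra are TIC-normalized (each pixel row of the
binned matrix scaled to unit total) before segmentation and correlation,
which removes pixel-to-pixel ionization-efficiency variation; raw
intensities are retained for ion-image rendering. All-zero pixels (e.g.
dropped acquisitions) are left at zero and counted in a message rather
than silently propagated as NaN.

**Segmentation.** Bisecting k-means starts from one all-pixel cluster and
repeatedly splits the cluster with the largest within-cluster SSE by
2-means until k clusters exist. It was chosen over agglomerative
clustering for its near-linear cost in pixels, and over flat k-means for
its deterministic cluster hierarchy (the bisection log records every
split). Each split runs Lloyd's algorithm with Euclidean distance, at most
100 iterations, best of `trials_per_split` (default 10) random
two-distinct-pixel initializations — plus one deterministic farthest-point
initialization (the pixel farthest from the cluster centroid, then the
pixel farthest from it). That extra trial matters: structures like the
follicle cortex occupy well under 0.1 % of the section, and two uniformly
random pixels essentially never land such that Lloyd converges onto a
50-pixel structure inside a several-thousand-pixel cluster, whereas the
farthest-point start does so deterministically. The best split by SSE
still wins, so the added trial can only improve the objective. Ties in
pixel assignment go to the first centroid; a split whose all member pixels
are identical is resolved by peeling one pixel off (SSE stays 0).

**Co-localization.** Each feature's ion image is correlated with each
binary ROI mask over *all* pixels of the section (not a local window),
matching the mask-versus-image formulation. Pearson r is invariant to
positive affine rescaling of the image, so TIC normalization does not
change r; complementing the mask flips its sign. A zero-variance image has
no defined correlation and returns `NA` with a warning — never a silent 0.
Features are kept at r ≥ `min_r` (default 0.5 — a permissive screen meant
to be refined by inspecting the ion images), each feature is assigned
exclusively to its best-scoring ROI (marker lists per zone are disjoint),
lists are truncated to `top_n` (default 25) and ranked by descending r
with ties broken by ascending m/z.

**Annotation.** Theoretical m/z = neutral monoisotopic mass + cation mass
− one electron, for the four positive adducts seen for skin lipids by
MALDI ([M+H]⁺, [M+Na]⁺, [M+K]⁺, [M+NH4]⁺; glycerolipids ionize almost
exclusively as Na⁺/K⁺ adducts). Matches within 2.5 ppm (inclusive) are
sorted by absolute ppm error — the "best match score". The bundled lipid
table is a small, synthetic, hand-built stand-in covering the DG, TG, PC,
SM, PA and CerPE classes with formulas derived from standard class rules
(e.g. DG(c:d) → C(c+3)H(2c−2d+4)O5); a real study would swap in a LIPID
MAPS export via `read_lipid_db(path)`.

**Evidence tiers.** An MSI annotation is *identified* when the feature is
also detected by LC–MS (adduct-switch-aware neutral-mass agreement within
tolerance — e.g. MALDI [M+K]⁺ at 661.51678 and LC–MS [M+NH4]⁺ at
640.58744 share the neutral 622.55362) **and** at least `min_frags`
diagnostic MS2 fragments are observed; *annotated* when cross-detected
without sufficient fragments; *unmatched* otherwise. "Sufficient" defaults
to one fragment — minimal positive evidence matching a binary outcome.
Diagnostic chemistry is simplified to acyl RCOOH neutral losses
(glycerolipids, including the diacyl part of PC) plus the phosphocholine
head-group fragment 184.0733 (PC/SM); retention time is carried but not
used for matching, since no RT-matching rule is defined for this workflow.

## Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| `tolerance_ppm` | 2.5 | ppm | binning linkage, deisotope window, annotation and cross-match tolerance |
| `max_isotopes` | 3 | — | 13C shifts considered in deisotoping |
| `k` | regions + 1 (phantom) / 6 | — | segmentation clusters |
| `trials_per_split` | 10 | — | random 2-means restarts per bisection |
| `min_r` | 0.5 | — | minimum Pearson r for a marker |
| `top_n` | 25 | — | markers reported per ROI |
| `min_frags` | 1 | — | fragments required for tier *identified* |
| `pixel_size_um` | 10 | µm | raster pitch |
| acquisition window | 200–1500 | m/z | applied on imzML read, configurable |

For the phantom, the default k is the number of ground-truth regions plus
one for the dermis background — eight with the default panel (epidermis,
SG peripheral, SG central, ORS, IRS, medulla, cortex, background). Using
fewer clusters than spectrally distinct classes forces merges and is the
first thing to revisit when segmentation looks underfit on real data.

In the pipeline, clusters whose best overlap is the plain background are
not screened for markers: after TIC normalization, background features are
relatively depressed wherever strong zone markers dominate the TIC, so
they correlate positively with the background mask and would be reported
as "markers of bulk dermis". The screen targets the morphological ROIs,
which is what marker discovery means here; `rank_markers()` itself is
agnostic and accepts any mask set.

## What the phantom emulates — and what it does not

The generator plants, on a 120×120 grid at 10 µm pitch, an epidermis band,
an elliptical sebaceous gland with a peripheral ring and central core
(area ratio set by `sg_core_frac` = 0.55), and a four-layer concentric
follicle. Its default marker panel uses the eight marker m/z values
characteristic of those zones, two of which carry full lipid identities
(DG(36:1) as [M+K]⁺, planted at its theoretical 661.51678; PC(37:1) as
[M+K]⁺ at 840.58791) so annotation and tiering are exercised.

Statistical structure: marker intensities are log-normal (strictly
positive, heavy-tailed, like real MSI intensities) with meanlog log(20000)
and sdlog 0.4 against 200 background features at meanlog log(300) — sebum
lipids genuinely dominate sebaceous-gland spectra, and this ratio makes a
marker roughly a quarter of a pixel's TIC in its zone. Every peak's m/z is
jittered by Gaussian noise of 0.3 ppm (FTICR-like mass stability), M+1
isotope partners are appended (binomial carbon estimate when the formula
is known, fixed 0.4 ratio otherwise), markers leak at 1 % of their mean
outside their zone, and 1 % of pixels are dropped. Companion LC–MS tables
carry one feature per lipid-backed marker at the switched adduct (DG/TG →
[M+NH4]⁺, otherwise [M+H]⁺), with fragment lists for a configurable
fraction so both tiers arise.

The phantom does **not** emulate: profile-mode peak shapes or transients,
matrix cluster ions, chemical noise correlated across pixels, intensity
gradients from matrix deposition, section folds or co-registration error,
multiple charge states, or in-source fragmentation. Consequently, a
passing phantom suite demonstrates the correctness of the algorithms under
the stated noise model — not that real sections will segment this cleanly.
Real data will have lower ARI and will need the permissive `min_r` screen
followed by visual inspection of ion images, which is precisely how the
workflow is meant to be used.

## Numerical choices and degenerate inputs

* imzML arrays are written as uncompressed little-endian 64-bit floats for
  both m/z and intensity, so write→read is value-exact; the ibd UUID is an
  MD5 digest of the array payload, making equal datasets byte-identical on
  disk (and determinism checkable by file comparison).
* All randomness flows from explicit seeds; RNG state is saved and
  restored around every seeded operation, so library calls never perturb a
  caller's RNG stream.
* Cross-match neutrals below 1e-6 Da are treated as non-positive and
  dropped (guards the adduct-minus-adduct float edge).
* Empty datasets bin to a 0-feature matrix rather than erroring; the
  pipeline, by contrast, refuses to run on zero spectra, since every
  downstream stage would be vacuous.
* `adjusted_rand()` returns 1 when both partitions are single clusters
  (the chance-correction denominator vanishes only in that degenerate
  agreement case).
* Ion-image PNGs are clipped at the 99th-percentile intensity before
  scaling, so a single hot pixel cannot flatten the display range.

## Problem sizes used in validation

The self-contained validation runs the full pipeline on the default
120×120-pixel phantom (≈ 14,400 spectra, ≈ 210 binned features) and checks
segmentation ARI ≥ 0.9 with marker precision and recall of 1.0; unit and
property tests use 48×48 and 60×60 phantoms with 40–60 background
features. Oracle equivalence is established on 200 random instances each
for the 2-means split (≤ 12 points, exhaustive minimum-SSE bipartition),
peak binning (50-peak pools, O(n²) single-linkage union-find) and Pearson
scoring (direct covariance formula, 1e-12).

## Known limitations

* The lipid table bundled for demonstration is tiny; annotation quality on
  real data is bounded by the table you supply.
* Exclusive best-ROI marker assignment hides genuinely shared markers
  (e.g. an ORS lipid also present in epidermis appears only under its
  better-correlated zone). Inspect the full score matrix when that
  matters.
* Isobaric species within 2.5 ppm cannot be distinguished by accurate mass
  alone; the tier system flags, but does not resolve, such ambiguity
  without fragments.
* No multiple-testing control is applied to the correlation screen; it is
  a ranking device, not an inference procedure.
* Spatial structure is ignored by the clustering (pixels are exchangeable
  given their spectra); spatially regularized segmentation is out of
  scope.
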