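---
title: "marrowniche: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{marrowniche: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`marrowniche` implements a quantitative pipeline for studying the bone-marrow
adipocyte niche in B-cell leukaemia and similar settings. It covers three
analysis tracks plus the synthetic benchmarks that validate them:

1. **Histomorphometry** — segmentation of adipocyte "ghosts" in H&E-style
   trephine sections and per-biopsy count/density/size statistics normalised
   to the region of interest (ROI), with two-group Mann–Whitney comparison.
2. **Phosphoproteomics** — extracted-ion-chromatogram (XIC) peak-height
   quantification of identified phosphopeptides, per-sample sum
   normalisation, differential testing, kinase-substrate enrichment analysis
   (KSEA) and ontology over-representation.
3. **Pulsed SILAC** — proteinGroups-style record filtering, log2 H/M ratio
   normalisation, cross-timepoint co-regulation and a pathway
   over-representation report.

Every track has a generator (`gen_marrow_image()`, `gen_phospho_raw()`,
`gen_silac_table()`) that produces inputs with known ground truth; all
recovery claims in the test suite are claims about those synthetic
benchmarks, not about any particular clinical dataset.

# Histomorphometry

## The segmentation model

In H&E sections, adipocytes appear as *empty* vacuoles: the lipid dissolves
during processing, leaving a bright, nearly textureless ellipse on a pink,
textured haematopoietic background. The segmentation therefore works on two
neighbourhood features of the luminance image (Rec. 601 weights), computed
over a square window of radius `window_radius_px` (default 3 px) with
reflected borders:

* the **moving median** (robust brightness, speckle-resistant), and
* the **moving standard deviation** (local texture),

plus their elementwise product as a combined channel. Thresholds may be
fixed or `"auto"`; `"auto"` uses an Otsu histogram split (256 bins) of the
channel restricted to the ROI — upper class kept for the median-luminance
channel, lower class for the sd channel. A constant channel makes the Otsu
split meaningless, so that case is an explicit error instructing a fixed
threshold.

A subtlety dictates how the two conditions combine. The moving sd is
necessarily high in a band of roughly one window radius around *every*
vacuole edge (the window straddles the step), so a pixelwise AND of
"bright" and "smooth" erodes each object by about the window radius and
systematically underestimates areas. The package instead treats the smooth
condition as a *seed* detector and the bright condition as the *extent*:
the final mask is the union of bright connected components that contain at
least one bright-and-smooth pixel (morphological reconstruction), holes
filled. Textured-bright artefacts contain no smooth seed and are rejected
wholesale; true vacuoles are recovered at their full luminance extent.
Raising the luminance threshold still can only shrink the mask.

## Cluster separation

Adjacent adipocytes merge into one blob at thresholding. Blobs are split on
the distance transform: watershed with an extension radius of half the
minimum seed separation (`min_seed_separation_um`, default 15 µm), so two
distance maxima closer than that merge into one object. Ridge pixels are
assigned to a neighbouring object, which makes the split exactly
area-conserving — an invariant the tests assert.

## Shape filtering and the perimeter estimator

Objects are filtered by area (`min_area_um2` = 200, `max_area_um2` = 15 000
µm²) and by form factor $4\pi A / P^2$ (circle = 1, default minimum 0.5).
These defaults bracket human bone-marrow adipocyte diameters (~15–140 µm)
and are configuration-exposed, since the original acquisition settings are
not published.

The perimeter $P$ of a rasterised object is ill-defined at the pixel level:
counting boundary cracks overestimates a circle's perimeter by $4/\pi$,
while chain codes through pixel centres underestimate axis-aligned
rectangles. The package uses a corner-weighted crack-boundary estimator

$$ P = 1.010\,n_{\text{edges}} - 0.3725\,n_{\text{corners}} $$

where $n_{\text{edges}}$ counts unit boundary cracks and
$n_{\text{corners}}$ counts boundary turns (checkerboard junctions count
twice). The two weights were calibrated once, before the tests were
written, on rasterised disks of radius 10–60 px and on axis-aligned
rectangles: disks come out with form factor 0.976–1.023 and a 100×4
rectangle within $10^{-3}$ of its closed form $4\pi\cdot400/208^2$. For
degenerate, very small objects the estimator is floored at the equal-area
circle perimeter divided by $\sqrt{1.05}$, so the form factor never exceeds
$1 + \varepsilon$ with $\varepsilon = 0.05$ (the discretisation allowance).

## Morphometry and group comparison

Counts are normalised to the ROI area only (`density_per_mm2 = n /
roi_area_mm2`), so excluded bone or artefact regions never dilute density.
Objects touching the ROI border are kept by default (`exclude_border`
flips this). Group comparisons use a two-sided Mann–Whitney U with
mid-ranks; for total $n \le 12$ the p-value is computed by complete
enumeration of the $\binom{n}{n_a}$ assignments (ties handled exactly),
otherwise by the tie-corrected normal approximation with continuity
correction.

## What the image generator emulates — and what it does not

`gen_marrow_image()` plants lognormally sized ellipses (median diameter 55
µm, log-sd 0.25, axis ratio in [1, 1.6] so planted shapes stay above the
default form-factor cut), with uniform bright interiors, an optional thin
dark rim drawn *outside* the truth boundary, Gaussian background noise
(sd 0.03 on the [0,1] scale), optional dark artefact blobs excluded from
the ROI, and touching pairs overlapping 10–30 % of the smaller radius so
the separation stage has a known answer. Default canvas is 1024×1024 px at
1 µm/px; the ground-truth label map assigns shared pixels of a pair to the
nearer centre. It does **not** model stain variation, uneven illumination,
partial-volume boundary blur, non-convex adipocytes, or dense packing
beyond the rejection-sampling limit (exceeding it is a reported error, not
a silent truncation). Passing recovery tests on these images therefore
demonstrates the internal consistency and geometric accuracy of the
pipeline, not robustness to every real-world staining artefact — ROI
delineation, in particular, remains an expert input.

# Phosphoproteomics

## XIC quantification

For each identified peptide (id table with target m/z and expected apex
retention time), the XIC collects all raw points within ±`ppm_tol` (default
10 ppm, the instrument-level mass tolerance) and ±`rt_half_window_s`
(default 30 s, matching chromatographic peak bases of ≈30 s). The peak
height is the **maximum point intensity** of the trace, with no smoothing
or apex fitting by default (a 3-point moving-average switch exists); a
trace with fewer than `min_points` (default 10) points is a missing
measurement, never imputed. Heights are normalised to each sample's total
and rescaled by the mean total, which leaves fold changes invariant to any
per-sample global scale factor. Note that sum normalisation assumes the
bulk of the signal is unchanged: if a large, one-sided share of total
intensity is regulated, the common-mode correction absorbs part of the
effect.

Differential testing: mean log2 fold change (condition B vs A) and a
two-sided equal-variance Student t test on log2 heights (Welch by flag),
requiring at least two present values per condition, BH-corrected across
tested peptides. Zero-variance degenerate cases resolve to p = 1 (equal
means) or p = 0.

## KSEA and ontology enrichment

Peptides significant at raw p < 0.05 (the substrate-grouping convention;
the stricter |log2 FC| ≥ 1 site-level rule is a second preset) are split by
fold-change sign and each kinase's substrate set is tested per direction
with the inclusive upper-tail hypergeometric $P[X \ge k]$, computed in
exact log-binomial arithmetic. The universe defaults to tested peptides
mapping to ≥1 substrate set — not all detected peptides — to avoid
inflating $N$ with unannotatable sites (a flag switches to all-detected).
BH is pooled across kinase×direction tests. Peptides annotated to several
kinases count for each.

Each kinase also receives a fold-change z-score
$z = (\bar{x}_m - \bar{x})\sqrt{m}/s$ over its $m$ measured substrates,
classified at the inclusive ±1.5 thresholds (over/under-represented/
neutral). The z-score, being a function of continuous fold changes, is the
*calibrated* KSEA statistic: under label permutation of a null dataset its
two-sided normal p is uniform (the test suite checks this with a
Kolmogorov–Smirnov test). The hypergeometric p, by contrast, is discrete
and conservative by construction — at typical set sizes
$P(p = 1) \approx e^{-Kn/N}$ is large — so it can only be checked for
validity (super-uniformity), not for KS-uniformity. Both checks are run.

## What the phospho generator emulates

Each peptide gets a Gaussian elution peak (base width `peak_width_s` = 30 s,
σ = base/4) sampled so at least `points_per_peak` = 10 points fall within
the base width with one point exactly at the apex (which makes the
max-intensity height an exact oracle at zero noise), m/z jitter up to
±2 ppm, lognormal baseline amplitudes spanning 2^18–2^24, and per-sample
log2 amplitude noise. Regulated peptides carry a planted log2 fold change;
planted kinases get dedicated regulated substrate sets and decoy kinases
are drawn from unregulated, unannotated peptides. Not modelled: co-eluting
interferences, saturated peaks, retention-time drift between runs, and
missingness mechanisms other than the min-points rule.

# Pulsed SILAC

Records flagged reverse (decoy), contaminant or identified only by modified
peptides are removed in that order, then records without a single valid H/M
ratio; the per-rule removal counts are reported and additive. Ratios are
log2-transformed and median-centred per timepoint (mean-centring by flag).
Proteins present at both timepoints are classified by sign against a
configurable `margin` (default 0): co-down, co-up, discordant, or
unclassified within the margin. The pathway report runs a two-sided Fisher
exact test (point-probability rule) per pathway on the 2×2 table (co-down
vs not) × (in pathway vs not) over the universe of quantified proteins,
BH-corrected, and retains pathways with q ≤ 0.05 **and** enrichment factor
$(k/n)/(K/N) > 2$, sorted by enrichment factor.

Two structural caveats follow from these definitions and are worth stating
explicitly. First, median-centring assumes the bulk of the proteome is
unchanged; under *global* repression (most proteins down) the centring
lands inside the down cluster and the margin-0 sign rule then measures
relative, not absolute, repression — the global-repression readout belongs
on the uncentred log2(H/M) scale, as `analysis/04_pulse_silac.R`
demonstrates. Second, with the universe fixed to the quantified proteins
the enrichment factor is bounded by $N/n$; when ~87 % of proteins are
co-down the bound is ≈1.14, so an enrichment > 2 report is only meaningful
when hits are a minority of the universe (the benchmark regime uses a 30 %
co-down background with planted pathways 90–100 % co-down). Reports of
larger factors at near-global repression necessarily compare against a
broader external annotation universe, which this package deliberately does
not model.

# Pipeline, determinism and numerical choices

* All randomness flows from explicit seeds; generators restore the caller's
  RNG state. The orchestration layer derives per-stage seeds
  deterministically from one global seed so stages can be re-run
  independently; two runs with the same config produce byte-identical
  tabular outputs.
* YAML configs are schema-checked (unknown keys are errors *before* any
  stage runs) and defaulted; the effective parameters, an output manifest
  with MD5 digests and the wall time go into `report.json`.
* Coordinates are 0-based, row-major, origin top-left; areas are pixel
  counts × pixel area. Label maps are stored losslessly in PNG by splitting
  labels into low/high 8-bit channels.
* Exact-test tie-breaking: the two-sided Fisher rule includes tables whose
  point probability is within relative 1e-7 of the observed table's, the
  conventional guard against floating-point ties.
* Benchmark problem sizes (20 images of 50 objects; 500–2000 peptides;
  100–500 enrichment simulations; 470-protein SILAC tables) were chosen as
  the smallest sizes at which the binomial/Monte-Carlo margins of the
  stated thresholds are comfortably resolved.

# Known limitations

* The original acquisition pipeline's exact filter order and thresholds are
  proprietary and unpublished; this package fixes one documented
  interpretation (seed/extent reconstruction, Otsu auto-thresholds) and
  exposes every parameter.
* Whether the upstream "size" output is an area or a diameter is not
  stated; area in µm² is assumed throughout.
* No retention-time alignment across runs, no MS2/identification modelling,
  no phosphosite-localisation scoring, no stain normalisation, no
  whole-slide tiling.
* The Mann–Whitney exact branch enumerates up to $n = 12$; beyond that the
  tie-corrected normal approximation is used.
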