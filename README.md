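# marrowniche

Quantitative analysis of the bone-marrow adipocyte niche: adipocyte
histomorphometry from H&E-style trephine images, XIC-based phosphopeptide
quantification with kinase-substrate enrichment analysis (KSEA), and
pulsed-SILAC protein-synthesis analysis with pathway over-representation —
each stage paired with a synthetic-data generator carrying known ground
truth, so every recovery claim is testable end to end.

It is written for researchers studying how adipocyte-rich marrow
microenvironments reshape leukaemic cells: pathologists quantifying marrow
adiposity on biopsies, and proteomics analysts working downstream of
search-engine output (identification tables, proteinGroups-style exports).

## What it computes

**Histomorphometry.** Adipocytes in H&E sections are empty, bright,
low-texture vacuoles. Segmentation thresholds two neighbourhood features of
the luminance image — moving median and moving standard deviation over a
(2r+1)² window — inside an expert-drawn ROI, separates touching vacuoles by
watershed on the distance transform, and filters objects by area and form
factor

    FF = 4·pi·A / P²            (circle = 1; default minimum 0.5)

with perimeter from a corner-weighted crack-boundary estimator. Outputs are
per-object geometry and per-biopsy count, density (count / ROI area in
mm²), and size distribution; cohorts are compared with a two-sided
Mann–Whitney U (exact by enumeration up to n = 12).

**Phosphoproteomics.** For each identified peptide, an extracted ion
chromatogram within ±10 ppm / ±30 s of the expected apex; peak height = max
point intensity (≥10 points required, otherwise missing); per-sample sum
normalisation; equal-variance t tests on log2 heights with
Benjamini–Hochberg correction. KSEA groups sites significant at raw
p < 0.05 into kinase substrate sets, tests each direction with the
inclusive upper-tail hypergeometric, and scores each kinase's fold-change
shift as z = (x̄_set − x̄)·√m / s, classified at ±1.5.

**Pulsed SILAC.** ProteinGroups-style records are filtered (decoy →
contaminant → modified-only → no valid ratio, counts reported), H/M ratios
log2-transformed and median-centred per timepoint, proteins classified by
cross-timepoint sign agreement, and co-downregulated proteins tested per
pathway with a two-sided Fisher exact test; the report keeps pathways with
BH FDR ≤ 5 % and enrichment factor (k/n)/(K/N) > 2.

## Worked example

```r
library(marrowniche)

# one synthetic biopsy with 50 planted adipocytes, then full segmentation
sim <- gen_marrow_image(marrow_image_params(n_adipocytes = 50, seed = 42))
seg <- segment_adipocytes(sim$image, sim$roi)
seg$summary$n_adipocytes
#> [1] 50
round(seg$summary$density_per_mm2, 1)
#> [1] 47.7
# per-object area error vs ground truth, matched by nearest centroid
i <- apply(outer(sim$truth$objects$centroid_row, seg$objects$centroid_row + 1, "-")^2 +
           outer(sim$truth$objects$centroid_col, seg$objects$centroid_col + 1, "-")^2,
           1, which.min)
mean(abs(seg$objects$area_um2[i] - sim$truth$objects$area_um2) /
     sim$truth$objects$area_um2)
#> [1] 0.006
```

The recovered count matches the planted truth, density is count per mm² of
ROI, and per-object areas are within ~1 % of the generator's label map.

The `analysis/` directory holds the narrative drivers, each a thin script
over the package functions, writing its tables under `results/`:

```sh
Rscript analysis/01_histomorphometry.R     # cohort morphometry + Mann-Whitney
Rscript analysis/02_phospho_differential.R # XIC quant + differential sites
Rscript analysis/03_ksea_ontology.R        # KSEA + ontology enrichment
Rscript analysis/04_pulse_silac.R          # SILAC filtering/classification/report
```

`analysis/01` prints, for example:

```
diagnosis: median density 23.9 /mm^2 (true 23.9), remission: 95.0 /mm^2
Mann-Whitney U = 0, two-sided p = 0.0009391 (normal approximation with tie correction)
```

— an adipocyte-poor cohort against an adipocyte-rich one, with the density
difference and its two-sided p-value; `analysis/04` prints the per-rule
filter removals, the fraction of newly synthesised proteome down at both
pulse timepoints, and the Table-style pathway report (set, k/K, n/N,
enrichment factor, p, q).

## Layout

```
R/                  implementation (generators, histo, phospho, enrich, silac, pipeline)
analysis/           numbered narrative drivers
scripts/acceptance.R  benchmark recomputation
tests/testthat/     unit, property and acceptance suites
vignettes/          methods and design notes
```
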