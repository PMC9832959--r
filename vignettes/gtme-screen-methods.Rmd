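---
title: "Methods: image-based screening analysis for sex-dimorphic GTme proliferation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based screening analysis for sex-dimorphic GTme proliferation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtscreen)
```

# The assay and what this package computes

Genital tubercle mesenchymal (GTme) cells proliferate sex-dimorphically in
culture — male cells, primed by embryonic androgen exposure, outgrow female
cells — and that difference is the readout of an image-based 384-well
screen: wells are seeded at 300–500 cells, treated (compound library at
250 nM, or siRNA), grown for six days, Hoechst-stained, and imaged at four
fields per well. Segmenting the nuclei gives each well two numbers: a total
cell count and a mean nuclear area.

`gtscreen` implements the complete analysis of that screen — hit calling,
false-discovery estimation, hit categorisation, sex partitioning, family
enrichment, and the supporting growth-curve, qPCR and BrdU quantifications —
together with a seeded synthetic-data generator that stands in for the
wet-lab screen and supplies ground truth for every stage.

# The synthetic-data generator

The generator's defaults are the study conditions; they are fixed once and
all tests run against them.

## Growth model

Observed counts follow discrete multiplicative growth with lognormal noise:

* expected count after $d$ days: $n_0 \, r_{\text{sex}}^{\,d} \, e$, where
  $r_{\text{male}} = 1.35 > r_{\text{female}} = 1.25$ per day and $e$ is the
  compound's multiplicative effect on the final count ($e = 1$ for DMSO and
  null compounds);
* the observed count is the expectation times a unit-mean lognormal factor
  with coefficient of variation `count_cv = 0.08`, floored at zero and
  rounded.

The daily rates were chosen so that a 6-day culture starting from ~400
cells reaches the low thousands per well with a clear male advantage by day
5, the qualitative shape such assays measure. Growth-curve readouts give
curves, not equations; discrete multiplicative growth with multiplicative
noise is the simplest model that reproduces them.

Two seeding policies are intentional: *screen* wells draw $n_0$ uniformly
from 300–500 (well-to-well seeding spread within the stated range, which is
what the robust MAD statistic has to absorb), while *growth-course*
replicates are all seeded at the midpoint (a time-course experiment controls
seeding density; this is what makes per-timepoint Welch tests on $n = 4$
replicates well-powered).

Hormonal modulation enters as multiplicative factors on the daily rate:
methyltestosterone `MT = c(male 1.03, female 1.08)` (boosts female growth
strongly, male weakly) and the androgen-receptor antagonist
`FLUT = c(male 0.92, female 1.00)`. An optional epithelial contamination
fraction adds a second population with its own growth rate, emulating the
purity difference between the crude and FACS-based isolations; the default
is 0 (pure).

## Nuclear size model

Mean nuclear area rises from `size0 = 60` px² towards a plateau
`size_plateau = 120` px² as an exponential approach with per-day rate
`size_rate = 0.35`:
$s(d) = s_\infty - (s_\infty - s_0)(1 - \rho)^d$. Compounds may declare an
additive area shift (negative = shrinkage), which is how planted C1/C2
material is produced. With `couple_size_growth = TRUE` the daily growth
excess scales with the remaining distance of the size to its plateau, so
proliferation slows as nuclei enlarge — the differentiation coupling that
`size_growth_correlation()` detects as a negative Spearman correlation.

## Field images

Nuclei are rendered into 16-bit fields (256×256 by default) as flat-core
blobs with a narrow Gaussian edge whose half-maximum sits exactly at the
drawn radius ($r \sim N(6, 0.8)$ px), over a background of 500 grey levels
with peak 20 000 and Gaussian read noise (sd 100). The flat-top-with-soft-edge
profile was chosen deliberately over a plain Gaussian: it makes the
thresholded area nearly threshold-independent, so ground-truth areas
($\pi r^2$) are recoverable to a few percent, and neighbouring intensity
skirts do not bridge. Placement is hard-disk rejection sampling with a
3-px clearance between nucleus edges (overlap is an opt-in stress mode);
infeasible packings error out after a bounded number of attempts rather
than degrading silently. Per-well counts are split multinomially across the
four fields, and the exact centers, radii and intended areas are recorded
as ground truth.

What the generator does **not** emulate: point-spread functions,
vignetting, autofluorescence, debris, cell-cycle chromatin texture, or
spatial plate gradients. Passing the imaging round-trip therefore shows
that the segmentation pipeline is faithful to its own forward model, not
that it matches a commercial readout on real micrographs — the commercial
software's parameters are unpublished, so only functional equivalence on
synthetic truth can be asserted.

# Image readout

`segment_nuclei()` re-implements the per-field measurement: morphological
opening with a disc (radius 15 px) as a rolling-ball-style background
estimate, subtraction, a global threshold (Otsu by default; a fixed
threshold for noiseless fixtures), connected-component labelling, optional
distance-transform watershed splitting, and an area filter.

Numerical choices:

* **Blank fields** are legal. Under Otsu, a field whose post-subtraction
  dynamic range is below 3% of full scale returns zero objects (a pure-noise
  field never reaches this); a strictly constant image under Otsu is a
  degenerate-image error. The fixed-threshold path handles both naturally.
* **`max_area` is the splitting trigger, not a hard filter.** Blobs larger
  than `max_area` are watershed-split when `split_touching = TRUE`;
  otherwise they are kept and flagged `oversize`, so merged nuclei still
  count once rather than vanishing. `min_area` (20 px²) always filters.
* **Determinism**: watershed seeds come from the distance transform with a
  fixed tolerance; relabelling is contiguous from 1 in original label
  order, so results are reproducible and independent of file enumeration
  order.
* **Border-touching objects are kept**: the counting bias is symmetric
  across wells and cancels in the plate-relative MAD statistics.

`summarize_well()` sums counts over the four fields and pools all object
areas for an unweighted mean; an empty well reports count 0 with the area
flagged missing. "Nuclear size" is object area in pixel²; physical
calibration (µm²/px) is a reporting-time scalar, never baked into the
statistics.

# Hit calling

Each assay plate (one per sex) is analysed independently. For the wells of
a plate, the center and spread are the sample median and the **raw** median
absolute deviation — deliberately unscaled (no 1.4826 normal-consistency
factor), because the hit band is defined directly in raw MAD units:

$$\text{MAD} = \operatorname{median}_w \bigl|c_w - \operatorname{median}(c)\bigr|$$

A compound is a **hyperhit** when the mean count of its technical
quadruplets is at least $\text{median} + k\,\text{MAD}$ and a **hypohit**
below $\text{median} - k\,\text{MAD}$, with $k = 3$; a compound is a screen
hit if it is a hit in either sex. Choices worth stating:

* **Inclusive boundary** (`>=`): a mean exactly 3 MAD away is a hit. The
  strict alternative differs only on exact ties; it is available via
  `inclusive = FALSE` and the choice is echoed in every report.
* **Control wells enter the plate statistics** by default (configurable to
  compound wells only). Nothing in the hit rule itself dictates which
  wells define the per-plate median; including the DMSO wells stabilises
  the null.
* **Degenerate plates** (MAD = 0) emit no calls and a loud warning rather
  than infinite deviations.
* **Controls are judged per well** for the false-discovery rate, while
  compounds are judged on replicate means — an intentional asymmetry: the
  FDR is the fraction of individual negative-control wells that stray
  outside the band, reported as a percentage for hyper and hypo
  separately (7 flagged of 160 gives 4.375%).

Hit categories live on the count-versus-size plane. The nuclear-size shift
of a hit is its replicate-mean area in per-plate area-MAD units; shrinkage
is a shift of $-3$ or beyond (`size_k`, a first-class config value — the
category boundaries on the scatterplot are inherently qualitative, so the
quantification is the package's own):
C1 = hypohit with shrinkage (the cytotoxic signature), C2 = hyperhit with
shrinkage, C3 = any hit without shrinkage; size-*enlarged* hits land in C3
with an extra flag. Every hit receives exactly one category and the
male/female/both Venn partition is asserted to be a disjoint cover on every
run.

Kinase-family enrichment uses an in-package two-sided Fisher exact test
(probability-ordering rule, log-binomial-coefficient accumulation, with a
1e-7 relative tie tolerance): for each family, hits-in-family versus
hits-outside against non-hits, labelled enriched when the family's hit
fraction strictly exceeds the overall hit fraction, ranked by p within
label. No ontology service is called; annotations are a user-supplied
compound-to-family table.

# Supporting quantifications

* **Welch t-test** (unequal variances, Welch–Satterthwaite df, two-sided)
  is the only significance test used, applied per timepoint to growth
  curves with **no multiplicity correction** — matching the assay's
  reporting convention; every output table carries that statement. A
  summary form accepts mean ± SD or SEM with $n$ (SEM converted by
  $\sigma = \text{SEM}\sqrt{n}$).
* **ΔΔCt**: per sample $\Delta Ct = Ct_{\text{target}} -
  Ct_{\text{reference}}$ (Rpl7-style housekeeping normalisation), calibrated
  by the arithmetic mean $\Delta Ct$ of the calibrator group (equivalently,
  the geometric mean of calibrator folds is exactly 1), relative expression
  $2^{-\Delta\Delta Ct}$. Efficiency correction is not modelled. Enhanced
  expression ⟺ fold > 1 ⟺ lower ΔΔCt.
* **BrdU density** is a boundary-inclusive point-in-polygon count over the
  shoelace area, in cells/px²; points outside the ROI go to a QC field. The
  pixel scale of reported densities is instrument-specific, so absolute
  densities are treated as data. Group summaries are printed as **both**
  mean ± SD and mean ± SEM, labelled, because "±" conventions differ
  between reports, and the parser accepts either.
* **Size–growth trend** uses Spearman (not Pearson) correlation between
  per-interval log growth rate and interval-start area, since the claim is
  monotonic, not linear.

# Reproducibility and problem sizes

All randomness flows from one top-level seed through named substreams
(layout / effects / counts / images / qpcr / brdu), so each stage is
independently reproducible and identical seeds give byte-identical tables
and images. Sizes used by the test-suite and the analysis scripts, chosen
to exercise the full study geometry while keeping runs interactive: the
full 438-compound, 6-plates-per-sex screen for hit-recovery checks
(20 replicate screens), 200 seeded growth courses for the sex-dimorphism
power check, a 24-well mini-plate at 4 fields/well for the imaging round
trip, 1000 random plates for the MAD oracle, and 500 random 2×2 tables for
the exact-test oracle.

# Known limitations

* The hit threshold and FDR are plate-relative; no cross-plate
  normalisation (B-score, loess) is applied — the analysed screen applies
  none — so plate gradients, if present in real data, are not corrected.
* Planted effects are multiplicative on the final count; slow-onset or
  biphasic compound kinetics are not modelled.
* The imaging model omits optical artefacts (see above); segmentation
  equivalence to closed-source commercial software cannot be asserted.
* Single-dose screening only; no dose–response modelling.
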