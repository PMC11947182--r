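---
title: "Methods: region-level analysis of multi-replicate MSI lipidomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-level analysis of multi-replicate MSI lipidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, and numerical
decisions behind `msiregion`, in the spirit of a statistical methods
section: what each stage assumes, which knobs matter, and what the
synthetic benchmarks do and do not demonstrate about real data.

## The data model

A MALDI-MSI experiment rasters a laser across a tissue section and records
one mass spectrum per pixel. `msi_sample` stores the pixel spectra with
1-based imzML coordinates and an `acquisition_index` equal to the spectrum
storage order in the file — the only ordering the imzML format exposes, and
the axis along which detector drift accumulates. Intensities are accepted
as 32- or 64-bit floats on disk and processed in double precision.

A `feature_matrix` is one sample's pixels against the shared, aligned m/z
bin list. Zero encodes "no detected signal": peak picking discards
sub-threshold intensity, so zeros are structural and every normalization
step preserves them exactly.

## Peak binning and cross-sample alignment

Peaks are local maxima exceeding `snr` (default 3) times a robust noise
estimate, 1.4826 x the median absolute deviation of the spectrum, with a
minimum apex separation of one bin width. Centroided input degenerates to
thresholding. Binning is a greedy left-to-right merge over the sorted m/z
values: a value joins the open bin while its ppm distance to the *running
bin mean* stays within the tolerance (5 ppm default). Using the running
mean rather than the first element makes the rule symmetric under small
calibration drift; a consequence worth noting is that consecutive bin
centers always end up separated by more than the tolerance, so bins never
overlap. Alignment pools the apex m/z values of *every pixel of every
sample* into a single binning pass, which is what guarantees one shared
feature axis across sections — the prerequisite for any cross-replicate
statistics.

## Annotation

Features are matched against an LC-MS/MS-validated library by accurate
mass within 10 mDa (a Dalton window, not ppm, following the validation
procedure the library comes from). The closest entry wins; exact ties are
reported and flagged ambiguous rather than silently resolved. Two filters
follow: positive-mode matches to phosphatidylinositol and
phosphatidylserine are removed (these classes ionize efficiently only as
negative ions, so such matches are almost certainly false), and manually
curated m/z exclusion windows (default 5 ppm each) remove features whose
ion images are known artifacts. Both filters are order-independent row
filters and keep audit logs.

Lipid shorthand is parsed as `CLASS C:D` or per-chain `CLASS A:B/C:D` with
carbons and double bonds summed over chains. The saturation split used by
the enrichment sets calls a lipid "saturated" at <= 1 total double bond by
default — monounsaturated species grouped with fully saturated ones. The
boundary is a documented choice (`saturated_max_db`), not a community
standard; results at cutoff 0 are one argument away.

## Normalization

Two sources of technical variance are corrected:

* **Within-run drift.** Detector response changes over an acquisition; the
  per-pixel TIC of a raw run can drift by tens of percent.
* **Between-run scale.** Separate sections differ in overall sensitivity
  (sample preparation, matrix deposition, detector state).

TIC normalization rescales each pixel so its feature sum hits a common
target. It is exact by construction (the acceptance suite checks the sums
to 1e-12) but corrects neither mass-dependent drift nor differences in the
composition of the total signal: matrix-derived background ions contribute
a large, run-specific share of every pixel's TIC, so dividing by the
whole-spectrum sum leaves the *annotated* signal unequalized across runs.
The pipeline therefore applies TIC against the full feature matrix and
reports drift diagnostics on the annotated features, where the residual
spread is visible.

**Sparse LOESS** is the workhorse. Per lipid and per sample, a local
polynomial regression (degree 2, tricube weights) of intensity against
acquisition index is fitted using only the non-zero pixels; the fitted
trend is divided out and the series rescaled to the lipid's reference — the
median of its non-zero intensities pooled over all samples. The span is
chosen so the smoothing window covers about 10 % of the sample's total
pixel count (counting all pixels, not only tissue pixels), clamped to the
minimum of `degree + 2` support points; series with fewer non-zero pixels
than that pass through unchanged and are logged. Zeros stay exactly zero —
the "sparse" contract — which is what preserves spatial distributions:
a lipid absent outside its home region contributes no off-region support,
so the trend is estimated where the lipid actually lives.

Two numerical decisions:

* The trend is fitted on *log* intensity and back-transformed. Drift and
  detector response are multiplicative, so the log scale is the natural
  domain; it also keeps the fitted trend strictly positive at sharp
  magnitude transitions (tissue edge against matrix), where a quadratic
  local fit of raw intensities can overshoot through zero and the guard
  denominator would amplify pixels by orders of magnitude.
* The division uses `max(trend, 1e-8 * reference)` as denominator — with a
  log-domain trend the guard is a formality, but it is kept as a hard
  floor.

The drift report gives, per sample and normalization, the OLS slope of
per-pixel TIC against acquisition index over non-zero pixels, the median
TIC, and the `relative_slope` — the fitted fractional TIC change across
the run. Comparisons between normalizations use the relative slope:
absolute slopes are meaningless across outputs whose levels differ by
orders of magnitude (TIC-normalized sums are O(1), LOESS-normalized sums
sit at the pooled-median scale).

**A limitation worth understanding.** Equalizing every lipid's per-sample
level to a pooled reference is exactly what corrects between-run scale —
and it is also, unavoidably, a flattening of any *biological* difference in
a lipid's overall level between samples. A group effect confined to one
region survives only through within-sample redistribution: the measurable
log2 fold change is attenuated by roughly the affected region's share of
the lipid's non-zero pixels. For an effect in a region holding ~90 % of a
lipid's detected pixels, a true -1.0 log2 effect shrinks to about -0.1
after normalization. This is a property of the method, not of the
implementation; it applies equally to real data processed this way. The
effect-recovery benchmark therefore plants its effects in replicates free
of technical variance and runs the segmentation and statistics on the
aligned matrices directly, isolating the statistical recovery property;
when interpreting real normalized data, fold changes of region-dominant
lipids should be read as redistribution measures, not absolute abundance
ratios.

## Segmentation

Each section is segmented independently (no cross-sample embedding):
`log(1 + x)` transform, per-feature standardization (zero-variance features
dropped, standardized values clipped at +-10), projection onto the first
10 principal components, a k-nearest-neighbor graph (k = 20, Euclidean,
self included) reweighted by the Jaccard overlap of neighbor sets with
edges below 1/15 pruned, and Louvain community detection at resolution 0.9
with a fixed seed. These defaults reconstruct the conventions of the
single-cell clustering toolkits this recipe comes from; every one is
overridable. Clusters are relabeled contiguously by decreasing size, and
isolated pixels become flagged singletons.

Clustering deliberately over-segments relative to anatomy: a section
yields more clusters than morphological regions, and the cluster-to-region
map is many-to-one. In practice the map comes from comparing cluster
rasters with H&E-stained serial sections; in this package it is a plain
table (`assign_regions()`), and on synthetic data the generator's truth
provides it automatically by majority vote (`evaluate_segmentation()`).
Unmapped clusters become `unassigned`; `unassigned` and `off_tissue` never
enter group statistics. Segmentation quality is scored as the adjusted
Rand index *after* majority mapping (splitting a region across clusters is
harmless; merging distinct regions is the failure mode), with the raw
cluster-level ARI reported alongside.

Marker tables (`top_cluster_lipids()`) rank lipids per cluster by their
mean intensity after scaling each lipid by its global non-zero median, the
scale on which "elevated in this cluster" is comparable across lipids of
very different absolute abundance.

## Regional statistics

Per sample, region, and lipid, the summary statistic is the mean intensity
over *all* pixels of the region — zeros included, since absence of signal
is information — and tests operate on its log2. All-zero cells yield a
missing value and are excluded.

Differential testing is a one-way ANOVA over the sex x treatment cells
(four cells in the full design; per-sex and pooled variants are one
argument away) with Tukey HSD studentized-range adjustment for the
pairwise contrasts at a 95 % confidence level. The log2 fold change is the
difference of cell means, oriented so contrasts read "exposed - control".
Degenerate inputs are handled explicitly: identical observations give
F = 0, p = 1; zero within-cell variance with distinct means gives
F = Inf, p = 0; cells with fewer than 2 replicates are skipped and logged.
The volcano rule flags p < 0.05 and |log2 FC| > 0.5 (strict inequalities;
exactly 0.5 is not a high effect). No across-lipid FDR is applied to the
volcano by default, matching the reporting convention the workflow
follows; the enrichment layer is where multiplicity is controlled.

Class enrichment groups lipids into class x saturation sets ("PE Unsat.",
"PG Sat.", ...) and compares each set's log2 fold changes against all
non-member lipids with a two-sample one-sided Kolmogorov-Smirnov test in
both directions, Benjamini-Hochberg-corrected across all set x direction
tests within a region/contrast. The exact one-sided two-sample
distribution is used when sample sizes allow, which keeps the test
calibrated at small set sizes: on null simulations (set of 10 among 100
exchangeable lipids) the empirical type-I error at alpha = 0.05 is about
0.04, and on the fully separated 3-of-10 example the p value equals the
enumerated permutation tail 1/C(10,3). Sets smaller than 3 members are
skipped and logged.

## The synthetic generator

`synthetic_config()` describes a study; `generate_dataset()` emits
centroided `msi_sample` objects plus truth tables (regions per pixel,
per-pixel drift, per-region per-lipid means, the effect table, and the
matching annotation library). Pixel intensity is

```
region_mean[region, lipid] x group_effect x sample_scale x drift(i) x lognormal(0, sigma)
```

zeroed with the dropout probability, acquired in row-major raster order,
and fully reproducible from the seed.

Defaults define the benchmark conditions and were chosen to emulate data
on which this workflow demonstrably works — strongly localized regional
lipid chemistry, drift large enough to matter, between-run variation that
simple TIC division cannot fix:

* **Geometry.** 120 x 120 raster; off-tissue margin of 10 % of the grid
  side; a centred airway (lumen radius 8 %, epithelial ring to 14 % of the
  grid side, optional basement-membrane ring) in an alveolar field. The
  airway is centred so anatomy is symmetric along the acquisition order
  and does not tilt the TIC-vs-index drift diagnostic.
* **Regional chemistry.** Each tissue region elevates 12 dedicated marker
  lipids 6-fold (polyunsaturated PE and SM in the airway epithelium, PG and
  saturated PC in the alveolar field, lyso-lipids and free fatty acids in
  the lumen), and every lipid additionally carries a per-region profile
  factor with log-sd 0.8 — regional lipidomes differ broadly, not only in
  a handful of markers, as real ion images show.
* **Parenchymal texture.** Each sample's alveolar field is divided into 4
  Voronoi patches whose profiles vary with log-sd 0.3. Real parenchyma is
  heterogeneous; a perfectly homogeneous field is both unrealistic and
  degenerate for graph clustering (one giant community that absorbs small
  neighbors).
* **Matrix background.** 8 matrix-derived ions, absent from the annotation
  library, strong on the bare margin (6x base) and present over tissue
  (12x base): in MALDI most of the total signal is not annotatable lipid.
  Their per-sample deposition factor spans 2x independently of the tissue
  scale factor, and their drift has opposite sign (matrix signal decays) —
  together these are why whole-spectrum TIC normalization corrects drift
  only partially and cannot equalize annotated signal across runs.
* **Off-tissue channels.** Most lipid channels are exact zeros off tissue
  (sub-threshold signal does not survive SNR peak picking); a random 15 %
  of channels carry sparse mass-specific chemical interference (present in
  30 % of off-tissue pixels at 2 % of base intensity). Exactly identical
  all-zero pixels would be degenerate for the SNN graph, and fully dense
  off-tissue background would contaminate the LOESS support.
* **Technical variance.** Linear multiplicative drift of amplitude 0.5
  with per-lipid amplitude jitter of +-50 % (detector drift is
  mass-dependent); per-sample scale factors log-spaced over a 2x range per
  replicate, with the *same* factor set recurring in every group x sex
  cell so that sensitivity is orthogonal to treatment — the generator-side
  counterpart of randomized acquisition order.
* **Noise.** Lognormal pixel noise with sigma 0.3 and 10 % zero inflation
  on tissue.
* **Effects.** The default template decreases 10 unsaturated PE/PG lipids
  by 1.0 log2 unit in the alveolar region of the exposed group, mirroring
  the kind of surfactant-lipid depletion this analysis is designed to
  detect; `n = 3` replicates per group x sex cell.

What passing the synthetic benchmarks does **not** show: robustness to
isotope interference and peak-shape artifacts (the generator emits clean
centroids), to mis-registration between serial sections, to
intensity-dependent (as opposed to random) dropout, or to tissue-folding
artifacts. The generator's regions are geometric idealizations; real
region boundaries are irregular and partly ambiguous even under H&E.

## Benchmark problem sizes

The test suite and the acceptance script size their simulations to run on
a single CPU in minutes: the segmentation benchmark uses one full
120 x 120 section with 100 lipids; the drift benchmark six 100 x 100
sections with 40 lipids (texture patches and off-tissue interference
disabled — they are segmentation-realism features, and the drift benchmark
isolates normalization); the effect-recovery benchmark six 60 x 60
sections with the default panel, free of technical variance for the reason
given above; the KS calibration 1000 null simulations. Unit tests use
smaller grids with the same structure.

## Known limitations

* Sparse LOESS attenuates region-dominant group effects (see above); an
  internal-standard-based normalization would decouple technical scale
  from biology but requires spiked acquisitions this package does not
  model.
* With n = 3 per cell, the ANOVA is powered only for large effects; the
  enrichment layer aggregates across lipids and is the more sensitive
  instrument at this design size.
* Cluster-to-region assignment is manual by design. The package scores
  segmentations against synthetic truth, but on real data the map is the
  analyst's call against histology.
* Annotation is accurate-mass-only against a validated library; isobaric
  lipids within 10 mDa are reported as ambiguous ties, and in-source
  fragments (e.g. a PA feature arising from PC) are not automatically
  inferred.
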