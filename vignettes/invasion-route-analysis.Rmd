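---
title: "Linking glioblastoma invasion routes to cell states: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking glioblastoma invasion routes to cell states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Glioblastoma kills by local invasion rather than metastasis, and it
invades along distinguishable routes: along blood vessels (perivascular
invasion), as single cells through parenchyma and white matter (diffuse
invasion), and along the meninges (leptomeningeal spread). This package
implements, as one tested workflow, the computational chain that connects
those routes to the four transcriptional states of glioblastoma cells
(MES-like, AC-like, OPC-like, NPC-like): spatial proteomics on multiplex
immunofluorescence scans, single-cell state scoring and embedding, a
regulatory-landscape meta-analysis over gene modules, time-lapse cell
tracking with vessel association, and survival statistics. A
synthetic-data module generates seeded inputs with planted ground truth
for every stage, so the whole chain is testable by recovery without any
external download.

Each stage lives in exported functions under `R/`; the numbered scripts
under `analysis/` are thin drivers that run one stage each on the
synthetic scenario and write tables under `results/`.

# Spatial proteomics

A multiplex scan is an H x W x 8 pixel grid. Four channels are common to
every slide — nuclei (DAPI), autofluorescence (AF), a pan-tumor stain and
an endothelial stain — and up to four channels carry proteins of
interest.

**Channel correction.** `correct_channels()` replaces each channel by its
residual after an L2-regularised regression (no intercept) on the other
seven channels, with pixels as observations; residuals are clipped at
zero. The penalty is zero for DAPI and AF and a tuning constant for the
rest, acting on the per-pixel-normalised Gram matrix so that its scale is
intensity-squared units (default `1e4`, comparable to the squared
dynamic range of a bright stain, which confines the correction to
strongly shared variation such as spectral bleed). We chose the
no-intercept form because it makes the two boundary behaviours exact: at
penalty zero a channel that duplicates another is absorbed entirely, and
as the penalty grows every channel converges back to its raw values.

**Base segmentation.** `segment_base()` clusters the (DAPI, AF, tumor,
vessel) pixel vectors with k-means, k = 5 by default, 10 restarts under a
fixed seed. The vascular mask V is the cluster maximal in the vessel
channel; the tumor mask T is the union of clusters whose tumor-channel
centroid reaches at least half the maximum — on real stains tumor pixels
split into nucleus-rich and cytoplasm-rich clusters, and both belong to
T. A channel that is zero everywhere yields an empty mask rather than an
error. Pixels claimed by both masks resolve to the vessel class, since
the endothelial signal is host-derived and morphologically distinct.

**Compartment labeling.** `label_compartments()` produces the 9-class
schema: high/medium/low-density tumor, circle-shaped aggregates,
perivascular tumor, corpus-callosum diffuse, elongated diffuse, vessels,
and parenchyma. Density is the uniform box-filter mean of the T mask
(window 31 px); high/medium/low are cut at cell-fractions 0.80 and 0.45
of the filtered density. We deliberately use absolute fraction cutoffs
rather than within-slide quantiles (a quantile option remains available):
quantile thresholds make a compartment's definition depend on the slide's
composition — adding perivascular sleeves moves the median density and
silently relabels medium-density tumor — whereas "at least 80% of the
window is tumor cells" transfers across slides. Perivascular tumor is T
within 10 px of V. Aggregates are connected components with area 100-2000
px and moment-based roundness at least 0.8 (we compute roundness as
area / (pi (major/2)^2) from second moments instead of a perimeter-based
circularity because digital perimeters are biased upward on small discs).
Elongated diffuse cells are components with eccentricity at least 0.9 and
area at least 20 px within low-density tumor; the area floor keeps
dithered single-cell speckle in sparse tumor from masquerading as
elongated cells. When an anatomical band mask is supplied, elongated
components inside it form the corpus-callosum class; without the mask
that class merges into the elongated class, giving the 8-class schema.
Precedence for overlapping claims is vessel > perivascular > aggregates >
high/medium density > elongated > low density > parenchyma; elongated
cells are detected inside low-density tumor, which they refine.

**Scoring.** `compartment_scores()` implements, per protein i and class
j, the mean over the class's pixels of z_i / z_DAPI — mean intensity
corrected for local cellularity through the DAPI channel. DAPI is floored
at `eps` (default 1 intensity unit) because the formula is undefined on
DAPI-empty pixels. Empty classes return NA with a pixel count of zero.
`compartment_areas()` returns per-class pixel fractions (summing to 1
exactly). Group-wise protein differences between route groups use a
two-sided Welch heteroscedastic t-test per (protein, class) with no
multiplicity adjustment (`spatial_de()`); knockout-versus-control area
shifts are reported with 90% t-intervals (`score_ko_shift()`).

# Single-cell states

**QC.** `qc_filter()` applies, in order: a 500-detected-genes floor per
cell, a 10-cell prevalence floor per gene, kit-specific detected-gene
ceilings (defaults 5100 for v2 chemistry, 7200 for v3 — the ceilings are
arguments, and the synthetic scenario supplies ceilings matched to its
own depth), a 30% mitochondrial-fraction ceiling, and removal of flagged
ribosomal/mitochondrial/hemoglobin genes. Rules are sequential: each
operates on the matrix left by its predecessor, and the report counts
removals per rule, which the tests check against literal brute-force
recounts.

**Scoring and cell cycle.** Expression is library-size normalised to
10,000 counts per cell and log1p-transformed. `score_signature()` scores
a gene set per cell as the signature mean minus the mean of a control set
drawn per signature gene from its average-expression bin (24 bins, 100
controls per gene, fixed seed) — the expression-matched control
construction standard in single-cell toolkits. `cc_regress()` scores the
S and G2M phases this way and regresses the difference (S - G2M) out of
every gene, so that cycling and non-cycling cells of one state co-locate.

**Embedding.** `neftel_embedding()` places each cell in the 2-D
"butterfly" plot: the vertical coordinate is
D = max(SC_OPC, SC_NPC) - max(SC_AC, SC_MES); above the axis the
horizontal coordinate separates NPC from OPC,
x = sign(SC_NPC - SC_OPC) log2(|SC_NPC - SC_OPC| + 1), below it MES from
AC analogously. Quadrants are NPC (upper right), OPC (upper left), MES
(lower right), AC (lower left). Exact ties resolve deterministically to
the lower left and carry a flag; the embedding is invariant to adding a
constant to all four scores of a cell. State calls are the arg-max score.

**Association and differential expression.** `state_route_association()`
is Pearson's chi-squared test of independence on the state x route table
(no continuity correction), with standardized residuals for mosaic-plot
shading; a 4-state by 3-route design has 6 degrees of freedom. `dge()`
is a per-gene two-sided Wilcoxon rank-sum test on log-normalised
expression with Benjamini-Hochberg adjustment; fold changes are log2
ratios of group mean normalised expression with pseudocount 1, and the
MA ordinate is the log2 total raw count. `select_route_regulators()`
shortlists regulators at adjusted p < 0.01 and |log2FC| > 0.5.

# Regulatory landscape

Per-sample regulator x gene-module coefficient tables (the output shape
of a regulatory-clustering method; fitting such tables is outside this
package's scope) are merged by `merge_landscape()`: union of regulators
with absent entries at zero, concatenated module columns, then a
z-transform of each regulator row to mean zero and population standard
deviation one. We z-transform along regulator rows — not module columns —
because the downstream clustering compares modules by their regulator
profiles, and row-wise scaling is what makes one regulator's coefficients
commensurable across samples with different fitting scales.

Modules are clustered by complete-linkage agglomeration under Euclidean
distance (`cluster_modules()`, the hclust defaults) and the dendrogram is
cut at a height — or to a target count — by `cut_metamodules()`; the
height is data-specific and exposed, never hard-coded. A metamodule's
signature keeps the genes present in at least 4 member modules
(`metamodule_signatures()`). Overlap with external state or route
signatures is the Jaccard index (`jaccard_overlap()`). Route signatures
can be refit from expression data by one-vs-rest differential expression,
taking the top 50 genes by fold change at adjusted p < 0.01
(`fit_route_signatures()`) — there is no single canonical recipe for
fitting such route signatures, so this top-N one-vs-rest construction is
our explicit, documented choice. Regulator selectivity for growth condition, patient, or invasion
route is a classical one-way ANOVA of the regulator's z-transformed
per-module coefficients across the factor's levels, two-sided and
unadjusted (`regulator_anova()`); we use the z-transformed coefficients
because they are the quantity the landscape displays and clusters.
Regulators with zero variance are reported as missing.

# Motility and vessel association

`detect_blobs()` is scale-normalised Laplacian-of-Gaussian detection over
a small sigma ladder, with kernels normalised so the detection threshold
is in intensity units. `link_tracks()` runs one constant-velocity Kalman
filter per track (white-acceleration process noise) and matches
predictions to detections frame by frame with an optimal gated bipartite
assignment; the Hungarian solver is implemented in the package (no
dependency provides one) and is tested against brute-force enumeration.
Unmatched detections seed tracks; tracks coast through at most `max_gap`
missed frames. Reported positions are the assigned measurements, so
noiseless scenes are reproduced exactly. `track_speeds()` averages speed
over a track's whole lifetime: summed displacements over elapsed time,
times pixel size over frame interval. `vessel_association()` dilates the
endothelial mask with a disc (default radius 5 px, an exposed parameter
with no canonical value) and classifies a cell by whether its centre falls
inside; for whole tracks, the majority of positions decides, so a free
cell briefly crossing a vessel is not counted. This mask-dilation rule
also stands in for the slice assay's convolutional classifier — a
deliberate substitution of a transparent geometric rule for an
unpublished model. `bootstrap_proportion()` resamples cells with
replacement within replicates, reports percentile intervals, and tests
group differences on the bootstrap distribution of the difference.

# Survival

`km_logrank()` wraps product-limit estimation and the standard logrank
chi-square (aggregated risk-set handling of ties), checked against an
independent risk-set-table oracle. `tma_fractions()` turns per-nucleus
intensities into positive fractions per core under fixed per-marker
thresholds. `cox_marker()` fits a proportional-hazards model of survival
on the marker fraction with age, sex and transcriptional subtype
(baseline: classical) as covariates and cluster-robust variance over
patient id; the marker enters on the percentage-point scale (0-100), the
scale on which reported hazard ratios near 1.01-1.02 per unit are
plausible — per-proportion scaling would imply hazard ratios in the
hundreds. With a single patient cluster the robust variance degenerates
to the naive one, and the function says so rather than failing.
`phenotype_concordance()` defines concordance as the fraction of mouse
replicates agreeing with their line's modal call, averaged over lines —
one reasonable reconstruction of an undefined summary, flagged as such.

# The synthetic scenarios

Each generator is deterministic given its seed and emits ground truth
alongside the data; every recovery test consumes only the data and
compares only against the truth.

*Imaging* (`gen_multiplex_image()`): a 512 x 512 parenchyma background
with a dense tumor disk (fully filled core, 65%- and 35%-filled rims),
gently curved vessels of width 3-6 px with half-filled perivascular
sleeves, six circular aggregates, a corpus-callosum-like band of
horizontal elongated cells, and scattered elongated diffuse cells. DAPI
carries nucleus-scale granularity (dense nuclear dots inside tumor,
sparse elsewhere) so that it is a genuine cellularity proxy and channels
are not mutually collinear; each stain has independent multiplicative
cell texture. Observed channels are a linear bleed-through mixture of the
truth signals plus Gaussian noise clipped at zero — the simplest model
that exercises the regression-based correction; no attempt is made to
simulate optics (point-spread, autofluorescence spectra). Planted shapes
keep clearance margins from each other so the analytic area budget
(sausage formula for vessels and sleeves, disc/annulus/ellipse areas
otherwise) matches the rasterised truth to well under 2% per class; the
truth's density subclasses are defined by the same box-filter rule the
pipeline uses, because "high-density" is inherently a neighbourhood
property.

*States* (`gen_state_counts()`): negative-binomial counts (dispersion 2)
over 2000 genes with four disjoint 50-gene state signatures up-shifted
4-fold in their state's cells, 250 cells per state by default,
route-biased assignment to six samples over three invasion routes, 20%
cycling cells, and planted QC violators that each break exactly one rule:
high-mitochondrial cells (25x mito means), doublets (tripled sum of two
clean profiles, calibrated to exceed the scenario's kit ceilings of
1250/1350 detected genes — chosen between the clean-cell and doublet
detected-gene distributions of this depth), low-depth cells, and rare
genes seen in under 10 cells. Baseline gene means are floored so no real
gene trips the prevalence rule by chance. `count_noise = FALSE` returns
the expected means, used by the noise-free embedding checks.

*Landscape* (`gen_regulatory_tables()`): 6 samples x 20 modules, 40
regulators; each module belongs to one of 3 planted metamodules whose 4
driver regulators gain +3 in its columns over N(0, 0.5) noise; route-,
patient- and condition-selective regulators gain their effect in the
matching samples' columns (default: a route effect of 2); module gene
sets draw 30 of a 60-gene metamodule pool, so within-metamodule sets
overlap and the 4-module support rule is exercised.

*Tracks* (`gen_tracks_movie()`): 20 constant-velocity particles over 50
frames at 0.25 h/frame and 2 um/px, speeds uniform on 5-20 um/h — within
the range reported for glioma cell migration ex vivo; 40% of cells travel
along straight endothelial segments, the rest on straight free paths kept
clear of the vessel corridor so the planted association labels are
unambiguous; start points are sampled so no particle leaves the frame,
keeping per-frame displacement exactly speed x dt. Frames render cells as
Gaussian spots (amplitude 150, sigma 2.5) over mild noise.

*Survival* (`gen_survival_tma()`): 150 subjects split over two
route-phenotype groups, exponential event times with log-hazards
group_effect (0.8) and marker_beta (0.02 per percentage point), 20%
censoring, and four 200-nucleus cores per subject whose bimodal
intensities contain exactly round(fraction x n) positive nuclei, so
mid-threshold classification recovers the planted fraction.

What passing these recovery tests shows — and does not show: the chain
correctly implements its own rules at realistic desk-scale sizes. The
generators do not emulate optical blur, segmentation errors from crowded
nuclei, ambient RNA or batch effects, curved vessel networks in 3-D, or
non-proportional hazards; performance on real scans and libraries
depends on upstream steps (instrument unmixing, nucleus segmentation,
alignment) that are out of scope here.

# Numerical choices and degenerate inputs

Seeds: a single global seed fans out to stage seeds via a fixed affine
map (`child_seed()`), kept below 2^31. K-means uses 10 restarts under the
stage seed. Box filters normalise by the in-bounds window at borders.
Second moments of pixel components add the 1/12 grid-cell correction so
1-px-wide shapes have finite eccentricity. Ridge corrections fall back to
a tiny-ridge solve if the Gram submatrix is singular; all-constant
channels are flagged and skipped. Empty compartments score NA; empty
masks give empty vessel classes; a movie with no detections yields an
empty track set; a one-level grouping is an error for the logrank (df
would be 0). Ties in the embedding go to the lower-left quadrant and are
flagged rather than silently assigned.

# Problem sizes used by the tests

The default test and acceptance runs use the scenario sizes above
(512 x 512 imaging scans; 1000 cells x 2000 genes; 120 modules x 40
regulators; 20 tracks x 50 frames; 150-300 subjects), with 150-500
replicate seeds for the calibration checks (ANOVA size, bootstrap
coverage, Cox bias and coverage) — sizes at which the sampling error of
the checked quantity is several times smaller than the acceptance band
it must fall in.
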