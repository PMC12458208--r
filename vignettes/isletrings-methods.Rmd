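---
title: "Spatial quantification of islet macrophage infiltration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial quantification of islet macrophage infiltration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`isletrings` quantifies how macrophages distribute around pancreatic islets
in multiplex immunofluorescence sections stained for a nuclear dye
(Hoechst/DAPI), insulin, CD68 (pan-macrophage) and HLA class II
(antigen presentation). The pipeline mirrors the whole-slide workflow used
in human type 1 diabetes tissue studies:

1. **Cell detection** on the nuclear channel, each nucleus expanded into a
   whole-cell compartment.
2. **Marker classification** per cell (insulin, CD68, HLA-II), with
   composite calls (CD68+HLA-II+ "activated macrophages", insulin+HLA-II+
   "stressed beta cells") formed by conjunction.
3. **Region geometry**: insulin-containing islets (ICIs) segmented from the
   insulin channel, insulin-deficient islets (IDIs) taken from annotations,
   a 10 um peri-islet collar, eight 25 um concentric rings reaching 200 um
   from every islet boundary, and randomly placed exocrine reference
   squares.
4. **Quantification**: per-region counts, percentages and densities per
   mm2, plus smoothed macrophage density maps.
5. **Group statistics**: Shapiro-Wilk-gated one-way ANOVA/Tukey or
   Kruskal-Wallis/Dunn, a two-way group-by-ring ANOVA, and Spearman
   correlation with a Fisher-z confidence interval.

Because the tissue collections this design targets are not publicly
downloadable, the package ships a first-class synthetic-tissue generator
with known ground truth; every quantitative claim about the pipeline is a
parameter-recovery statement against that ground truth.

# The synthetic tissue model

`generateTissue()` draws one virtual section from a fully specified
configuration (`tissueConfig()`); the output is a pure function of the
configuration, including its seed.

**Geometry.** The tissue is the image rectangle inset by 100 um. Islets are
star-shaped regions: circles of radius $r_0 \sim U(r_{\min}, r_{\max})$
perturbed by low-order radial harmonics
$r(\theta) = r_0\,(1 + \sum_{k=2}^{5} a_k \cos(k\theta + \phi_k))$ with
amplitudes scaled by the irregularity parameter. This reproduces
"islet-shaped" outlines without modelling real morphology. Islets are
placed disjointly by rejection sampling (an error is raised when the
requested packing is infeasible), keeping a 200 um image margin when the
image can afford it.

**Cells.** Cell centres are uniform in the tissue at the configured
density under a hard-core minimum spacing, realised by greedy thinning of
uniform proposals. The density default, 9,950 cells/mm2, is the value
implied by the paired whole-tissue CD68+ percentages and densities of the
study emulated (e.g. 856.3 cells/mm2 at 8.6\% in the type 1 diabetes
group). The spacing default of 6.5 um exceeds the structural floor of
1.5x the minimum nucleus radius; in a 4 um physical section nuclei rarely
overlap in-plane, and this is also what makes threshold-plus-split
detection an appropriate model of the emulated tool.

**Marker structure.** Each cell's zone is its distance band from the
nearest islet boundary (islet interior, ring 1..8 at 25 um per band,
exocrine beyond 200 um). CD68 positivity is Bernoulli with the zone's
configured fraction; `groupPreset()` encodes the published group profiles
(islet and ring-1 values as printed; rings 2-8, for which only the
qualitative shape is reported, interpolate between ring 1 and the exocrine
value). CD68+ cells are macrophages; non-macrophage cells inside an ICI
are beta cells with probability 0.7 (a conventional beta share of the
endocrine mass), and beta cells are the only insulin+ cells.

**Co-expression copula.** HLA-II positivity is heterogeneous per islet:
for islet $i$, the macrophage HLA-II+ fraction $p^{mac}_i$ (applied to
macrophages in the islet and its 10 um collar) and the beta-cell HLA-II+
fraction $p^{beta}_i$ are drawn from Beta marginals coupled by a Gaussian
copula whose latent Pearson correlation is $2\sin(\pi\rho_S/6)$, so the
population Spearman correlation equals the configured $\rho_S$ exactly.
The Beta marginals use configurable between-islet SDs (defaults 0.10 and
0.15); the printed per-region SDs of the emulated study are much larger,
but they conflate latent islet heterogeneity with small-count binomial
noise, and the generator reproduces the latter mechanically. Elsewhere
macrophages use the group-mean fraction and other cells a 2\% background
rate.

**Rendering.** Channels are 8-bit. Nuclei are soft-edged filled ellipses
(area-preserving aspect 0.75-1) at a per-cell intensity drawn from the
channel's foreground model; markers render as cell-sized blobs (nucleus
radius + 2.5 um) on CD68/HLA-II; insulin renders as a diffuse islet fill
(level 30 by default) plus brighter beta-cell blobs, the whole foreground
multiplied by the islet's soft shape field because insulin does not extend
beyond the islet. Per-pixel Gaussian background noise is added and the
result clamped to 0-255. The default levels (background ~8-10, foreground
~185-190, SDs 4-14) give the clean separation of well-stained slides;
autofluorescence texture, vasculature and lobular heterogeneity are
deliberately not modelled, so passing recovery tests demonstrate pipeline
correctness, not robustness to poor staining.

# Detection and classification

**Nuclei.** The nuclear channel is smoothed (sigma 1.5 um), thresholded
(triangle method by default - the histogram-elbow rule suited to
dominant-background fluorescence), and connected components are labelled.
Touching nuclei are split by seeding at local maxima of the smoothed
intensity within a 2.5 um window and assigning each foreground pixel to
its nearest seed; at realistic densities thresholded blobs merge across
the smoothing skirt, where distance-transform maxima disappear but
intensity maxima remain one-per-nucleus. Detections outside 10-400 um2
are discarded; survivors are renumbered in raster order, making the output
deterministic.

**Expansion.** Each nucleus is dilated by 5 um (a standard whole-cell
approximation), implemented as a threshold on the exact Euclidean
nearest-seed distance transform, with contested territory assigned to the
nearer nucleus boundary so cell interiors are disjoint.

**Features and calls.** Mean intensities are measured per channel over
nucleus, cell and cytoplasm (cell minus nucleus; empty cytoplasm is
missing). The classifier is either a fixed threshold per marker on the
whole-cell mean - used throughout the recovery runs, at the midpoint
between the generator's background (for insulin: islet-fill) and
foreground levels - or a seeded random forest (50 trees, depth <= 8) over
all compartment features, mirroring the "random trees" object classifiers
of the emulated workflow. Per-channel minimum-intensity floors (the 99.5th
percentile of pixels farther than 5 um from any nucleus) veto positive
calls in empty tissue. A single HLA-II classifier stands for "highly
expressed HLA-II"; no separate high tier is modelled because the emulated
methods describe one classifier per signal.

# Region geometry

All region arithmetic is raster-based on the native 0.325 um pixel grid.
No vector-geometry engine is used: buffering, nearest-boundary
partitioning and band construction all derive from one exact Euclidean
nearest-seed distance transform (a Danielsson vector transform implemented
in C++), which is both faster at whole-slide scale and closer in spirit to
the pixel-classifier heritage of the emulated tool. A raster boundary
convention is needed: the continuous region boundary runs a fixed 0.25 px
outside the outermost in-region pixel centres (the mean gap between a
smooth curve and the nearest interior pixel centre on this grid), and all
distance-band cuts subtract that offset. With it, pixel-counted areas of
discs, annuli and dilations match the analytic values to ~0.3\%,
comfortably inside the 1\% the geometry tests demand. Region areas are
pixel counts times pixel area; exported GeoJSON polygons are traced
contours, so the area attribute is authoritative and the polygon is a
visual aid.

**ICI segmentation.** The insulin channel is smoothed (sigma 2 um) and
thresholded with the triangle rule, followed by a refinement that re-cuts
halfway between the background level and the diffuse islet-fill level
(estimated as the lower quartile of the pre-mask). The triangle threshold
alone sits at the background elbow and dilates every islet by the
smoothing skirt (~2.5 um, enough to sink the 0.90 IoU contract on small
islets); the half-height refinement centres the boundary on the smoothed
edge. A minimum-contrast guard (fill at least 8 grey levels above
background) declares insulin-free sections islet-free instead of
thresholding noise. The mask is then morphologically closed (radius 5 um),
hole-filled, and components below 1,000 um2 are dropped. IDIs come from
GeoJSON annotations (classification `Islet-IDI`) and may not overlap an
ICI.

**Collars and rings.** The peri-islet region of an islet is the tissue
within 10 um of its boundary, outside all islets; ring $k$ covers
$((k-1)\,25, k\,25]$ um. Between neighbouring islets territory belongs to
the islet whose boundary is nearer (exact ties follow the deterministic
scan order of the distance transform; they are a measure-zero pixel set),
so each family is pairwise disjoint and nothing is double-counted - the
choice matters because naive expansions overlap between adjacent islets
and would inflate peri-islet percentages. Rings exclude all islet
interiors, not just the parent's: a cell inside another islet is an islet
cell. Everything is clipped to the tissue rectangle.

**Exocrine squares.** Axis-aligned squares (published design: 15 of
500 um) are placed uniformly at random, rejecting any square within the
peri-islet buffer of an islet boundary, containing islet tissue, leaving
the tissue, or overlapping an accepted square. Outer rings may cross
exocrine squares by design - the two analyses are independent passes.

**Assignment.** A cell joins a region when its nucleus centroid lies in
the region's closed footprint; a centroid exactly on a ring's outer edge
belongs to that ring. Families overlap (the collar lies inside ring 1), so
a cell can hold one membership per family.

# Quantification and statistics

Per region: area, cell count, and for each marker and composite the count,
percentage (missing - not zero - when a region holds no cells, matching
per-islet dot-plot conventions where an empty region contributes no
observation) and density per mm2. Density maps bin CD68+ centroids on a
50 um grid, convert to per-mm2, and smooth with a 100 um Gaussian; with
zero bandwidth the map conserves mass exactly.

The statistics battery follows the published decision rules: Shapiro-Wilk
per group at alpha = 0.05 (groups above Shapiro's 5,000-value limit are
gated on a deterministic order-statistic subsample); all-normal routes to
one-way ANOVA with Tukey HSD, otherwise Kruskal-Wallis with Dunn z-tests
(Bonferroni-adjusted, capped at 1). The Kruskal-Wallis p-value is exact -
full enumeration over partitions of the observations into the observed
group sizes - whenever the enumeration is small (<= 300,000 partitions),
and chi-square otherwise. The ring profile uses a fixed-effects two-way
ANOVA with interaction and partial (Type III) sums of squares, since
region counts per group are never balanced, with Tukey-adjusted pairwise
contrasts from estimated marginal means; terms with zero sum of squares
report F = 0, and a zero-residual fit falls back to a direct
model-matrix decomposition. Spearman's rho is the Pearson correlation of
average ranks; its confidence interval uses the Fisher z-transform with
$SE = \sqrt{1.06/(n-3)}$ (the standard closed form for rank correlations;
the emulated study does not state its CI method) and the p-value the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation. Per-region observations
are pooled across donors within group, replicating the emulated design
as-is; donor-clustered inference is intentionally out of scope.

# Reproducibility and problem sizes

One experiment seed expands into per-stage and per-donor child seeds by a
multiplicative congruential step, so donor simulations never share a
stream; reruns with the same configuration produce bit-identical images,
tables and artefact hashes (verified in the test suite). The recovery runs
use desk-scale sections chosen so every pooled estimate has a standard
error several times smaller than its tolerance: one 1.65 mm section
(~20,000 cells) for whole-tissue recovery, and single 2.2 mm sections
packed with 200 small ICIs (radius 22-42 um) for the zone profiles -
real sections are far larger but carry the same per-islet information, and
packing many islets into one image is what makes a 200-islet pool
tractable on one CPU. The activated-macrophage share (t7) pools the
peri-islet macrophages of both 200-islet sections to halve its binomial
error.

# Known limitations

* The generator's intensity model is clean by design; no attempt is made
  to emulate autofluorescence, staining gradients or section artefacts,
  so recovery results bound pipeline correctness, not robustness.
* Ring/peri territory partitioning and tissue clipping are explicit
  choices; the emulated study does not state how (or whether) it resolved
  overlapping expansions between adjacent islets.
* The z-stack best-focus flattening of the emulated acquisition precedes
  this pipeline; inputs are single-plane.
* Hotspot reading of density maps stays visual; no automated hotspot
  calling is provided.
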