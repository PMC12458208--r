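# isletrings

Spatial quantification of macrophage infiltration around pancreatic islets
in multiplex immunofluorescence (mIF) whole-slide images.

In human type 1 diabetes, macrophages (CD68+ cells) accumulate in and
around the islets of Langerhans, and the activated subset additionally
expresses HLA class II. Quantifying that accumulation requires more than a
whole-tissue cell count: the signal lives in *where* the macrophages sit
relative to each islet boundary. `isletrings` implements the complete
analysis for 4-channel sections (Hoechst/DAPI, insulin, CD68, HLA-II):

* **Cell detection** from the nuclear channel (smoothing, triangle
  threshold, intensity-maxima splitting of touching nuclei), 5 µm
  whole-cell expansion clipped between neighbours, and per-compartment
  intensity features.
* **Marker classification** per cell — fixed thresholds or seeded random
  forests — with channel floors and composite calls
  (CD68+HLA-II+, insulin+HLA-II+).
* **Region geometry**: insulin-containing islets (ICIs) segmented from
  the insulin channel, insulin-deficient islets (IDIs) from GeoJSON
  annotations, a 10 µm peri-islet collar, eight concentric 25 µm rings
  out to 200 µm (territory between neighbouring islets split at the
  equidistant frontier), and randomly sampled exocrine squares.
* **Quantification**: per-region counts, percentages and densities per
  mm², plus smoothed macrophage density maps, for every region of the
  collar family: with ring index $k$ and ring width $w$, ring $k$ of an
  islet covers distances $((k-1)w,\,kw]$ from its boundary.
* **Group statistics**: descriptive summaries; Shapiro–Wilk-gated one-way
  ANOVA + Tukey HSD or Kruskal–Wallis + Dunn (exact permutation p for
  small samples); two-way group x ring ANOVA (Type III); Spearman
  correlation with a Fisher-z 95% CI, $SE = \sqrt{1.06/(n-3)}$.

Because the tissue collections this analysis targets are not publicly
available, the package includes a first-class **synthetic tissue
generator** (`generateTissue()`) with exact ground truth: star-shaped
islets, hard-core cell placement at realistic density, zone-wise CD68+
fractions, and per-islet HLA-II co-expression drawn from a Gaussian
copula with exact Spearman control
($\rho_{\text{latent}} = 2\sin(\pi\rho_S/6)$). Every quantitative claim
about the pipeline is tested as parameter recovery against that ground
truth.

## Worked example

Simulate a 0.6 mm section with three ICIs, run the full pipeline, and pool
the zone percentages:

```r
library(isletrings)

cfg <- tissueConfig(imageSizePx = c(1846, 1846), nIslets = 3,
                    isletRadiusUmRange = c(30, 45), seed = 42)
gen <- generateTissue(cfg)
gen$truth
#> GroundTruthTissue: 1592 cells (171 CD68+, 71 beta), 3 islets (3 ICI)

cells <- detectCells(gen$stack)
cells
#> CellSet: 1592 cells, expanded, 0.325 um/px

model <- midpointClassifier(cfg, calibrateChannelFloors(gen$stack, cells))
calls <- classifyCells(cells, model)

seg <- segmentIslets(gen$stack)
rs  <- buildRegionSet(seg$labels, rep("islet_ICI", nrow(seg$table)),
                      gen$truth@tissueRect, pixelSize(gen$stack))
rs  <- addTissueRegion(makeRingSet(makePeriIslet(rs)))
st  <- regionStats(assignCells(cells, rs), calls, rs)

matchToTruth(cells, gen$truth)$f1
#> [1] 1
```

Pooling `st` over region classes prints

```
pooled %CD68+: islet 5.8 | peri-islet 8.5 | ring 1 13.6 | whole tissue 10.1
```

every detected cell matched a true cell (F1 = 1), and the pooled ring-1
percentage recovers the configured 13.6% exactly at this seed; the islet
and peri-islet values scatter around their configured 6.2% / 13.6% with
the binomial error expected from a single small section (a few hundred
cells per zone). `runPipeline()` wraps these stages, writes every artefact
(OME-TIFF, CSV, GeoJSON, density TIFF) with a hashed JSON manifest, and
`runGroupExperiment()` simulates multi-donor disease groups
(`groupPreset("t1d_ici")`, `"t1d_idi"`, `"aab_pos"`, `"non_diabetic"`) and
runs the statistics battery on the pooled observations.

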