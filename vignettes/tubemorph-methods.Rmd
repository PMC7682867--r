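---
title: "Quantifying epithelial-to-mesenchymal transformation of neural tube cells in 3D: methods and design notes"
author: "tubemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tubemorph methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Oncogenic transcription factors such as PAX3-FOXO1 can push embryonic neural
tube cells out of their epithelial state: nuclei round up, lose their
medial-lateral alignment, detach from the apical surface, migrate beyond the
tube boundary into adjacent tissue, regroup into dense clusters, and slow
their progression through the cell cycle. `tubemorph` implements the
quantitative read-outs with which such a transformation is scored in
3D-imaged chick embryos:

* **nuclear shape** — prolate/oblate ellipticity and sphericity from a
  moment-based ellipsoid fit of each segmented nucleus;
* **nuclear orientation** — polar angles of the fitted major axis in the
  embryo frame (θ against the dorso-ventral axis, φ within the
  medial-lateral / antero-posterior plane);
* **migration** — distance of each nucleus centre to the apical surface
  (lumen) and the fraction of GFP+ (electroporated) nuclei whose centres lie
  outside the neural tube;
* **cohesion** — DBSCAN clustering of cell centres (radius 10 µm, minimum 3
  cells) and an exponential model of the cluster-size distribution;
* **proliferation** — marker-positive fractions among GFP+ cells (e.g. an
  EdU-like S-phase label) and Dean–Jett–Fox deconvolution of univariate
  DNA-content histograms into G0/G1, S and G2/M fractions.

Because raw embryo microscopy is not redistributable, the package ships a
first-class synthetic generator (`generatePhantom()`, `simulateDnaEvents()`)
that renders embryo-like volumes with known ground truth, so that every
stage of the pipeline is tested against constructions whose answer is known.

## The embryo phantom

### Geometry

The neural tube is modelled as a solid half-cylinder whose axis runs along
the antero-posterior (y) axis; the flat medial face carries a thin slit —
the apical cavity (lumen). Everything outside the half-cylinder stands in
for adjacent (mesodermal) tissue. This is the minimal geometry that supports
every downstream measurement: a non-trivial distance transform to the
apical surface, and a binary in-tube / emigrated compartment call. The
default frame samples at 0.5 µm isotropic voxels, a confocal-like
resolution at which a (2, 2, 3) µm nucleus spans roughly 400 voxels —
comfortably above the 95-voxel quality filter — while debris stays below
it.

### Tissue states

* **Epithelial** (control-like): nuclei with semi-axes (2, 2, 3) µm, major
  axes drawn by rotating the medial-lateral axis about a uniformly random
  axis by |N(0, 5°)|, all centres inside the tube. Centres are placed by
  random sequential adsorption with a minimum spacing of 10.5 µm. That
  spacing was fixed once, just above the 10 µm clustering radius, so that a
  control tissue contains *no* density clusters by construction — the
  pseudostratified packing density of a real epithelium is deliberately not
  reproduced, and positive cluster counts in controls would be phantom
  artefacts, not biology.
* **Mesenchymal** (transformed): rounder nuclei (default semi-axes
  2.4, 2.4, 2.7 µm), orientations uniform on the sphere, each nucleus
  emigrating beyond the tube with probability `emigrationProb` (the flags
  are the *first* draws from the seeded RNG stream, so they can be replayed
  independently), and ~30% of in-tube nuclei grouped into seeded clusters
  of ~6 members whose consecutive spacing lies between the geometric
  non-touching floor (2·c + 1 µm) and 9.5 µm — below the 10 µm DBSCAN
  radius.

### Rendering

Nuclei are rendered as solid ellipsoids (DNA channel everywhere; GFP and
marker channels only inside flagged nuclei), then the stack is smoothed
with a Gaussian of σ = 0.25 µm (half a voxel; the scale of a confocal
point-spread function), scaled by a per-slice attenuation factor, and
corrupted with additive Gaussian noise before clipping to the [0, 1]
dynamic range. Debris alternates between small bright specks and larger
particles rendered far above the dynamic range, whose clipped cores stay
saturated after the blur — the two populations that the size and
saturation arms of the quality filter are meant to remove. The rendered
size of every debris blob stays below 95 voxels.

What the phantom does *not* emulate: realistic epithelial packing density
(see above), textured chromatin, anisotropic axial PSF, spectral bleed
between channels, and partial nuclear overlaps in crowded tissue. Passing
phantom tests therefore demonstrates the correctness of the measurement
chain, not robustness to every real-microscopy artefact.

## The measurement chain

`measureNuclei()` runs the full chain and is the single entry point used by
the pipeline, the tests and the acceptance script.

1. **Bleach correction** (`bleachCorrect`): every z-slice is multiplied by
   (top-slice mean / its own mean), equalising per-slice means along tissue
   depth. Segmentation runs on the corrected DNA channel, but per-object
   intensity statistics are taken from the *raw* channel — saturation must
   be judged on acquisition values, and the slice gains would otherwise pull
   clipped voxels below the saturation level.
2. **Background subtraction** (`subtractBackground`): morphological top-hat
   on the GFP channel with a ball of 4 µm (larger than a nucleus radius),
   removing slowly varying autofluorescence. The grey-scale ball
   erosion/dilation is computed exactly by decomposing the ball into
   x-segments and sharing van Herk 1D min/max passes across offsets of
   equal segment length.
3. **Segmentation** (`segmentNuclei`): Otsu threshold computed on the full
   3D histogram; exact Euclidean distance transform (Felzenszwalb
   lower-envelope algorithm, anisotropy-aware) of the foreground; seeds =
   distance-transform local maxima greedily thinned to a minimum separation
   of 5 µm (below the 10.5 µm nucleus spacing, above the ~4 µm maxima
   spread inside one nucleus); seeded watershed by priority flood with
   deterministic tie-breaking. Foreground components without seeds get
   fresh labels and are left to the quality filter.
4. **Quality filter** (`qualityFilter`): removes objects with fewer than 95
   voxels (strictly — an object of exactly 95 voxels is kept) or with more
   than 50% of DNA-channel voxels at or above 0.98 of the dynamic range.
5. **Morphometry** (`fitEllipsoid`, `shapeMetrics`, `orientationAngles`):
   centroid + covariance eigendecomposition; semi-axes √(5λ) (the
   uniform-solid-ellipsoid moment relation — an assumption to keep in mind
   for real chromatin, which is not uniform); Sheppard's correction
   (voxelSize²/12 subtracted from each eigenvalue) removes the grid
   -sampling bias. Prolate ellipticity 2(c−b)/(b+c) and oblate
   2(b−a)/(a+b) on ascending semi-axes a ≤ b ≤ c — the convention under
   which a 2:2:3 control nucleus scores 0.4; sphericity π^⅓(6V)^⅔/A with
   the Knud Thomsen surface-area approximation (p = 1.6075). Orientation
   angles fold the axis to x ≥ 0 (ties: y ≥ 0, then z ≥ 0), giving
   θ ∈ [0°, 180°] and φ ∈ (−90°, 90°], with the control tissue centred on
   θ = 90°, φ = 0°.
6. **Spatial statistics** (`distanceToApical`, `emigrationFraction`,
   `dbscanClusters`, `fitClusterSizeDistribution`,
   `nearestNeighbourDistances`): distances sampled from the exact EDT of
   the cavity complement at each centre's containing voxel; DBSCAN with
   eps = 10 µm and minPts = 3 (a point counts itself), expanded in index
   order. The "minimum of 3 cells" convention is applied twice: as minPts
   *and* as a floor on emitted cluster size, because border-point stealing
   can otherwise emit 2-member artefacts. The cluster-size distribution is
   fitted as % = A·e^(−k·size) by least squares on the log scale with
   zero-percentage classes dropped — the simplest reproducible estimator
   for an exponential-fit figure.

## Cell-cycle deconvolution

`fitDeanJettFox()` models a univariate DNA-content histogram as

> w₁·N(μ₁, σ₁) + w₂·N(μ₂, σ₂) + wₛ·S(x),

where S is a flat compartment on (μ₁, μ₂) convolved with a Gaussian whose
s.d. interpolates σ₁ → σ₂ (evaluated by 64-point quadrature; an optional
second-order polynomial S shape is available via `sPolyOrder = 2`, matching
the original formulation — the flat S is the default because it is exactly
identifiable on the simulator, whose S phase is uniform between 1× and 2×
the G1 mean). Parameters are fitted by bounded Levenberg–Marquardt least
squares on bin counts (unweighted, for determinism; Poisson weighting would
be a natural extension), with the G1 and G2 means manually constrained to
user ranges and σ bounded below by one bin width. Initialisation is
deterministic: μ₁ at the highest-count bin inside the G1 range, μ₂ at
2μ₁ clamped to the G2 range, σ at 5% of the mean, weights from the
histogram mass split at (μ₁+μ₂)/2.

One numerical choice deserves emphasis: before fitting, the histogram
support is extended with *empty* bins across the whole constrained window
(0.6·G1ₗₒ to 1.35·G2ₕᵢ). A pure-G1 sample yields data only around μ₁;
without the empty bins, the G2 and S components can hide outside the
observed support and leak unpenalised tails into it. The empty bins encode
the fact that the instrument recorded no events there, which pins absent
components to zero weight.

Hardware gating (singlets, granularity, GFP) is not modelled; event tables
arrive pre-gated with a GFP flag, as produced by `simulateDnaEvents()`.

## Group statistics

`mannWhitneyU()` reports the rank-sum U of the first group with midrank
ties, an exact two-sided p by full enumeration of the null distribution
when the smaller group has ≤ 8 values and no ties, and a tie-corrected
normal approximation (without continuity correction, for exactness of the
symmetry identities) otherwise. Two-sided throughout. `fractionPositive()`
takes the embryo as the unit of replication for count-based metrics
(per-embryo positive % among GFP+ cells, then mean ± s.e.m. across
embryos); intensity-based metrics are compared at the cell level.

## Orchestration

`runPipeline()` consumes a YAML or list configuration (named conditions,
each a set of `phantomConfig()` arguments plus optional DNA-content
fractions; shared filter/cluster/threshold/DJF settings; one root seed from
which per-condition and per-module substreams are derived) and writes, per
condition: the multi-channel stack and masks as multi-directory TIFF in
C,Z,Y,X order with geometry in a JSON sidecar, ground-truth and measured
nucleus tables, cluster memberships and group comparisons as CSV (floats at
9 significant digits), and a machine-readable JSON summary with every
headline metric. Identical configurations reproduce all outputs bit for
bit; a failing condition is logged and skipped without aborting the others.
The package is driven from R — the exported functions, this vignette and
`scripts/acceptance.R` are the interface; no shell subcommand layer is
shipped.

## Problem sizes and numerical tolerances

The test suite exercises phantoms of 6–300 nuclei and the acceptance
script 200–500 nuclei per condition (volumes of 1–25 million voxels),
DNA-content fits at 20 000 events and 256 bins, and oracle comparisons on
≤ 20³ grids and ≤ 100-point clouds — sizes chosen so that every oracle can
be brute-forced exactly while the rendered volumes remain realistic.
Key tolerances: ellipsoid recovery 5% / 5° against analytic voxelisations;
phase-fraction recovery ±0.03 at 3% CV; mean prolate ellipticity of the
calibration phantom within ±0.05 of the 0.4 control value; distance
transforms exact to floating point against exhaustive search.

## Known limitations

* Segmentation assumes blob-like nuclei; heavily overlapping nuclei beyond
  what the watershed separates are merged.
* The √(5λ) semi-axis estimator is exact for uniform solids only.
* The DBSCAN size floor makes whole-cluster demotion order-dependent in
  rare border-stealing configurations; the partition of core points is
  order-invariant and is what the tests pin down.
* The exponential cluster-size fit needs at least two realised size
  classes and ignores sampling error in the log-linear weighting.
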