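# tubemorph

3D nuclear morphometry, spatial statistics and cell-cycle deconvolution for
quantifying epithelial-to-mesenchymal transformation of embryonic neural
tube cells — with a synthetic embryo-phantom generator so the entire
pipeline is testable without microscope data.

## Who this is for

Developmental and cancer biologists quantifying, from multi-channel 3D
stacks of electroporated (GFP-marked) neural tube tissue, whether an
oncogene such as PAX3-FOXO1 drives cells out of their epithelial state; and
anyone needing the underlying measurements individually: nuclear ellipsoid
fits, orientation in tissue coordinates, distance-to-surface transforms,
DBSCAN cell clustering, or Dean–Jett–Fox DNA-content fitting.

## What it computes

For each segmented nucleus (Otsu threshold → exact 3D Euclidean distance
transform → seeded watershed → size/saturation quality filter that removes
objects under 95 voxels or with > 50% saturated voxels):

* **Shape** — semi-axes a ≤ b ≤ c from the second-moment relation
  (semi-axis = √(5λ), Sheppard-corrected), then

      prolate ellipticity = 2(c − b)/(b + c)
      oblate  ellipticity = 2(b − a)/(a + b)
      sphericity          = π^(1/3) (6V)^(2/3) / A   (Knud Thomsen A)

  Control neural tube nuclei (2:2:3 axis ratio) score a prolate
  ellipticity of 0.4; transformed, rounder nuclei score near 0.
* **Orientation** — the major axis in embryo polar coordinates:
  θ = angle to the dorso-ventral axis, φ = azimuth in the medial-lateral /
  antero-posterior plane; epithelial tissue centres on θ = 90°, φ = 0°.
* **Migration** — micrometre distance from each nucleus centre to the
  apical surface (lumen), and the percentage of GFP+ nuclei outside the
  neural tube mask.
* **Cohesion** — DBSCAN clusters (eps 10 µm, minimum 3 cells) and the
  exponential fit % = A·e^(−k·size) of the cluster-size distribution.
* **Cell cycle** — Dean–Jett–Fox deconvolution of DNA-content histograms
  (two Gaussians plus a broadened S compartment, G1/G2 means constrained to
  user ranges) into G0/G1, S and G2/M fractions.
* **Group statistics** — per-embryo marker-positive percentages among GFP+
  cells and exact/tie-corrected Mann–Whitney U comparisons.

The synthetic generator renders both tissue states (epithelial: elongated,
aligned, confined, regularly spaced; mesenchymal: rounder, randomly
oriented, partly emigrated, with seeded clusters) plus image noise, depth
attenuation and saturated debris, writing the ground truth before
rendering.

## Worked example

```r
library(tubemorph)

cfg <- phantomConfig("epithelial", nNuclei = 50, seed = 1)
ph  <- generatePhantom(cfg)
ph
#> TissuePhantom: epithelial state, 50 nuclei
#>   volume: 88 x 204 x 128 voxels; channels: dna, gfp, edu
#>   voxel size (um): 0.5 x 0.5 x 0.5

mm <- measureNuclei(ph)
nu <- mm$nuclei
nrow(nu)                                      # 50 nuclei kept
mean(nu$prolate)                              # 0.398
median(nu$theta); median(nu$phi)              # 90.3 ; 0.1  (degrees)
mean(nu$distApical)                           # 12.8 um to the lumen
100 * mean(nu$emigrated[nu$gfpPositive])      # 0 % emigrated (control)
100 * mean(nu$eduPositive[nu$gfpPositive])    # 70 % EdU+ (p = 0.75 draw)

ev  <- simulateDnaEvents(20000, c(0.55, 0.35, 0.10), g1Mean = 100,
                         cv = 0.03, seed = 2)
fitDeanJettFox(dnaHistogram(ev), djfConstraints(c(80, 120), c(160, 240)))
#> Dean-Jett-Fox fit: G0/G1 54.6%, S 35.2%, G2/M 10.2%
#>   G1 mean 99.98  G2 mean 200  rss 17300
```

The measured mean prolate ellipticity of 0.398 reproduces the 0.4 of an
elongated 2:2:3 control nucleus; the orientation medians confirm
medial-lateral alignment (θ 90°, φ 0°); no control nucleus leaves the tube;
and the cell-cycle fit recovers the simulated 55/35/10 phase split within a
point.

A full multi-condition run (phantom → segmentation → morphometry → spatial
→ statistics → TIFF/CSV/JSON report) is one call:

```r
runPipeline(list(
  seed = 1, outputDir = "out",
  clusterParams = list(eps = 10, minClusterSize = 3),
  conditions = list(
    control = list(phantom = list(state = "epithelial",  nNuclei = 100),
                   dnaFractions = c(0.55, 0.35, 0.10)),
    fusion  = list(phantom = list(state = "mesenchymal", nNuclei = 100),
                   dnaFractions = c(0.70, 0.20, 0.10)))))
```

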