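#' @import methods
NULL

#' Embryo coordinate frame
#'
#' Fixes the anatomical axes used throughout the package and the mapping
#' between voxel indices and physical coordinates. The first array dimension
#' is the medial-lateral axis (x), the second the antero-posterior axis (y),
#' the third the dorso-ventral axis (z). Physical coordinates follow the
#' voxel-centre convention: `coord = (index - 1) * voxelSize + origin` with
#' 1-based array indices (so 0-based voxel indices in the stated formula).
#'
#' @slot voxelSize numeric(3), micrometres per voxel along (x, y, z);
#'   strictly positive.
#' @slot origin numeric(3), physical coordinate of voxel (1, 1, 1) in
#'   micrometres.
#' @export
setClass("EmbryoFrame",
  representation(voxelSize = "numeric", origin = "numeric"),
  prototype(voxelSize = c(1, 1, 1), origin = c(0, 0, 0)),
  validity = function(object) {
    if (length(object@voxelSize) != 3 || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      return("voxelSize must be three strictly positive values")
    if (length(object@origin) != 3 || any(!is.finite(object@origin)))
      return("origin must be three finite values")
    TRUE
  })

#' Phantom generator configuration
#'
#' Parameters of the synthetic embryo volume: tissue state, number and shape
#' of nuclei, orientation jitter, emigration probability, seeded clusters,
#' marker positivity, imaging artefacts (noise, per-slice attenuation,
#' saturated debris) and the RNG seed. The same configuration and seed always
#' reproduce the identical ground-truth table and image.
#'
#' @slot state `"epithelial"` or `"mesenchymal"`.
#' @slot nNuclei integer, number of nuclei to place.
#' @slot semiAxes numeric(3), ground-truth ellipsoid semi-axes (a, b, c) in
#'   micrometres, ascending.
#' @slot orientationNoiseDeg numeric, s.d. of the angular jitter around the
#'   medial-lateral axis (epithelial state only).
#' @slot emigrationProb numeric, probability that a nucleus is placed outside
#'   the neural tube (mesenchymal state only).
#' @slot clusterSpec list with `nClusters`, `fraction` (fraction of in-tube
#'   nuclei placed into seeded clusters) and `radius` (member spacing bound,
#'   micrometres); mesenchymal state only.
#' @slot markerProbs named numeric, per-channel positivity probability among
#'   GFP+ nuclei (e.g. `c(edu = 0.75)`).
#' @slot gfpProb numeric, probability a nucleus is GFP+ (electroporated).
#' @slot noiseSd numeric, s.d. of additive Gaussian image noise.
#' @slot attenuationPerSlice numeric, multiplicative intensity decay per
#'   z-slice (1 = none).
#' @slot nDebris integer, number of small saturated debris blobs.
#' @slot minSpacing numeric, minimum centre-to-centre spacing in micrometres.
#' @slot volumeDim integer(3) voxel dimensions, or NA to size automatically
#'   from `nNuclei` and `minSpacing`.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomConfig",
  representation(state = "character", nNuclei = "integer",
    semiAxes = "numeric", orientationNoiseDeg = "numeric",
    emigrationProb = "numeric", clusterSpec = "list",
    markerProbs = "numeric", gfpProb = "numeric", noiseSd = "numeric",
    attenuationPerSlice = "numeric", nDebris = "integer",
    minSpacing = "numeric", volumeDim = "integer", seed = "integer"),
  validity = function(object) {
    if (!object@state %in% c("epithelial", "mesenchymal"))
      return("state must be 'epithelial' or 'mesenchymal'")
    if (object@nNuclei < 0) return("nNuclei must be >= 0")
    if (length(object@semiAxes) != 3 || any(object@semiAxes <= 0))
      return("semiAxes must be three positive values")
    if (is.unsorted(object@semiAxes))
      return("semiAxes must be ascending (a <= b <= c)")
    probs <- c(object@emigrationProb, object@gfpProb, object@markerProbs)
    if (any(probs < 0 | probs > 1))
      return("all probabilities must lie in [0, 1]")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@attenuationPerSlice <= 0 || object@attenuationPerSlice > 1)
      return("attenuationPerSlice must lie in (0, 1]")
    if (object@nDebris < 0) return("nDebris must be >= 0")
    if (object@minSpacing <= 0) return("minSpacing must be > 0")
    fr <- object@clusterSpec$fraction
    if (!is.null(fr) && (fr < 0 || fr > 1))
      return("clusterSpec$fraction must lie in [0, 1]")
    TRUE
  })

#' Synthetic embryo volume with ground truth
#'
#' A rendered multi-channel voxel stack (named channels, at least `dna` and
#' `gfp`), the neural-tube and apical-cavity masks, the coordinate frame, the
#' ground-truth nucleus table, and the generating configuration.
#'
#' @slot channels named list of 3D numeric arrays (x, y, z order).
#' @slot tubeMask,cavityMask logical 3D arrays.
#' @slot frame an [EmbryoFrame-class].
#' @slot truth data.frame, one row per ground-truth nucleus (centre, semi-axes,
#'   major axis, compartment, GFP and marker flags, seeded cluster id).
#' @slot config the generating [PhantomConfig-class].
#' @export
setClass("TissuePhantom",
  representation(channels = "list", tubeMask = "array", cavityMask = "array",
    frame = "EmbryoFrame", truth = "data.frame", config = "PhantomConfig"),
  validity = function(object) {
    if (nrow(object@truth) != object@config@nNuclei)
      return("truth table must have one row per configured nucleus")
    if (length(object@channels) &&
        !all(vapply(object@channels, function(ch)
          identical(dim(ch), dim(object@tubeMask)), logical(1))))
      return("all channels must share the mask dimensions")
    TRUE
  })

#' Nucleus segmentation result
#'
#' Integer label volume (0 = background), per-object voxel index lists and a
#' per-object statistics table (voxel count, centroid in micrometres, and
#' per-channel mean / max intensity and saturated-voxel fraction).
#'
#' @slot labelVolume integer 3D array.
#' @slot objects data.frame with columns `label`, `nVoxels`, `x`, `y`, `z`
#'   and `mean_<channel>`, `max_<channel>`, `satFrac_<channel>`.
#' @slot voxelIndices list of integer vectors (linear indices) per object.
#' @slot frame an [EmbryoFrame-class].
#' @export
setClass("SegmentationResult",
  representation(labelVolume = "array", objects = "data.frame",
    voxelIndices = "list", frame = "EmbryoFrame"),
  validity = function(object) {
    if (nrow(object@objects) != length(object@voxelIndices))
      return("objects table and voxelIndices must have equal length")
    if (nrow(object@objects) &&
        !all(object@objects$nVoxels ==
             lengths(object@voxelIndices)))
      return("nVoxels must equal the length of each voxel list")
    TRUE
  })

#' Quality-filter parameters
#'
#' Objects smaller than `minVoxels` voxels (strictly) or with a saturated-voxel
#' fraction above `maxSaturatedFraction` are removed; objects with exactly
#' `minVoxels` voxels are kept.
#'
#' @slot minVoxels integer, minimum object size in voxels (default 95).
#' @slot maxSaturatedFraction numeric in \[0, 1\] (default 0.5).
#' @export
setClass("QualityFilterParams",
  representation(minVoxels = "integer", maxSaturatedFraction = "numeric"),
  prototype(minVoxels = 95L, maxSaturatedFraction = 0.5),
  validity = function(object) {
    if (object@minVoxels < 1) return("minVoxels must be >= 1")
    if (object@maxSaturatedFraction < 0 || object@maxSaturatedFraction > 1)
      return("maxSaturatedFraction must lie in [0, 1]")
    TRUE
  })

#' Moment-based ellipsoid fit of a nucleus
#'
#' @slot centre numeric(3), centroid in micrometres.
#' @slot semiAxes numeric(3), ascending (a <= b <= c), micrometres.
#' @slot principalAxes 3x3 matrix, columns = unit minor, middle, major axes;
#'   orthonormal within 1e-6.
#' @export
setClass("EllipsoidFit",
  representation(centre = "numeric", semiAxes = "numeric",
    principalAxes = "matrix"),
  validity = function(object) {
    if (any(object@semiAxes <= 0)) return("semi-axes must be positive")
    if (is.unsorted(object@semiAxes)) return("semi-axes must be ascending")
    g <- crossprod(object@principalAxes)
    if (max(abs(g - diag(3))) > 1e-6)
      return("principal axes must be orthonormal within 1e-6")
    TRUE
  })

#' DBSCAN parameters
#'
#' Neighbourhood radius and minimum cluster size, following the convention
#' that a cluster contains at least `minClusterSize` cells and that two cells
#' of the same cluster are at most `eps` micrometres apart; `minClusterSize`
#' doubles as the DBSCAN minPts (a point counts itself).
#'
#' @slot eps numeric, micrometres (default 10).
#' @slot minClusterSize integer (default 3).
#' @export
setClass("ClusterParams",
  representation(eps = "numeric", minClusterSize = "integer"),
  prototype(eps = 10, minClusterSize = 3L),
  validity = function(object) {
    if (object@eps <= 0) return("eps must be > 0")
    if (object@minClusterSize < 1) return("minClusterSize must be >= 1")
    TRUE
  })

#' DBSCAN clustering result
#'
#' @slot labels integer per-point cluster id, 0 = noise.
#' @slot sizes integer member count per cluster (cluster k at position k).
#' @slot sizeDistribution data.frame with `size` and `pct` (percent of
#'   clusters in each realised size class; sums to 100).
#' @slot params the [ClusterParams-class] used.
#' @export
setClass("ClusterResult",
  representation(labels = "integer", sizes = "integer",
    sizeDistribution = "data.frame", params = "ClusterParams"),
  validity = function(object) {
    if (length(object@sizes) &&
        any(object@sizes < object@params@minClusterSize))
      return("every emitted cluster must reach minClusterSize")
    if (nrow(object@sizeDistribution) &&
        abs(sum(object@sizeDistribution$pct) - 100) > 1e-6)
      return("size distribution percentages must sum to 100")
    TRUE
  })

#' Univariate DNA-content histogram
#'
#' @slot binEdges numeric, fluorescence a.u., length = bins + 1.
#' @slot counts numeric events per bin, non-negative.
#' @slot nEvents integer total.
#' @export
setClass("DnaHistogram",
  representation(binEdges = "numeric", counts = "numeric",
    nEvents = "integer"),
  validity = function(object) {
    if (length(object@binEdges) != length(object@counts) + 1)
      return("binEdges must have one more element than counts")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (abs(sum(object@counts) - object@nEvents) > 1e-9)
      return("counts must sum to nEvents")
    TRUE
  })

#' G1/G2 mean constraints for the Dean-Jett-Fox fit
#'
#' The ranges inside which the G0/G1 and G2/M peak means are allowed to move,
#' mirroring the manual constraining of both peaks during model optimisation.
#'
#' @slot g1Range,g2Range numeric(2), (lo, hi) in fluorescence a.u.; g2Range
#'   must lie entirely above g1Range.
#' @export
setClass("DjfConstraints",
  representation(g1Range = "numeric", g2Range = "numeric"),
  validity = function(object) {
    if (object@g1Range[1] >= object@g1Range[2]) return("g1Range: lo < hi")
    if (object@g2Range[1] >= object@g2Range[2]) return("g2Range: lo < hi")
    if (object@g2Range[1] <= object@g1Range[2])
      return("g2Range must lie above g1Range")
    TRUE
  })

#' Dean-Jett-Fox fit result
#'
#' @slot g1,g2 named numeric (mean, sd, weight); weights are the normalised
#'   phase fractions.
#' @slot sWeight numeric, S-phase fraction.
#' @slot phaseFractions named numeric (g1, s, g2m), summing to 1.
#' @slot fittedCurve numeric model counts per histogram bin.
#' @slot rss numeric residual sum of squares.
#' @export
setClass("DjfFit",
  representation(g1 = "numeric", g2 = "numeric", sWeight = "numeric",
    phaseFractions = "numeric", fittedCurve = "numeric", rss = "numeric"),
  validity = function(object) {
    fr <- object@phaseFractions
    if (any(fr < -1e-9 | fr > 1 + 1e-9)) return("fractions must lie in [0,1]")
    if (abs(sum(fr) - 1) > 1e-9) return("fractions must sum to 1")
    if (object@g1[["mean"]] >= object@g2[["mean"]])
      return("G1 mean must be below G2 mean")
    TRUE
  })
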