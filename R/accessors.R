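# Accessors and show methods for the S4 containers.

#' @rdname TissuePhantom-class
#' @aliases truthTable,TissuePhantom-method
#' @param x,object a `TissuePhantom`.
#' @param channel channel name, e.g. `"dna"`.
#' @export
setMethod("truthTable", "TissuePhantom", function(x) x@truth)

#' @rdname TissuePhantom-class
#' @export
setMethod("imageChannel", "TissuePhantom", function(x, channel) {
  if (!channel %in% names(x@channels))
    stop("unknown channel '", channel, "'; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[channel]]
})

#' @rdname TissuePhantom-class
#' @export
setMethod("channelNames", "TissuePhantom", function(x) names(x@channels))

#' @rdname TissuePhantom-class
#' @export
setMethod("tubeMask", "TissuePhantom", function(x) x@tubeMask)

#' @rdname TissuePhantom-class
#' @export
setMethod("cavityMask", "TissuePhantom", function(x) x@cavityMask)

#' @rdname TissuePhantom-class
#' @export
setMethod("embryoFrameOf", "TissuePhantom", function(x) x@frame)

#' @rdname TissuePhantom-class
#' @export
setMethod("show", "TissuePhantom", function(object) {
  d <- dim(object@tubeMask)
  cat("TissuePhantom:", object@config@state, "state,",
      nrow(object@truth), "nuclei\n")
  cat("  volume:", paste(d, collapse = " x "), "voxels; channels:",
      paste(names(object@channels), collapse = ", "), "\n")
  cat("  voxel size (um):",
      paste(object@frame@voxelSize, collapse = " x "), "\n")
})

#' @rdname SegmentationResult-class
#' @aliases objectTable,SegmentationResult-method
#' @param x,object a `SegmentationResult`.
#' @export
setMethod("objectTable", "SegmentationResult", function(x) x@objects)

#' @rdname SegmentationResult-class
#' @export
setMethod("labelVolume", "SegmentationResult", function(x) x@labelVolume)

#' @rdname SegmentationResult-class
#' @export
setMethod("voxelIndices", "SegmentationResult", function(x) x@voxelIndices)

#' @rdname SegmentationResult-class
#' @export
setMethod("nObjects", "SegmentationResult", function(x) nrow(x@objects))

#' @rdname SegmentationResult-class
#' @export
setMethod("embryoFrameOf", "SegmentationResult", function(x) x@frame)

#' @rdname SegmentationResult-class
#' @export
setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult:", nrow(object@objects), "objects in a",
      paste(dim(object@labelVolume), collapse = " x "), "volume\n")
})

#' @rdname EllipsoidFit-class
#' @aliases semiAxes,EllipsoidFit-method
#' @param x,object an `EllipsoidFit`.
#' @export
setMethod("semiAxes", "EllipsoidFit", function(x) x@semiAxes)

#' @rdname EllipsoidFit-class
#' @export
setMethod("principalAxes", "EllipsoidFit", function(x) x@principalAxes)

#' @rdname EllipsoidFit-class
#' @export
setMethod("majorAxis", "EllipsoidFit", function(x) x@principalAxes[, 3])

#' @rdname EllipsoidFit-class
#' @export
setMethod("centre", "EllipsoidFit", function(x) x@centre)

#' @rdname EllipsoidFit-class
#' @export
setMethod("show", "EllipsoidFit", function(object) {
  cat("EllipsoidFit: semi-axes (um)",
      paste(signif(object@semiAxes, 4), collapse = ", "),
      "at centre", paste(signif(object@centre, 4), collapse = ", "), "\n")
})

#' @rdname ClusterResult-class
#' @aliases clusterLabels,ClusterResult-method
#' @param x,object a `ClusterResult`.
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterSizes", "ClusterResult", function(x) x@sizes)

#' @rdname ClusterResult-class
#' @export
setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@sizes), "clusters,",
      sum(object@labels == 0L), "noise points (eps =", object@params@eps,
      "um, min size =", object@params@minClusterSize, ")\n")
})

#' @rdname DjfFit-class
#' @aliases phaseFractions,DjfFit-method
#' @param x,object a `DjfFit`.
#' @export
setMethod("phaseFractions", "DjfFit", function(x) x@phaseFractions)

#' @rdname DjfFit-class
#' @export
setMethod("show", "DjfFit", function(object) {
  fr <- round(100 * object@phaseFractions, 1)
  cat("Dean-Jett-Fox fit: G0/G1", paste0(fr[["g1"]], "%,"),
      "S", paste0(fr[["s"]], "%,"), "G2/M", paste0(fr[["g2m"]], "%\n"))
  cat("  G1 mean", signif(object@g1[["mean"]], 4),
      " G2 mean", signif(object@g2[["mean"]], 4),
      " rss", signif(object@rss, 4), "\n")
})
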