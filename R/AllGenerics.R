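#' @describeIn TissuePhantom-class number of ground-truth nuclei.
#' @param x,object an object of the documented class.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @export
setGeneric("imageChannel", function(x, channel) standardGeneric("imageChannel"))

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setGeneric("tubeMask", function(x) standardGeneric("tubeMask"))

#' @export
setGeneric("cavityMask", function(x) standardGeneric("cavityMask"))

#' @export
setGeneric("embryoFrameOf", function(x) standardGeneric("embryoFrameOf"))

#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))

#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))

#' @export
setGeneric("voxelIndices", function(x) standardGeneric("voxelIndices"))

#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @export
setGeneric("phaseFractions", function(x) standardGeneric("phaseFractions"))

#' @export
setGeneric("semiAxes", function(x) standardGeneric("semiAxes"))

#' @export
setGeneric("principalAxes", function(x) standardGeneric("principalAxes"))

#' @export
setGeneric("majorAxis", function(x) standardGeneric("majorAxis"))

#' @export
setGeneric("centre", function(x) standardGeneric("centre"))
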