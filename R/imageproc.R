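#' Subtract image background by morphological top-hat
#'
#' Removes slowly varying background (e.g. tissue autofluorescence in the
#' GFP channel) as `image - opening(image, ball(radius))`. The structuring
#' element must be larger than a nucleus so that nuclei survive the opening
#' and are therefore preserved by the subtraction.
#'
#' @param image 3D numeric array.
#' @param radius ball radius in micrometres; must span at least one voxel.
#' @param frame an [EmbryoFrame-class] giving the voxel size.
#' @return 3D array, non-negative.
#' @examples
#' x <- array(0.2, c(8, 8, 4))
#' max(abs(subtractBackground(x, 2, embryoFrame())))  # flat background -> 0
#' @export
subtractBackground <- function(image, radius, frame = embryoFrame()) {
  if (radius <= 0) stop("radius must be > 0")
  radVox <- radius / frame@voxelSize
  if (all(radVox < 1))
    stop("radius ", radius, " um is smaller than one voxel")
  dims <- dim(image)
  er <- .morphBall3d(as.numeric(image), as.integer(dims),
                     as.numeric(radVox), 0L)
  op <- .morphBall3d(as.numeric(er), as.integer(dims),
                     as.numeric(radVox), 1L)
  out <- pmax(image - array(op, dims), 0)
  dim(out) <- dims
  out
}

#' Correct depth-dependent intensity attenuation
#'
#' Normalises the brightness of the stack along tissue thickness: every
#' z-slice is multiplied by (mean of the reference slice) / (its own mean),
#' with the top (first) slice as reference, so per-slice means become equal.
#' A single-slice stack is returned unchanged.
#'
#' @param image 3D numeric array.
#' @return 3D array with equal per-slice means.
#' @examples
#' x <- array(rep(c(1, 0.9, 0.81), each = 16), c(4, 4, 3))
#' apply(bleachCorrect(x), 3, mean)
#' @export
bleachCorrect <- function(image) {
  dims <- dim(image)
  if (length(dims) != 3) stop("image must be a 3D array")
  if (dims[3] == 1) return(image)
  m <- apply(image, 3, mean)
  zero <- which(m == 0)
  if (length(zero))
    stop("cannot bleach-correct: slice ", zero[1], " has zero mean")
  sweep(image, 3, m[1] / m, "*")
}

#' Segment nuclei in a DNA-stain channel
#'
#' Foreground by Otsu threshold, then touching nuclei are split by a seeded
#' watershed on the negated Euclidean distance transform: seeds are the
#' distance-transform local maxima, greedily thinned so that accepted seeds
#' are at least `minSeedDistance` apart (micrometres). Foreground components
#' left without a seed receive their own labels. Per-object statistics are
#' computed over every supplied channel. Anisotropic voxel sizes are
#' honoured by the physical-distance transform.
#'
#' @param channels named list of 3D arrays; must contain `dna`, the DNA
#'   stain used for object statistics. May be a [TissuePhantom-class],
#'   whose channels and frame are then used.
#' @param frame an [EmbryoFrame-class]; ignored when `channels` is a
#'   phantom.
#' @param minSeedDistance minimum seed separation, micrometres.
#' @param satLevel intensity at or above which a voxel counts as saturated
#'   (dynamic range 0-1). Saturation must be judged on raw acquisition
#'   values, so when thresholding a preprocessed copy, supply it as a
#'   separate channel via `segChannel` and keep `dna` raw.
#' @param segChannel name of the channel to threshold and watershed
#'   (default `dna`).
#' @return a [SegmentationResult-class]; empty (0 objects) for a blank image.
#' @export
segmentNuclei <- function(channels, frame = embryoFrame(),
                          minSeedDistance = 5, satLevel = 0.98,
                          segChannel = "dna") {
  if (is(channels, "TissuePhantom")) {
    frame <- channels@frame
    channels <- channels@channels
  }
  if (!"dna" %in% names(channels))
    stop("channels must contain a 'dna' channel")
  if (!segChannel %in% names(channels))
    stop("unknown segmentation channel '", segChannel, "'")
  dna <- channels[[segChannel]]
  dims <- dim(dna)
  emptyResult <- function() new("SegmentationResult",
    labelVolume = array(0L, dims),
    objects = data.frame(label = integer(0), nVoxels = integer(0),
                         x = numeric(0), y = numeric(0), z = numeric(0)),
    voxelIndices = list(), frame = frame)
  rng <- range(dna)
  if (diff(rng) < 1e-12) return(emptyResult())
  # one global threshold: present the whole volume as a single frame
  # (EBImage::otsu thresholds each 2D frame separately)
  thr <- EBImage::otsu(EBImage::Image(matrix(as.numeric(dna), ncol = 1)),
                       range = rng)
  fg <- dna > thr
  if (!any(fg)) return(emptyResult())

  edt <- .edt3d(!fg, as.integer(dims), frame@voxelSize)
  minVox <- min(frame@voxelSize)
  maxIdx <- .localMaxima3d(as.numeric(edt), as.logical(fg),
                           as.integer(dims), 1.2 * minVox)
  seeds <- array(0L, dims)
  if (length(maxIdx)) {
    ord <- order(edt[maxIdx], decreasing = TRUE)
    cand <- maxIdx[ord]
    coords <- voxelToCoords(frame, arrayInd(cand, dims))
    keep <- logical(length(cand))
    for (i in seq_along(cand)) {
      if (!any(keep)) {
        keep[i] <- TRUE
        next
      }
      kc <- coords[keep, , drop = FALSE]
      if (min(sqrt(colSums((t(kc) - coords[i, ])^2))) >= minSeedDistance)
        keep[i] <- TRUE
    }
    seeds[cand[keep]] <- seq_len(sum(keep))
  }
  lab <- .watershed3d(as.numeric(edt), as.logical(fg), seeds,
                      as.integer(dims))
  # components the watershed never reached (no seed) get fresh labels
  orphan <- fg & lab == 0L
  if (any(orphan)) {
    extra <- .label3d(as.logical(orphan), as.integer(dims))
    lab[orphan] <- extra[orphan] + max(lab)
  }
  buildSegmentation(array(lab, dims), channels, frame, satLevel)
}

# assemble the per-object table from a label volume
buildSegmentation <- function(lab, channels, frame, satLevel = 0.98) {
  dims <- dim(lab)
  fgIdx <- which(lab > 0L)
  labs <- lab[fgIdx]
  spl <- split(fgIdx, labs)
  ids <- as.integer(names(spl))
  voxelIndices <- unname(spl)[order(ids)]
  ids <- sort(ids)
  nObj <- length(voxelIndices)
  nVox <- lengths(voxelIndices)
  cen <- t(vapply(voxelIndices, function(ix)
    colMeans(voxelToCoords(frame, arrayInd(ix, dims))), numeric(3)))
  objects <- data.frame(label = seq_len(nObj),
    nVoxels = as.integer(nVox),
    x = if (nObj) cen[, 1] else numeric(0),
    y = if (nObj) cen[, 2] else numeric(0),
    z = if (nObj) cen[, 3] else numeric(0))
  # relabel volume consecutively in ascending original-label order
  if (nObj && !identical(ids, seq_len(nObj))) {
    newLab <- array(0L, dims)
    for (k in seq_len(nObj)) newLab[voxelIndices[[k]]] <- k
    lab <- newLab
  }
  for (ch in names(channels)) {
    v <- channels[[ch]]
    objects[[paste0("mean_", ch)]] <- vapply(voxelIndices, function(ix)
      mean(v[ix]), numeric(1))
    objects[[paste0("max_", ch)]] <- vapply(voxelIndices, function(ix)
      max(v[ix]), numeric(1))
    objects[[paste0("satFrac_", ch)]] <- vapply(voxelIndices, function(ix)
      mean(v[ix] >= satLevel), numeric(1))
  }
  new("SegmentationResult", labelVolume = lab, objects = objects,
      voxelIndices = voxelIndices, frame = frame)
}

#' Quality-filter segmented objects
#'
#' Removes every object with fewer than `minVoxels` voxels (strictly) or with
#' a saturated-voxel fraction in the DNA channel above
#' `maxSaturatedFraction`, i.e. debris and saturated unspecific objects.
#' Survivors are relabelled consecutively.
#'
#' @param seg a [SegmentationResult-class].
#' @param params a [QualityFilterParams-class].
#' @return a filtered [SegmentationResult-class].
#' @export
qualityFilter <- function(seg, params = qualityFilterParams()) {
  validObject(params)
  obj <- seg@objects
  if (nrow(obj) == 0) return(seg)
  sat <- if ("satFrac_dna" %in% names(obj)) obj$satFrac_dna else 0
  keep <- obj$nVoxels >= params@minVoxels &
          sat <= params@maxSaturatedFraction
  idx <- which(keep)
  lab <- array(0L, dim(seg@labelVolume))
  vox <- seg@voxelIndices[idx]
  for (k in seq_along(idx)) lab[vox[[k]]] <- k
  objects <- obj[idx, , drop = FALSE]
  if (nrow(objects)) objects$label <- seq_len(nrow(objects))
  rownames(objects) <- NULL
  new("SegmentationResult", labelVolume = lab, objects = objects,
      voxelIndices = vox, frame = seg@frame)
}

#' Classify objects as marker-positive
#'
#' An object is positive when its mean intensity in the named channel is at
#' or above the threshold — the automated surrogate for manual
#' positive-cell counting.
#'
#' @param seg a [SegmentationResult-class].
#' @param channel channel name as used at segmentation time.
#' @param threshold intensity threshold (a.u., dynamic range 0-1).
#' @return logical vector, one flag per object.
#' @export
classifyPositive <- function(seg, channel, threshold) {
  col <- paste0("mean_", channel)
  if (!col %in% names(seg@objects))
    stop("unknown channel '", channel, "'")
  seg@objects[[col]] >= threshold
}
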