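#' Measure all nuclei of a phantom (or image stack) end to end
#'
#' Runs the full measurement chain: bleach correction of the DNA channel,
#' background subtraction of the GFP channel, segmentation, the
#' size/saturation quality filter, moment-based ellipsoid fits, shape
#' metrics, orientation angles, marker positivity calls, distance to the
#' apical surface and the emigration call.
#'
#' @param phantom a [TissuePhantom-class] (or a named channel list plus
#'   `frame`, `tubeMask`, `cavityMask`).
#' @param filterParams a [QualityFilterParams-class].
#' @param thresholds named positivity thresholds per non-DNA channel (mean
#'   object intensity, a.u.).
#' @param minSeedDistance watershed seed separation, micrometres.
#' @param bgRadius background-subtraction ball radius, micrometres.
#' @param frame,tubeMask,cavityMask used when `phantom` is a plain channel
#'   list.
#' @return list with `nuclei` (one row per kept object: centroid, voxel
#'   count, semi-axes, prolate/oblate/sphericity, theta/phi, per-channel
#'   positivity, distance to apical surface, emigrated flag) and `seg`
#'   (the filtered [SegmentationResult-class]).
#' @export
measureNuclei <- function(phantom, filterParams = qualityFilterParams(),
                          thresholds = c(gfp = 0.3, edu = 0.3),
                          minSeedDistance = 5, bgRadius = 4,
                          frame = NULL, tubeMask = NULL, cavityMask = NULL) {
  if (is(phantom, "TissuePhantom")) {
    channels <- phantom@channels
    frame <- phantom@frame
    tubeMask <- phantom@tubeMask
    cavityMask <- phantom@cavityMask
  } else {
    channels <- phantom
  }
  # segment on the bleach-corrected DNA but keep the raw channel for the
  # object statistics (saturation must be judged on acquisition values)
  channels$dnaCorr <- bleachCorrect(channels$dna)
  if ("gfp" %in% names(channels))
    channels$gfp <- subtractBackground(channels$gfp, bgRadius, frame)
  seg <- segmentNuclei(channels, frame, minSeedDistance = minSeedDistance,
                       segChannel = "dnaCorr")
  seg <- qualityFilter(seg, filterParams)
  obj <- seg@objects
  n <- nrow(obj)
  fits <- lapply(seq_len(n), function(k)
    fitEllipsoid(voxelToCoords(frame, arrayInd(seg@voxelIndices[[k]],
                                               dim(seg@labelVolume))),
                 frame))
  shp <- t(vapply(seq_len(n), function(k)
    shapeMetrics(fits[[k]], obj$nVoxels[k], frame), numeric(3)))
  ang <- t(vapply(seq_len(n), function(k)
    orientationAngles(majorAxis(fits[[k]])), numeric(2)))
  nuclei <- obj[, c("label", "nVoxels", "x", "y", "z")]
  if (n) {
    nuclei$a <- vapply(fits, function(f) f@semiAxes[1], numeric(1))
    nuclei$b <- vapply(fits, function(f) f@semiAxes[2], numeric(1))
    nuclei$c <- vapply(fits, function(f) f@semiAxes[3], numeric(1))
    nuclei$prolate <- shp[, 1]
    nuclei$oblate <- shp[, 2]
    nuclei$sphericity <- shp[, 3]
    nuclei$theta <- ang[, 1]
    nuclei$phi <- ang[, 2]
  } else {
    nuclei[c("a", "b", "c", "prolate", "oblate", "sphericity", "theta",
             "phi")] <- numeric(0)
  }
  for (ch in intersect(names(thresholds), names(channels)))
    nuclei[[paste0(ch, "Positive")]] <-
      classifyPositive(seg, ch, thresholds[[ch]])
  centres <- as.matrix(nuclei[, c("x", "y", "z")])
  if (!is.null(cavityMask) && n)
    nuclei$distApical <- distanceToApical(centres, cavityMask, frame)
  if (!is.null(tubeMask) && n) {
    idx <- coordsToVoxel(frame, centres)
    nuclei$emigrated <- !tubeMask[voxelToLinear(idx, dim(tubeMask))]
  }
  rownames(nuclei) <- NULL
  list(nuclei = nuclei, seg = seg)
}

validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("conditions", "seed", "outputDir"))
    if (is.null(config[[f]]))
      stop("pipeline config is missing required field '", f, "'")
  for (nm in names(config$conditions)) {
    cond <- config$conditions[[nm]]
    if (is.null(cond$phantom))
      stop("condition '", nm, "' is missing required field 'phantom'")
  }
  if (is.null(config$clusterParams))
    stop("pipeline config is missing required field 'clusterParams'")
  config
}

writeStackTiff <- function(channels, path) {
  # single multi-directory TIFF, C then Z order; each directory is a y-by-x
  # slice (axis order C, Z, Y, X); geometry goes in the JSON sidecar
  slices <- list()
  for (ch in names(channels)) {
    a <- pmin(pmax(channels[[ch]], 0), 1)
    for (z in seq_len(dim(a)[3])) slices[[length(slices) + 1]] <- t(a[, , z])
  }
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
}

#' Run the full phantom-to-report pipeline
#'
#' For each configured condition: generate the phantom, write the image
#' stack (multi-channel TIFF, C,Z,Y,X order, voxel size in a JSON sidecar)
#' and masks, measure all nuclei, cluster the GFP+ centres, simulate and fit
#' DNA-content events when requested, and write ground-truth, measured,
#' cluster and comparison tables (CSV) plus a machine-readable summary
#' (JSON) with every headline metric. Re-running with the same config
#' reproduces the outputs bit for bit.
#'
#' @param config a YAML file path or a list with `conditions` (named; each
#'   with a `phantom` sub-list of [phantomConfig()] arguments and optionally
#'   `dnaFractions`), `seed`, `outputDir`, and optional `clusterParams`,
#'   `filterParams`, `thresholds`, `djf` (g1Range, g2Range, g1Mean, cv,
#'   nEvents).
#' @param writeImages write TIFF stacks (default TRUE).
#' @return (invisibly) the summary list, one entry per condition plus
#'   `comparisons`.
#' @export
runPipeline <- function(config, writeImages = TRUE) {
  config <- validatePipelineConfig(config)
  outDir <- config$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cp <- do.call(clusterParams, as.list(config$clusterParams[
    intersect(names(config$clusterParams), c("eps", "minClusterSize"))]))
  fp <- if (is.null(config$filterParams)) qualityFilterParams()
        else do.call(qualityFilterParams, config$filterParams)
  thresholds <- if (is.null(config$thresholds)) c(gfp = 0.3, edu = 0.3)
                else unlist(config$thresholds)
  summary <- list(seed = config$seed)
  perCondition <- list()
  measured <- list()
  for (nm in names(config$conditions)) {
    cond <- config$conditions[[nm]]
    res <- tryCatch({
      pcArgs <- cond$phantom
      if (is.null(pcArgs$seed))
        pcArgs$seed <- substreamSeed(config$seed, match(nm,
          names(config$conditions)))
      pc <- do.call(phantomConfig, pcArgs)
      ph <- generatePhantom(pc)
      mm <- measureNuclei(ph, filterParams = fp, thresholds = thresholds)
      nuc <- mm$nuclei
      write.csv(truthTable(ph), file.path(outDir, paste0(nm, "_truth.csv")),
                row.names = FALSE)
      write.csv(format(nuc, digits = 9, trim = TRUE, scientific = FALSE),
                file.path(outDir, paste0(nm, "_nuclei.csv")),
                row.names = FALSE, quote = FALSE)
      if (writeImages) {
        writeStackTiff(ph@channels, file.path(outDir, paste0(nm, "_stack.tif")))
        writeStackTiff(list(tube = ph@tubeMask + 0, cavity = ph@cavityMask + 0),
                       file.path(outDir, paste0(nm, "_masks.tif")))
        jsonlite::write_json(list(axes = "CZYX",
          channels = channelNames(ph), voxelSizeUm = ph@frame@voxelSize,
          originUm = ph@frame@origin, dims = dim(tubeMask(ph))),
          file.path(outDir, paste0(nm, "_stack.json")), auto_unbox = TRUE)
      }
      gfpSel <- if ("gfpPositive" %in% names(nuc)) nuc$gfpPositive
                else rep(TRUE, nrow(nuc))
      centres <- as.matrix(nuc[gfpSel, c("x", "y", "z")])
      cl <- dbscanClusters(centres, cp)
      clTab <- data.frame(label = nuc$label[gfpSel],
                          cluster = clusterLabels(cl))
      write.csv(clTab, file.path(outDir, paste0(nm, "_clusters.csv")),
                row.names = FALSE)
      expFit <- tryCatch(fitClusterSizeDistribution(cl),
                         error = function(e) list(A = NA, k = NA, rss = NA))
      met <- list(
        nNuclei = nrow(nuc),
        meanProlate = mean(nuc$prolate),
        medianTheta = median(nuc$theta),
        medianPhi = median(nuc$phi),
        meanSphericity = mean(nuc$sphericity),
        emigrationPct = 100 * mean(nuc$emigrated[gfpSel]),
        meanDistApical = mean(nuc$distApical),
        nClusters = length(clusterSizes(cl)),
        clusterDecayK = expFit$k)
      for (ch in setdiff(names(thresholds), "gfp")) {
        col <- paste0(ch, "Positive")
        if (col %in% names(nuc))
          met[[paste0(ch, "PositivePct")]] <- 100 * mean(nuc[[col]][gfpSel])
      }
      if (!is.null(cond$dnaFractions)) {
        djf <- config$djf
        if (is.null(djf)) djf <- list()
        g1Mean <- if (is.null(djf$g1Mean)) 100 else djf$g1Mean
        ev <- simulateDnaEvents(
          n = if (is.null(djf$nEvents)) 20000 else djf$nEvents,
          fractions = unlist(cond$dnaFractions), g1Mean = g1Mean,
          cv = if (is.null(djf$cv)) 0.03 else djf$cv,
          seed = substreamSeed(config$seed,
            100 + match(nm, names(config$conditions))))
        fit <- fitDeanJettFox(dnaHistogram(ev),
          djfConstraints(
            if (is.null(djf$g1Range)) c(0.8, 1.2) * g1Mean else djf$g1Range,
            if (is.null(djf$g2Range)) c(1.7, 2.3) * g1Mean else djf$g2Range))
        met$phasePct <- as.list(100 * phaseFractions(fit))
      }
      measured[[nm]] <- nuc
      met
    }, error = function(e) {
      message("condition '", nm, "' failed: ", conditionMessage(e))
      list(error = conditionMessage(e))
    })
    perCondition[[nm]] <- res
  }
  summary$conditions <- perCondition
  # pairwise rank-sum comparisons of per-nucleus prolate ellipticity
  comps <- list()
  nms <- names(measured)
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      mw <- mannWhitneyU(measured[[nms[i]]]$prolate,
                         measured[[nms[j]]]$prolate)
      comps[[paste(nms[i], "vs", nms[j])]] <-
        list(metric = "prolate", U = mw$U, p = mw$p)
    }
    compTab <- data.frame(comparison = names(comps),
      U = vapply(comps, `[[`, numeric(1), "U"),
      p = vapply(comps, `[[`, numeric(1), "p"))
    write.csv(compTab, file.path(outDir, "comparisons.csv"),
              row.names = FALSE)
  }
  summary$comparisons <- comps
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
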