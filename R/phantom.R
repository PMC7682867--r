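#' Configure a synthetic embryo phantom
#'
#' Builds a [PhantomConfig-class] with state-dependent defaults. The
#' epithelial state emulates control neural tube tissue: elongated nuclei
#' (semi-axes 2, 2, 3 um), major axes along the medial-lateral axis with a
#' small angular jitter, all nuclei inside the tube, regular spacing above
#' the clustering radius. The mesenchymal state emulates transformed tissue:
#' rounder nuclei, orientations uniform on the sphere, a per-nucleus
#' probability of emigrating beyond the tube boundary, and a fraction of the
#' remaining nuclei grouped into seeded clusters with member spacing below
#' the DBSCAN radius.
#'
#' @param state `"epithelial"` or `"mesenchymal"`.
#' @param nNuclei number of nuclei.
#' @param semiAxes ground-truth semi-axes (a, b, c), micrometres, ascending.
#' @param orientationNoiseDeg s.d. of the angular jitter (degrees).
#' @param emigrationProb probability a nucleus is placed outside the tube
#'   (mesenchymal only).
#' @param clusterSpec list(nClusters, fraction, radius) of seeded clusters
#'   (mesenchymal only).
#' @param markerProbs named positivity probabilities, e.g. `c(edu = 0.75)`.
#' @param gfpProb probability a nucleus is GFP+ (electroporated).
#' @param noiseSd additive Gaussian image noise s.d. (intensity units,
#'   dynamic range 0-1).
#' @param attenuationPerSlice multiplicative per-z-slice intensity decay.
#' @param nDebris number of small saturated debris blobs (< 95 voxels each).
#' @param minSpacing minimum centre-to-centre spacing for non-clustered
#'   nuclei, micrometres; the default 10.5 sits above the 10 um clustering
#'   radius, so only seeded clusters (whose members are packed at the
#'   geometric non-touching spacing) form true density clusters.
#' @param volumeDim explicit voxel dimensions, or NA to size automatically.
#' @param seed RNG seed.
#' @return a [PhantomConfig-class].
#' @examples
#' phantomConfig("epithelial", nNuclei = 20, seed = 1)
#' @export
phantomConfig <- function(state = c("epithelial", "mesenchymal"),
                          nNuclei = 200L,
                          semiAxes = NULL,
                          orientationNoiseDeg = 5,
                          emigrationProb = if (state == "mesenchymal") 0.2 else 0,
                          clusterSpec = list(),
                          markerProbs = c(edu = 0.75),
                          gfpProb = 1,
                          noiseSd = 0.02,
                          attenuationPerSlice = 1,
                          nDebris = 5L,
                          minSpacing = NULL,
                          volumeDim = NA,
                          seed = 1L) {
  state <- match.arg(state)
  if (is.null(semiAxes))
    semiAxes <- if (state == "epithelial") c(2, 2, 3) else c(2.4, 2.4, 2.7)
  if (is.null(minSpacing)) minSpacing <- 10.5
  if (state == "mesenchymal" && length(clusterSpec) == 0) {
    # aim for ~6 members per seeded cluster
    nCl <- max(1L, as.integer(round(nNuclei * (1 - emigrationProb) * 0.3 / 6)))
    clusterSpec <- list(nClusters = nCl, fraction = 0.3, radius = 9.5)
  }
  new("PhantomConfig", state = state, nNuclei = as.integer(nNuclei),
      semiAxes = as.numeric(semiAxes),
      orientationNoiseDeg = orientationNoiseDeg,
      emigrationProb = emigrationProb, clusterSpec = clusterSpec,
      markerProbs = markerProbs, gfpProb = gfpProb, noiseSd = noiseSd,
      attenuationPerSlice = attenuationPerSlice, nDebris = as.integer(nDebris),
      minSpacing = minSpacing,
      volumeDim = if (all(is.na(volumeDim))) NA_integer_
                  else as.integer(volumeDim),
      seed = as.integer(seed))
}

# Tissue geometry: a solid half-cylinder (the neural tube) with its axis
# along y (antero-posterior), flat medial face at x = xApical, radius R in
# the x-z plane, and a thin slit cavity (the lumen) hugging the flat face.
phantomGeometry <- function(config, frame) {
  vs <- frame@voxelSize
  R <- 30
  xApical <- 8
  slitWidth <- 2
  rmax <- max(config@semiAxes)
  emigSpace <- if (config@state == "mesenchymal") 22 else 6
  if (!all(is.na(config@volumeDim))) {
    dims <- config@volumeDim
  } else {
    nxPhys <- xApical + R + emigSpace
    nzPhys <- 2 * R + 4
    effR <- R - rmax - 1
    effArea <- pi * effR^2 / 2
    nIn <- ceiling(config@nNuclei * (1 - config@emigrationProb))
    perPoint <- (4 / 3) * pi * (config@minSpacing / 2)^3 / 0.28
    nyTube <- ceiling(nIn * perPoint / effArea)
    cs <- config@clusterSpec
    if (length(cs) && !is.null(cs$nClusters) && cs$nClusters > 0) {
      sc <- 2.2 * cs$radius
      perCentre <- (4 / 3) * pi * (sc / 2)^3 / 0.28
      nyTube <- max(nyTube, ceiling(cs$nClusters * perCentre / effArea))
    }
    nOut <- config@nNuclei - nIn
    outArea <- max((nxPhys - xApical) * nzPhys - pi * R^2 / 2, 1)
    nyOut <- ceiling(nOut * perPoint / outArea)
    nyPhys <- max(48, nyTube, nyOut)
    dims <- as.integer(ceiling(c(nxPhys / vs[1], nyPhys / vs[2],
                                 nzPhys / vs[3])))
  }
  list(dims = dims, R = R, xApical = xApical, slitWidth = slitWidth,
       z0 = frame@origin[3] + (dims[3] - 1) * vs[3] / 2)
}

buildMasks <- function(geom, frame) {
  dims <- geom$dims
  xs <- frame@origin[1] + (seq_len(dims[1]) - 1) * frame@voxelSize[1]
  zs <- frame@origin[3] + (seq_len(dims[3]) - 1) * frame@voxelSize[3]
  dx <- xs - geom$xApical
  dz <- zs - geom$z0
  radial2 <- outer(dx^2, dz^2, "+")      # nx x nz
  tubeXZ <- (radial2 <= geom$R^2) & (dx >= 0)
  cavityXZ <- outer(dx < 0 & dx >= -geom$slitWidth, abs(dz) <= geom$R, "&")
  tube <- aperm(array(tubeXZ, c(dims[1], dims[3], dims[2])), c(1, 3, 2))
  cavity <- aperm(array(cavityXZ, c(dims[1], dims[3], dims[2])), c(1, 3, 2))
  list(tube = tube, cavity = cavity)
}

# Rejection placement with a global minimum spacing. `sampler` draws one
# candidate point; `accepted` is the running matrix of placed centres.
placeWithSpacing <- function(sampler, accepted, minSpacing, maxAttempts,
                             what = "nucleus") {
  for (i in seq_len(maxAttempts)) {
    p <- sampler()
    if (is.null(p)) next
    if (nrow(accepted) == 0 ||
        min(sqrt(colSums((t(accepted) - p)^2))) >= minSpacing)
      return(p)
  }
  stop("overcrowded volume: failed to place ", what, " after ", maxAttempts,
       " attempts; reduce nNuclei or minSpacing, or enlarge volumeDim")
}

#' Generate a synthetic embryo phantom
#'
#' Places nuclei according to the configured tissue state, writes the
#' ground-truth table, then renders the image channels: solid ellipsoids in
#' the DNA channel (GFP/marker channels only inside flagged nuclei), small
#' saturated debris blobs, a Gaussian blur, per-slice depth attenuation, and
#' additive Gaussian noise, in that order. All randomness flows from
#' `config@seed`; the per-nucleus emigration flags are the first draws from
#' the stream (`rbinom(nNuclei, 1, emigrationProb)`), so they can be
#' reproduced independently by replaying the seed.
#'
#' @param config a [PhantomConfig-class].
#' @param frame an [EmbryoFrame-class]. The default is confocal-like 0.5 um
#'   isotropic sampling, at which a (2, 2, 3) um nucleus spans roughly 400
#'   voxels — comfortably above the 95-voxel quality filter — while debris
#'   blobs stay below it.
#' @param render if FALSE, skip image rendering (masks and ground truth
#'   only); used for placement-level Monte-Carlo studies.
#' @return a [TissuePhantom-class].
#' @examples
#' ph <- generatePhantom(phantomConfig("epithelial", nNuclei = 10, seed = 1))
#' head(truthTable(ph))
#' @export
generatePhantom <- function(config, frame = embryoFrame(0.5),
                            render = TRUE) {
  validObject(config)
  geom <- phantomGeometry(config, frame)
  dims <- geom$dims
  masks <- buildMasks(geom, frame)
  n <- config@nNuclei
  rmax <- max(config@semiAxes)
  vs <- frame@voxelSize

  set.seed(config@seed)
  # --- draw order is part of the reproducibility contract ---
  # 1. emigration flags
  emig <- if (config@state == "mesenchymal" && n > 0)
    rbinom(n, 1, config@emigrationProb) == 1 else rep(FALSE, n)
  # 2. seeded-cluster assignment among in-tube nuclei
  clusterId <- rep(NA_integer_, n)
  cs <- config@clusterSpec
  if (config@state == "mesenchymal" && n > 0 && length(cs) &&
      cs$fraction > 0 && cs$nClusters > 0) {
    inTube <- which(!emig)
    nClustered <- round(cs$fraction * length(inTube))
    if (nClustered >= 2) {
      members <- sample(inTube, nClustered)
      clusterId[members] <- rep_len(seq_len(cs$nClusters), nClustered)
    }
  }

  # placement regions (physical um)
  yLim <- c(frame@origin[2] + rmax + 1,
            frame@origin[2] + (dims[2] - 1) * vs[2] - rmax - 1)
  inTubeSampler <- function() {
    # uniform in the half-disc cross-section, inset so the rendered
    # ellipsoid stays inside the tube and clear of the cavity slit
    effR <- geom$R - rmax - 1
    repeat {
      u <- runif(2, -effR, effR)
      if (u[1] >= rmax + 1 && sum(u^2) <= effR^2) break
    }
    c(geom$xApical + u[1], runif(1, yLim[1], yLim[2]), geom$z0 + u[2])
  }
  xMax <- frame@origin[1] + (dims[1] - 1) * vs[1]
  zLim <- c(frame@origin[3] + rmax + 1,
            frame@origin[3] + (dims[3] - 1) * vs[3] - rmax - 1)
  outTubeSampler <- function() {
    # adjacent tissue: lateral of the tube's curved face
    p <- c(runif(1, geom$xApical, xMax - rmax - 1),
           runif(1, yLim[1], yLim[2]), runif(1, zLim[1], zLim[2]))
    r2 <- (p[1] - geom$xApical)^2 + (p[3] - geom$z0)^2
    if (r2 > (geom$R + rmax + 1)^2) p else NULL
  }

  # 3. positions
  centres <- matrix(NA_real_, n, 3)
  placed <- matrix(numeric(0), 0, 3)
  if (n > 0) {
    clusterCentres <- NULL
    usedClusters <- sort(unique(clusterId[!is.na(clusterId)]))
    if (length(usedClusters)) {
      cc <- matrix(numeric(0), 0, 3)
      for (k in usedClusters) {
        p <- placeWithSpacing(inTubeSampler, cc, 2.2 * cs$radius, 2000L,
                              what = "cluster centre")
        cc <- rbind(cc, p)
      }
      clusterCentres <- cc
    }
    for (i in seq_len(n)) {
      if (emig[i]) {
        p <- placeWithSpacing(outTubeSampler, placed, config@minSpacing,
                              500L, what = paste0("nucleus ", i))
      } else if (!is.na(clusterId[i])) {
        k <- match(clusterId[i], usedClusters)
        anchorPool <- placed[which(clusterId[seq_len(i - 1)] == clusterId[i] &
                                   !is.na(clusterId[seq_len(i - 1)])), ,
                             drop = FALSE]
        gmin <- 2 * rmax + 1   # non-touching floor for packed members
        sampler <- function() {
          anchor <- if (nrow(anchorPool) == 0) clusterCentres[k, ]
                    else anchorPool[sample.int(nrow(anchorPool), 1), ]
          q <- anchor + randomUnitVector() * runif(1, gmin, cs$radius)
          r2 <- (q[1] - geom$xApical)^2 + (q[3] - geom$z0)^2
          ok <- q[1] >= geom$xApical + rmax + 1 &&
            r2 <= (geom$R - rmax - 1)^2 &&
            q[2] >= yLim[1] && q[2] <= yLim[2]
          if (ok) q else NULL
        }
        p <- placeWithSpacing(sampler, placed, gmin, 500L,
                              what = paste0("clustered nucleus ", i))
      } else {
        p <- placeWithSpacing(inTubeSampler, placed, config@minSpacing, 500L,
                              what = paste0("nucleus ", i))
      }
      centres[i, ] <- p
      placed <- rbind(placed, p)
    }
  }

  # 4. orientations
  axes <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (config@state == "epithelial") {
      u <- randomUnitVector()
      ang <- abs(rnorm(1, 0, config@orientationNoiseDeg))
      axes[i, ] <- as.numeric(rotationAboutAxis(u, ang) %*% c(1, 0, 0))
    } else {
      axes[i, ] <- randomUnitVector()
    }
    axes[i, ] <- axes[i, ] / sqrt(sum(axes[i, ]^2))
  }

  # 5. GFP flags; 6. marker flags
  gfp <- if (n > 0) rbinom(n, 1, config@gfpProb) == 1 else logical(0)
  markers <- lapply(config@markerProbs, function(p)
    if (n > 0) rbinom(n, 1, p) == 1 else logical(0))

  truth <- data.frame(id = seq_len(n),
    x = centres[, 1], y = centres[, 2], z = centres[, 3],
    a = rep(config@semiAxes[1], n), b = rep(config@semiAxes[2], n),
    c = rep(config@semiAxes[3], n),
    axisX = axes[, 1], axisY = axes[, 2], axisZ = axes[, 3],
    compartment = ifelse(emig, "emigrated", "in_tube")[seq_len(n)],
    gfp = gfp, clusterId = clusterId)
  for (m in names(markers)) truth[[paste0("marker_", m)]] <- markers[[m]]
  if (n == 0) truth$compartment <- character(0)

  channels <- list()
  if (render) {
    bg <- c(dna = 0.05, gfp = 0.02)
    sig <- c(dna = 0.8, gfp = 0.85)
    channels$dna <- array(bg[["dna"]], dims)
    channels$gfp <- array(bg[["gfp"]], dims)
    for (m in names(markers)) channels[[m]] <- array(0.02, dims)
    for (i in seq_len(n)) {
      vox <- ellipsoidVoxels(centres[i, ], config@semiAxes, axes[i, ], frame,
                             dims)
      channels$dna[vox] <- sig[["dna"]]
      if (gfp[i]) channels$gfp[vox] <- sig[["gfp"]]
      for (m in names(markers))
        if (markers[[m]][i]) channels[[m]][vox] <- 0.9
    }
    # 7. debris, rendered below the 95-voxel filter: alternating small
    # bright specks (dead-cell remnants) and larger over-exposed particles
    # rendered far above the dynamic range, whose clipped cores stay
    # saturated even after the blur
    for (d in seq_len(config@nDebris)) {
      big <- d %% 2 == 0
      r <- if (big) runif(1, 1.25, 1.4) else runif(1, 0.4, 0.7)
      p <- c(runif(1, frame@origin[1] + r + 1, xMax - r - 1),
             runif(1, frame@origin[2] + r + 1,
                   frame@origin[2] + (dims[2] - 1) * vs[2] - r - 1),
             runif(1, frame@origin[3] + r + 1,
                   frame@origin[3] + (dims[3] - 1) * vs[3] - r - 1))
      vox <- ellipsoidVoxels(p, rep(r, 3), c(0, 0, 1), frame, dims)
      channels$dna[vox] <- if (big) 10 else 3
    }
    # blur, depth attenuation, noise (8.), clip to dynamic range
    att <- config@attenuationPerSlice^(seq_len(dims[3]) - 1)
    for (ch in names(channels)) {
      # PSF-like smoothing: sigma 0.25 um (half a voxel at default sampling)
      x <- .gaussBlur3d(channels[[ch]], dims, 0.25 / mean(vs))
      x <- sweep(array(x, dims), 3, att, "*")
      if (config@noiseSd > 0)
        x <- x + array(rnorm(prod(dims), 0, config@noiseSd), dims)
      channels[[ch]] <- pmin(pmax(x, 0), 1)
      dim(channels[[ch]]) <- dims
    }
  }

  new("TissuePhantom", channels = channels, tubeMask = masks$tube,
      cavityMask = masks$cavity, frame = frame, truth = truth,
      config = config)
}

# linear voxel indices of a solid ellipsoid (centre um, semiAxes um,
# majorAxis unit vector; minor axes span its orthogonal complement)
ellipsoidVoxels <- function(centre, semiAxes, majorAxis, frame, dims) {
  Q <- cbind(orthonormalComplement(majorAxis), majorAxis)
  vs <- frame@voxelSize
  rmax <- max(semiAxes)
  lo <- pmax(coordsToVoxel(frame, centre - rmax)[1, ], 1)
  hi <- pmin(coordsToVoxel(frame, centre + rmax)[1, ], dims)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  p <- voxelToCoords(frame, g)
  d <- sweep(p, 2, centre, "-") %*% Q
  inside <- rowSums(sweep(d, 2, c(semiAxes[1], semiAxes[2], semiAxes[3]),
                          "/")^2) <= 1
  voxelToLinear(g[inside, , drop = FALSE], dims)
}

orthonormalComplement <- function(v) {
  p <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- p - sum(p * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2], v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  cbind(e1, e2)
}

#' Simulate univariate DNA-content events
#'
#' Draws flow-cytometry-like events: each event gets a true phase by the
#' given fractions; G0/G1 events are Normal(g1Mean, cv * g1Mean), G2/M events
#' Normal(2 g1Mean, cv * 2 g1Mean), and S events have true content uniform on
#' (g1Mean, 2 g1Mean) measured with the same relative noise.
#'
#' @param n number of events.
#' @param fractions numeric(3) (g1, s, g2m), non-negative, summing to 1.
#' @param g1Mean G0/G1 mean fluorescence (a.u.).
#' @param cv coefficient of variation of the measurement.
#' @param seed RNG seed.
#' @return data.frame with `value` (measured fluorescence), `phase`
#'   (true label: "g1", "s", "g2m") and `gfp` (events arrive pre-gated, so
#'   all TRUE).
#' @examples
#' ev <- simulateDnaEvents(1000, c(0.6, 0.3, 0.1), seed = 1)
#' table(ev$phase)
#' @export
simulateDnaEvents <- function(n, fractions, g1Mean = 100, cv = 0.03,
                              seed = 1L) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (cv <= 0) stop("cv must be > 0")
  if (n == 0)
    return(data.frame(value = numeric(0), phase = character(0),
                      gfp = logical(0)))
  set.seed(as.integer(seed))
  phase <- sample(c("g1", "s", "g2m"), n, replace = TRUE, prob = fractions)
  value <- numeric(n)
  i1 <- phase == "g1"; i2 <- phase == "g2m"; is <- phase == "s"
  value[i1] <- rnorm(sum(i1), g1Mean, cv * g1Mean)
  value[i2] <- rnorm(sum(i2), 2 * g1Mean, cv * 2 * g1Mean)
  tru <- runif(sum(is), g1Mean, 2 * g1Mean)
  value[is] <- rnorm(sum(is), tru, cv * tru)
  data.frame(value = pmax(value, .Machine$double.eps), phase = phase,
             gfp = TRUE)
}
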