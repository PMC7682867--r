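#' Distance from nucleus centres to the apical surface
#'
#' Euclidean distance transform of the complement of the apical-cavity mask
#' (physical units, anisotropy-aware), sampled at each centre's containing
#' voxel: the distance to the nearest cavity voxel, 0 inside the cavity.
#'
#' @param centres n x 3 matrix of centre coordinates (micrometres).
#' @param cavityMask logical 3D array of the apical cavity (lumen).
#' @param frame an [EmbryoFrame-class].
#' @return numeric distances (micrometres), one per centre.
#' @export
distanceToApical <- function(centres, cavityMask, frame = embryoFrame()) {
  if (!any(cavityMask)) stop("cavity mask is empty")
  centres <- rbind(centres)
  dims <- dim(cavityMask)
  idx <- coordsToVoxel(frame, centres)
  checkInsideVolume(idx, dims, "centre")
  D <- .edt3d(as.logical(cavityMask), as.integer(dims), frame@voxelSize)
  array(D, dims)[voxelToLinear(idx, dims)]
}

#' Fraction of GFP+ nuclei that emigrated from the neural tube
#'
#' A GFP+ nucleus counts as emigrated when its centre's containing voxel
#' lies outside the tube mask.
#'
#' @param centres n x 3 matrix of centre coordinates (micrometres).
#' @param gfpFlags logical, per-centre GFP positivity.
#' @param tubeMask logical 3D array of the neural tube.
#' @param frame an [EmbryoFrame-class].
#' @return fraction in \[0, 1\].
#' @export
emigrationFraction <- function(centres, gfpFlags, tubeMask,
                               frame = embryoFrame()) {
  centres <- rbind(centres)
  gfpFlags <- rep_len(gfpFlags, nrow(centres))
  if (!any(gfpFlags)) stop("no GFP+ centres: emigration fraction undefined")
  dims <- dim(tubeMask)
  idx <- coordsToVoxel(frame, centres[gfpFlags, , drop = FALSE])
  checkInsideVolume(idx, dims, "centre")
  mean(!tubeMask[voxelToLinear(idx, dims)])
}

#' DBSCAN clustering of cell centres
#'
#' Classic DBSCAN with neighbourhood radius `eps` and
#' `minPts = minClusterSize` (a point counts itself), expanded
#' deterministically in index order; clusters that end up with fewer than
#' `minClusterSize` members (possible when border points are claimed by an
#' earlier cluster) are demoted to noise, so every emitted cluster respects
#' the minimum size. The resulting partition is invariant under input
#' permutation up to label renaming.
#'
#' @param centres n x 3 (or n x d) matrix of coordinates (micrometres).
#' @param params a [ClusterParams-class] (defaults: eps 10 um, minimum
#'   cluster size 3).
#' @return a [ClusterResult-class].
#' @examples
#' pts <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(50, 50, 50))
#' clusterSizes(dbscanClusters(pts))
#' @export
dbscanClusters <- function(centres, params = clusterParams()) {
  validObject(params)
  centres <- rbind(centres)
  n <- nrow(centres)
  labels <- integer(n)
  if (n > 0) {
    D <- as.matrix(stats::dist(centres))
    nb <- lapply(seq_len(n), function(i) which(D[i, ] <= params@eps))
    core <- lengths(nb) >= params@minClusterSize
    cl <- 0L
    for (i in seq_len(n)) {
      if (labels[i] != 0L || !core[i]) next
      cl <- cl + 1L
      labels[i] <- cl
      queue <- setdiff(nb[[i]], i)
      while (length(queue)) {
        j <- queue[1]
        queue <- queue[-1]
        if (labels[j] == 0L) {
          labels[j] <- cl
          if (core[j]) queue <- c(queue, setdiff(nb[[j]],
                                                 which(labels != 0L)))
        }
      }
    }
    # demote undersized clusters (border points stolen by earlier clusters)
    if (cl > 0) {
      sz <- tabulate(labels, cl)
      bad <- which(sz < params@minClusterSize)
      if (length(bad)) {
        labels[labels %in% bad] <- 0L
        labels <- match(labels, sort(unique(labels[labels > 0L]))) |>
          (\(m) ifelse(is.na(m), 0L, m))() |> as.integer()
      }
    }
  }
  k <- max(labels, 0L)
  sizes <- if (k > 0) tabulate(labels, k) else integer(0)
  sizeDistribution <- if (k > 0) {
    tb <- table(sizes)
    data.frame(size = as.integer(names(tb)),
               pct = 100 * as.numeric(tb) / k)
  } else data.frame(size = integer(0), pct = numeric(0))
  new("ClusterResult", labels = labels, sizes = as.integer(sizes),
      sizeDistribution = sizeDistribution, params = params)
}

# log-linear least squares of pct = A * exp(-k * size); internal exact path
fitExpDecay <- function(size, pct) {
  keep <- pct > 0
  size <- size[keep]
  pct <- pct[keep]
  if (length(unique(size)) < 2)
    stop("degenerate fit: need at least 2 distinct cluster size classes")
  fit <- lm(log(pct) ~ size)
  res <- list(A = unname(exp(coef(fit)[1])), k = unname(-coef(fit)[2]),
              rss = sum(residuals(fit)^2))
  res
}

#' Exponential model of the cluster-size distribution
#'
#' Fits `percent-of-clusters = A * exp(-k * size)` to the realised size
#' classes by least squares on the linearised (log) scale; zero-percentage
#' classes are excluded from the log fit.
#'
#' @param sizes integer cluster sizes (one entry per cluster), or a
#'   [ClusterResult-class].
#' @return list with `A`, decay rate `k`, and `rss` (residual sum of squares
#'   on the log scale).
#' @export
fitClusterSizeDistribution <- function(sizes) {
  if (is(sizes, "ClusterResult")) sizes <- sizes@sizes
  if (length(sizes) < 2 || length(unique(sizes)) < 2)
    stop("degenerate fit: need at least 2 distinct cluster size classes")
  tb <- table(sizes)
  fitExpDecay(as.integer(names(tb)), 100 * as.numeric(tb) / length(sizes))
}

#' Nearest-neighbour distances between cell centres
#'
#' @param centres n x 3 (or n x d) matrix, n >= 2.
#' @return numeric, each point's distance to its closest other point
#'   (micrometres).
#' @examples
#' nearestNeighbourDistances(cbind(c(0, 1, 5), 0, 0))  # 1 1 4
#' @export
nearestNeighbourDistances <- function(centres) {
  centres <- rbind(centres)
  if (nrow(centres) < 2) stop("need at least 2 points")
  D <- as.matrix(stats::dist(centres))
  diag(D) <- Inf
  unname(apply(D, 1, min))
}
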