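#' @useDynLib tubemorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom lm coef residuals median sd quantile
#'   pwilcox pnorm dnorm setNames
#' @importFrom utils write.csv read.csv
NULL

#' Construct an embryo coordinate frame
#'
#' @param voxelSize micrometres per voxel along (x, y, z); a scalar is
#'   recycled (isotropic voxels).
#' @param origin physical coordinate of the first voxel, micrometres.
#' @return an [EmbryoFrame-class].
#' @examples
#' embryoFrame(0.5)
#' @export
embryoFrame <- function(voxelSize = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(voxelSize) == 1) voxelSize <- rep(voxelSize, 3)
  new("EmbryoFrame", voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' @rdname QualityFilterParams-class
#' @param minVoxels,maxSaturatedFraction see slots.
#' @export
qualityFilterParams <- function(minVoxels = 95L, maxSaturatedFraction = 0.5) {
  new("QualityFilterParams", minVoxels = as.integer(minVoxels),
      maxSaturatedFraction = maxSaturatedFraction)
}

#' @rdname ClusterParams-class
#' @param eps,minClusterSize see slots.
#' @export
clusterParams <- function(eps = 10, minClusterSize = 3L) {
  new("ClusterParams", eps = as.numeric(eps),
      minClusterSize = as.integer(minClusterSize))
}

#' @rdname DjfConstraints-class
#' @param g1Range,g2Range see slots.
#' @export
djfConstraints <- function(g1Range, g2Range) {
  new("DjfConstraints", g1Range = as.numeric(g1Range),
      g2Range = as.numeric(g2Range))
}

# physical coordinates (n x 3, um) -> 1-based voxel indices (n x 3)
coordsToVoxel <- function(frame, pts) {
  pts <- rbind(pts)
  idx <- sweep(sweep(pts, 2, frame@origin, "-"), 2, frame@voxelSize, "/")
  round(idx) + 1
}

# 1-based voxel indices (n x 3) -> physical coordinates of voxel centres (um)
voxelToCoords <- function(frame, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, frame@voxelSize, "*"), 2, frame@origin, "+")
}

# n x 3 voxel index matrix -> linear (column-major) indices
voxelToLinear <- function(idx, dims) {
  idx <- rbind(idx)
  as.integer((idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] +
             idx[, 1])
}

checkInsideVolume <- function(idx, dims, what = "point") {
  bad <- which(idx[, 1] < 1 | idx[, 1] > dims[1] |
               idx[, 2] < 1 | idx[, 2] > dims[2] |
               idx[, 3] < 1 | idx[, 3] > dims[3])
  if (length(bad))
    stop(what, " ", bad[1], " falls outside the image volume (voxel ",
         paste(idx[bad[1], ], collapse = ", "), ")")
  invisible(TRUE)
}

# rotation matrix sending unit vector `from` onto unit vector `to`
# (Rodrigues); identity if already aligned.
rotationBetween <- function(from, to) {
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  cth <- sum(from * to)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate 180 degrees about any perpendicular axis
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- p - sum(p * from) * from
    a <- a / sqrt(sum(a^2))
    return(2 * tcrossprod(a) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# rotation by `angleDeg` about unit axis `u`
rotationAboutAxis <- function(u, angleDeg) {
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# uniform random unit vector
randomUnitVector <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

angleBetweenDeg <- function(u, v) {
  c <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, c)) * 180 / pi
}

# derive a bounded substream seed from a root seed
substreamSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483629)
}
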