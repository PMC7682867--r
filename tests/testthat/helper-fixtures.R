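# shared fixtures: small phantoms and hand-built segmentations

frame05 <- embryoFrame(0.5)

smallEpithelial <- function(n = 10, seed = 1, ...) {
  generatePhantom(phantomConfig("epithelial", nNuclei = n, seed = seed,
                                noiseSd = 0, nDebris = 0L, ...))
}

# voxel index set of a ground-truth nucleus (row of a truth table)
truthVoxels <- function(row, frame, dims) {
  tubemorph:::ellipsoidVoxels(c(row$x, row$y, row$z), c(row$a, row$b, row$c),
                              c(row$axisX, row$axisY, row$axisZ), frame, dims)
}

# match measured objects to truth nuclei by nearest centre
matchToTruth <- function(nuclei, truth) {
  vapply(seq_len(nrow(nuclei)), function(i) {
    d2 <- (truth$x - nuclei$x[i])^2 + (truth$y - nuclei$y[i])^2 +
      (truth$z - nuclei$z[i])^2
    which.min(d2)
  }, integer(1))
}

# build a SegmentationResult from explicit voxel lists (linear indices)
segFromVoxelLists <- function(voxelLists, dims, frame = embryoFrame(),
                              dnaValues = NULL) {
  lab <- array(0L, dims)
  for (k in seq_along(voxelLists)) lab[voxelLists[[k]]] <- k
  dna <- array(0.5, dims)
  if (!is.null(dnaValues))
    for (k in seq_along(voxelLists)) dna[voxelLists[[k]]] <- dnaValues[[k]]
  tubemorph:::buildSegmentation(lab, list(dna = dna), frame)
}

# axis-aligned cuboid of exactly n voxels starting at (x0, y0, z0)
cuboidVoxels <- function(n, dims, x0 = 1, y0 = 1, z0 = 1) {
  stopifnot(n <= prod(dims) / 2)
  g <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                             z = seq_len(dims[3])))
  keep <- g[, 1] >= x0 & g[, 2] >= y0 & g[, 3] >= z0
  idx <- which(keep)[seq_len(n)]
  as.integer((g[idx, 3] - 1) * dims[1] * dims[2] +
             (g[idx, 2] - 1) * dims[1] + g[idx, 1])
}

# independent DBSCAN oracle: neighbourhoods and core points by brute force,
# core partition by transitive closure of the core-core <= eps graph,
# border points eligible for any cluster owning a core neighbour
dbscanOracle <- function(pts, eps, minPts) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= minPts
  lab <- rep(0L, n)
  coreIdx <- which(core)
  if (length(coreIdx)) {
    comp <- seq_along(coreIdx)
    adj <- D[coreIdx, coreIdx, drop = FALSE] <= eps
    repeat {
      changed <- FALSE
      for (i in seq_along(coreIdx)) {
        for (j in which(adj[i, ])) {
          if (comp[j] != comp[i]) {
            m <- min(comp[i], comp[j])
            comp[comp == comp[i] | comp == comp[j]] <- m
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    lab[coreIdx] <- match(comp, sort(unique(comp)))
  }
  eligible <- lapply(seq_len(n), function(i) {
    if (core[i]) return(lab[i])
    cn <- nb[[i]][core[nb[[i]]]]
    sort(unique(lab[cn]))
  })
  list(core = core, coreLabels = lab, eligible = eligible)
}

# full-enumeration oracle for the two-sided exact Mann-Whitney p-value
exactMwOracle <- function(a, b) {
  na <- length(a)
  pool <- c(a, b)
  N <- length(pool)
  r <- rank(pool)
  uOf <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  uObs <- uOf(seq_len(na))
  us <- combn(N, na, uOf)
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# canonical form of a partition labelling (noise = 0 kept as is)
canonicalPartition <- function(labels) {
  pos <- labels > 0
  out <- integer(length(labels))
  out[pos] <- match(labels[pos], unique(labels[pos]))
  out
}
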