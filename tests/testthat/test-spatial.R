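test_that("distance to the apical surface matches exhaustive search", {
  fr1 <- embryoFrame(1)
  # 3-4-5 triangle: cavity voxel at the origin, centre at voxel (3,4,0)
  cav <- array(FALSE, c(11, 11, 11))
  cav[1, 1, 1] <- TRUE
  expect_equal(distanceToApical(c(3, 4, 0), cav, fr1), 5)
  # centre inside the cavity -> 0
  expect_equal(distanceToApical(c(0, 0, 0), cav, fr1), 0)
  # random instances vs brute force, anisotropic voxels
  set.seed(10)
  fr <- embryoFrame(c(0.5, 0.7, 1.1))
  dims <- c(15L, 12L, 14L)
  for (rep in 1:5) {
    cav <- array(runif(prod(dims)) < 0.02, dims)
    if (!any(cav)) cav[4, 4, 4] <- TRUE
    vox <- which(array(runif(prod(dims)) < 0.05, dims))[1:20]
    vox <- vox[!is.na(vox)]
    centres <- tubemorph:::voxelToCoords(fr, arrayInd(vox, dims))
    d <- distanceToApical(centres, cav, fr)
    featP <- tubemorph:::voxelToCoords(fr, which(cav, arr.ind = TRUE))
    bf <- apply(centres, 1, function(p)
      sqrt(min(colSums((t(featP) - p)^2))))
    expect_equal(d, bf, tolerance = 1e-9)
  }
  expect_error(distanceToApical(c(1, 1, 1), array(FALSE, dims), fr), "empty")
  expect_error(distanceToApical(c(500, 1, 1), cav, fr), "outside")
})

test_that("emigration fraction matches the phantom ground truth", {
  cfg <- phantomConfig("mesenchymal", nNuclei = 150, emigrationProb = 0.2,
                       seed = 13)
  ph <- generatePhantom(cfg, render = FALSE)
  tr <- truthTable(ph)
  frac <- emigrationFraction(as.matrix(tr[, c("x", "y", "z")]), tr$gfp,
                             tubeMask(ph), embryoFrameOf(ph))
  expect_equal(frac, mean(tr$compartment == "emigrated"))
  expect_gt(frac, 0.15)
  # all centres inside the mask -> 0
  inTube <- tr[tr$compartment == "in_tube", ]
  expect_equal(emigrationFraction(as.matrix(inTube[, c("x", "y", "z")]),
                                  TRUE, tubeMask(ph), embryoFrameOf(ph)), 0)
  expect_error(emigrationFraction(c(1, 1, 1), FALSE, tubeMask(ph),
                                  embryoFrameOf(ph)), "GFP")
})

test_that("emigration fraction is an unbiased estimator of the emigration probability", {
  fracs <- vapply(1:50, function(s) {
    ph <- generatePhantom(phantomConfig("mesenchymal", nNuclei = 40,
                                        emigrationProb = 0.2, seed = 100 + s),
                          render = FALSE)
    tr <- truthTable(ph)
    emigrationFraction(as.matrix(tr[, c("x", "y", "z")]), tr$gfp,
                       tubeMask(ph), embryoFrameOf(ph))
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.2), 2 * se + 1e-12)
})

test_that("DBSCAN follows the 3-cell / 10-micron convention", {
  p <- rbind(c(0, 0, 0), c(8, 0, 0), c(4, 6, 0))
  cl <- dbscanClusters(p)
  expect_equal(clusterSizes(cl), 3L)
  expect_true(all(clusterLabels(cl) == 1L))
  far <- rbind(c(0, 0, 0), c(50, 0, 0))
  cl2 <- dbscanClusters(far)
  expect_equal(length(clusterSizes(cl2)), 0)
  expect_true(all(clusterLabels(cl2) == 0L))
  expect_equal(sum(dbscanClusters(matrix(numeric(0), 0, 3))@labels), 0)
})

test_that("DBSCAN equals the graph-closure oracle on 100 random instances", {
  set.seed(20)
  params <- clusterParams(eps = 10, minClusterSize = 3)
  for (inst in 1:100) {
    n <- sample(10:45, 1)
    pts <- cbind(runif(n, 0, 60), runif(n, 0, 60), runif(n, 0, 40))
    cl <- dbscanClusters(pts, params)
    orc <- dbscanOracle(pts, 10, 3)
    lab <- clusterLabels(cl)
    # core points: identical partition (up to label names)
    core <- orc$core
    expect_identical(canonicalPartition(lab[core]),
                     canonicalPartition(orc$coreLabels[core]))
    expect_true(all(lab[core] > 0))
    # border points: only ever assigned to a cluster of a core neighbour
    for (i in which(!core)) {
      if (lab[i] == 0L) {
        expect_equal(length(orc$eligible[[i]]), 0)
      } else {
        coreOfCluster <- orc$coreLabels[which(core & lab == lab[i])]
        expect_true(any(unique(coreOfCluster) %in% orc$eligible[[i]]))
      }
    }
  }
})

test_that("DBSCAN core partitions are invariant under input permutation", {
  # what density clustering guarantees under reordering: the partition of
  # core points is unchanged, and non-border points keep their noise status
  # (border points may legitimately switch between adjacent clusters)
  set.seed(21)
  for (rep in 1:10) {
    n <- 40
    pts <- cbind(runif(n, 0, 50), runif(n, 0, 50), runif(n, 0, 50))
    perm <- sample(n)
    a <- clusterLabels(dbscanClusters(pts))
    b <- clusterLabels(dbscanClusters(pts[perm, , drop = FALSE]))
    bUnperm <- integer(n)
    bUnperm[perm] <- b
    orc <- dbscanOracle(pts, 10, 3)
    core <- orc$core & a > 0L & bUnperm > 0L   # cores of emitted clusters
    expect_identical(canonicalPartition(a[core]),
                     canonicalPartition(bUnperm[core]))
    nonBorder <- !orc$core & lengths(orc$eligible) == 0
    expect_true(all(a[nonBorder] == 0L))
    expect_true(all(bUnperm[nonBorder] == 0L))
  }
})

test_that("epithelial phantoms produce no clusters; seeded clusters are recovered", {
  ph <- generatePhantom(phantomConfig("epithelial", nNuclei = 60, seed = 31),
                        render = FALSE)
  tr <- truthTable(ph)
  cl <- dbscanClusters(as.matrix(tr[, c("x", "y", "z")]))
  expect_equal(length(clusterSizes(cl)), 0)
  phM <- generatePhantom(phantomConfig("mesenchymal", nNuclei = 120,
                                       seed = 32), render = FALSE)
  trM <- truthTable(phM)
  clM <- dbscanClusters(as.matrix(trM[, c("x", "y", "z")]))
  seeded <- which(!is.na(trM$clusterId))
  recovered <- mean(clusterLabels(clM)[seeded] > 0)
  expect_gte(recovered, 0.9)
})

test_that("exponential cluster-size fit recovers exact and sampled decay rates", {
  # exact renormalised percentages: k recovered to 1e-6
  s <- 3:8
  pct <- 100 * exp(-0.5 * (s - 3)) / sum(exp(-0.5 * (s - 3)))
  fit <- tubemorph:::fitExpDecay(s, pct)
  expect_equal(fit$k, 0.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # degenerate: one size class
  expect_error(fitClusterSizeDistribution(rep(5L, 10)), "degenerate")
  expect_error(fitClusterSizeDistribution(integer(0)), "degenerate")
  # geometric cluster sizes: recovered rate within 3 s.e. of the truth
  set.seed(33)
  p <- 0.4
  sizes <- 3L + rgeom(200, p)
  fit <- fitClusterSizeDistribution(sizes)
  tb <- table(sizes)
  ref <- lm(log(100 * as.numeric(tb) / length(sizes)) ~
              as.integer(names(tb)))
  seSlope <- coef(summary(ref))[2, "Std. Error"]
  expect_lt(abs(fit$k - (-log(1 - p))), 3 * seSlope)
})

test_that("nearest-neighbour distances match the exhaustive oracle", {
  expect_equal(nearestNeighbourDistances(rbind(c(0, 0, 0), c(3, 4, 0))),
               c(5, 5))
  expect_equal(nearestNeighbourDistances(cbind(c(0, 1, 5), 0, 0)),
               c(1, 1, 4))
  set.seed(34)
  pts <- matrix(runif(600, 0, 100), ncol = 3)
  d <- nearestNeighbourDistances(pts)
  bf <- vapply(seq_len(200), function(i)
    min(vapply(seq_len(200), function(j)
      if (i == j) Inf else sqrt(sum((pts[i, ] - pts[j, ])^2)), numeric(1))),
    numeric(1))
  expect_equal(d, bf, tolerance = 1e-12)
  expect_error(nearestNeighbourDistances(rbind(c(1, 2, 3))), "2 points")
})
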