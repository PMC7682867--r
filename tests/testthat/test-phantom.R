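test_that("empty configuration yields an empty truth table and background-only image", {
  cfg <- phantomConfig("epithelial", nNuclei = 0L, nDebris = 0L, seed = 3)
  ph <- generatePhantom(cfg)
  expect_equal(nrow(truthTable(ph)), 0)
  dna <- imageChannel(ph, "dna")
  expect_lt(max(dna), 0.05 + 6 * cfg@noiseSd)
  expect_setequal(channelNames(ph), c("dna", "gfp", "edu"))
})

test_that("epithelial phantoms confine nuclei to the tube with near medial-lateral axes", {
  ph <- smallEpithelial(n = 50, seed = 1)
  tr <- truthTable(ph)
  expect_equal(nrow(tr), 50)
  expect_true(all(tr$compartment == "in_tube"))
  angToX <- acos(pmin(1, abs(tr$axisX))) * 180 / pi
  expect_true(all(angToX < 20))
  # major axes are unit vectors
  expect_equal(tr$axisX^2 + tr$axisY^2 + tr$axisZ^2, rep(1, 50),
               tolerance = 1e-12)
})

test_that("identical configuration and seed reproduce truth and image bit for bit", {
  cfg <- phantomConfig("epithelial", nNuclei = 12, seed = 11, nDebris = 2L)
  ph1 <- generatePhantom(cfg)
  ph2 <- generatePhantom(cfg)
  expect_identical(truthTable(ph1), truthTable(ph2))
  expect_identical(imageChannel(ph1, "dna"), imageChannel(ph2, "dna"))
  expect_identical(imageChannel(ph1, "gfp"), imageChannel(ph2, "gfp"))
})

test_that("mesenchymal emigration flags replay the seeded RNG stream", {
  cfg <- phantomConfig("mesenchymal", nNuclei = 200, emigrationProb = 0.2,
                       seed = 7)
  ph <- generatePhantom(cfg, render = FALSE)
  tr <- truthTable(ph)
  set.seed(7)
  expected <- rbinom(200, 1, 0.2)
  expect_identical(tr$compartment == "emigrated", expected == 1)
})

test_that("truth compartments are consistent with the tube mask", {
  for (seed in c(2, 9)) {
    cfg <- phantomConfig("mesenchymal", nNuclei = 80, seed = seed)
    ph <- generatePhantom(cfg, render = FALSE)
    tr <- truthTable(ph)
    frame <- embryoFrameOf(ph)
    idx <- tubemorph:::coordsToVoxel(frame, as.matrix(tr[, c("x", "y", "z")]))
    inside <- tubeMask(ph)[tubemorph:::voxelToLinear(idx, dim(tubeMask(ph)))]
    expect_identical(inside, tr$compartment == "in_tube")
  }
})

test_that("seeded cluster members sit within the stated spacing of a cluster mate", {
  cfg <- phantomConfig("mesenchymal", nNuclei = 100, seed = 5)
  ph <- generatePhantom(cfg, render = FALSE)
  tr <- truthTable(ph)
  clustered <- tr[!is.na(tr$clusterId), ]
  expect_gt(nrow(clustered), 10)
  for (k in unique(clustered$clusterId)) {
    m <- as.matrix(clustered[clustered$clusterId == k, c("x", "y", "z")])
    if (nrow(m) < 2) next
    D <- as.matrix(dist(m))
    diag(D) <- Inf
    expect_true(all(apply(D, 1, min) <= cfg@clusterSpec$radius + 1e-9))
  }
})

test_that("rendered channels respect positivity flags", {
  ph <- smallEpithelial(n = 8, seed = 4, gfpProb = 0.5,
                        markerProbs = c(edu = 0.5))
  tr <- truthTable(ph)
  frame <- embryoFrameOf(ph)
  dims <- dim(tubeMask(ph))
  gfp <- imageChannel(ph, "gfp")
  edu <- imageChannel(ph, "edu")
  for (i in seq_len(nrow(tr))) {
    vox <- truthVoxels(tr[i, ], frame, dims)
    if (tr$gfp[i]) expect_gt(mean(gfp[vox]), 0.5)
    else expect_lt(mean(gfp[vox]), 0.1)
    if (tr[["marker_edu"]][i]) expect_gt(mean(edu[vox]), 0.5)
    else expect_lt(mean(edu[vox]), 0.1)
  }
  # lumen is free of rendered nuclei
  expect_lt(max(imageChannel(ph, "dna")[cavityMask(ph)]), 0.3)
})

test_that("overcrowding fails with an explicit error", {
  cfg <- phantomConfig("epithelial", nNuclei = 500,
                       volumeDim = c(60L, 60L, 60L), seed = 1)
  expect_error(generatePhantom(cfg, render = FALSE), "overcrowded")
})

test_that("DNA event simulator honours phase fractions and noise model", {
  # single-component case
  ev <- simulateDnaEvents(10000, c(1, 0, 0), g1Mean = 100, cv = 0.03,
                          seed = 2)
  expect_true(all(ev$phase == "g1"))
  expect_lt(abs(mean(ev$value) - 100), 3 * 3 / sqrt(10000) * 100 / 100 + 0.1)
  # mixed fractions recovered within 3 binomial s.e.
  fr <- c(0.6, 0.3, 0.1)
  ev <- simulateDnaEvents(10000, fr, seed = 5)
  emp <- as.numeric(table(factor(ev$phase, c("g1", "s", "g2m")))) / 10000
  se <- sqrt(fr * (1 - fr) / 10000)
  expect_true(all(abs(emp - fr) <= 3 * se))
  expect_true(all(ev$value > 0))
  expect_equal(nrow(ev), 10000)
  # empty and invalid cases
  expect_equal(nrow(simulateDnaEvents(0, c(1, 0, 0))), 0)
  expect_error(simulateDnaEvents(10, c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(simulateDnaEvents(10, c(1.2, -0.2, 0)), "non-negative")
})
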