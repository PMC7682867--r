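test_that("top-hat background subtraction removes flat offsets and keeps nuclei", {
  fr <- embryoFrame()
  # flat image -> zero
  expect_equal(max(abs(subtractBackground(array(0.3, c(10, 10, 6)), 3, fr))),
               0)
  # zero image -> zero
  expect_equal(max(abs(subtractBackground(array(0, c(10, 10, 6)), 3, fr))), 0)
  # bright ellipsoid on constant offset: offset removed, feature preserved
  dims <- c(24L, 24L, 24L)
  B <- 0.2
  img <- array(B, dims)
  vox <- tubemorph:::ellipsoidVoxels(c(12, 12, 12), c(2, 2, 3), c(1, 0, 0),
                                     fr, dims)
  img[vox] <- B + 0.6
  out <- subtractBackground(img, 4, fr)
  expect_equal(out[vox], img[vox] - B, tolerance = 1e-12)
  inner <- array(FALSE, dims)
  inner[vox] <- TRUE
  expect_equal(max(out[!inner]), 0)
  expect_error(subtractBackground(img, 0.3, embryoFrame(1)), "voxel")
})

test_that("bleach correction equalises per-slice means to the top slice", {
  base <- array(rep(runif(36, 0.2, 0.8), 5), c(6, 6, 5))
  decayed <- sweep(base, 3, 0.9^(0:4), "*")
  out <- bleachCorrect(decayed)
  m <- apply(out, 3, mean)
  expect_true(all(abs(m - m[1]) / m[1] < 0.01))
  # already-equal stack: unchanged up to floating point
  expect_equal(bleachCorrect(base), base, tolerance = 1e-12)
  # single slice: identity
  one <- array(runif(16), c(4, 4, 1))
  expect_identical(bleachCorrect(one), one)
  bad <- base
  bad[, , 3] <- 0
  expect_error(bleachCorrect(bad), "slice 3")
})

test_that("segmentation recovers well-separated phantom nuclei exactly", {
  ph <- smallEpithelial(n = 10, seed = 6)
  seg <- qualityFilter(segmentNuclei(ph))
  expect_equal(nObjects(seg), 10)
  tr <- truthTable(ph)
  dims <- dim(tubeMask(ph))
  frame <- embryoFrameOf(ph)
  found <- matchToTruth(objectTable(seg), tr)
  expect_setequal(found, seq_len(10))   # 100% recall
  for (k in seq_len(nObjects(seg))) {
    gt <- truthVoxels(tr[found[k], ], frame, dims)
    got <- voxelIndices(seg)[[k]]
    jac <- length(intersect(gt, got)) / length(union(gt, got))
    expect_gt(jac, 0.9)
  }
})

test_that("blank images segment to zero objects", {
  fr <- embryoFrame()
  seg <- segmentNuclei(list(dna = array(0, c(10, 10, 5))), fr)
  expect_equal(nObjects(seg), 0)
  expect_true(all(labelVolume(seg) == 0L))
})

test_that("touching nuclei are split by the seeded watershed", {
  fr <- embryoFrame(0.5)
  dims <- c(48L, 32L, 32L)
  img <- array(0.05, dims)
  # centres 1.2 major-diameters apart along x; gap closes after a wide blur
  c1 <- c(5.4, 8, 8)
  c2 <- c1 + c(1.2 * 2 * 3, 0, 0)
  for (cc in list(c1, c2))
    img[tubemorph:::ellipsoidVoxels(cc, c(2, 2, 3), c(1, 0, 0), fr, dims)] <-
      0.8
  img <- array(tubemorph:::.gaussBlur3d(img, dims, 2), dims)
  seg <- segmentNuclei(list(dna = img), fr, minSeedDistance = 5)
  # blur merged them into one foreground component
  fg <- img > 0.2
  expect_equal(max(tubemorph:::.label3d(as.logical(fg), dims)), 1)
  expect_equal(nObjects(seg), 2)
})

test_that("label volumes partition the image", {
  ph <- smallEpithelial(n = 6, seed = 2)
  seg <- segmentNuclei(ph)
  expect_equal(sum(objectTable(seg)$nVoxels) + sum(labelVolume(seg) == 0L),
               prod(dim(labelVolume(seg))))
  expect_equal(objectTable(seg)$nVoxels, lengths(voxelIndices(seg)))
})

test_that("quality filter applies the 95-voxel boundary convention", {
  dims <- c(20L, 20L, 20L)
  seg <- segFromVoxelLists(list(cuboidVoxels(94, dims, x0 = 1),
                                cuboidVoxels(95, dims, z0 = 12)), dims)
  out <- qualityFilter(seg, qualityFilterParams(minVoxels = 95))
  expect_equal(nObjects(out), 1)
  expect_equal(objectTable(out)$nVoxels, 95L)
  expect_equal(sort(unique(as.integer(labelVolume(out)))), c(0L, 1L))
})

test_that("quality filter matches exhaustive predicate evaluation and is idempotent", {
  set.seed(42)
  dims <- c(30L, 30L, 40L)
  nObj <- 20
  sizes <- sample(60:140, nObj, replace = TRUE)
  satu <- runif(nObj)
  lists <- lapply(seq_len(nObj), function(k)
    cuboidVoxels(sizes[k], c(30L, 30L, 2L), x0 = 1) +
      as.integer((2 * (k - 1)) * 30 * 30))
  dnaVals <- lapply(seq_len(nObj), function(k) {
    v <- rep(0.5, sizes[k])
    v[seq_len(floor(satu[k] * sizes[k]))] <- 1.0
    v
  })
  seg <- segFromVoxelLists(lists, dims, dnaValues = dnaVals)
  params <- qualityFilterParams(minVoxels = 95, maxSaturatedFraction = 0.5)
  out <- qualityFilter(seg, params)
  expectKeep <- sizes >= 95 &
    vapply(seq_len(nObj), function(k) mean(dnaVals[[k]] >= 0.98),
           numeric(1)) <= 0.5
  expect_equal(nObjects(out), sum(expectKeep))
  expect_equal(objectTable(out)$nVoxels, as.integer(sizes[expectKeep]))
  # removed + kept = original
  expect_equal(nObjects(out) + sum(!expectKeep), nObjects(seg))
  # idempotence
  out2 <- qualityFilter(out, params)
  expect_equal(objectTable(out2), objectTable(out))
  expect_identical(labelVolume(out2), labelVolume(out))
  # empty in, empty out
  empty <- segFromVoxelLists(list(), dims)
  expect_equal(nObjects(qualityFilter(empty, params)), 0)
})

test_that("positivity classification matches the ground-truth marker flags", {
  ph <- smallEpithelial(n = 15, seed = 8, gfpProb = 0.6,
                        markerProbs = c(edu = 0.5))
  seg <- qualityFilter(segmentNuclei(ph))
  tr <- truthTable(ph)
  found <- matchToTruth(objectTable(seg), tr)
  expect_equal(classifyPositive(seg, "gfp", 0.3), tr$gfp[found])
  expect_equal(classifyPositive(seg, "edu", 0.3), tr$marker_edu[found])
  expect_true(all(!classifyPositive(seg, "dna", 2)))   # above global max
  expect_true(all(classifyPositive(seg, "dna", 0)))    # threshold zero
  expect_error(classifyPositive(seg, "nope", 0.5), "unknown channel")
})
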