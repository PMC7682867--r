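stdConstraints <- djfConstraints(c(80, 120), c(160, 240))

test_that("single-component histograms fit to a pure G1 population", {
  ev <- simulateDnaEvents(20000, c(1, 0, 0), g1Mean = 100, cv = 0.03,
                          seed = 41)
  fit <- fitDeanJettFox(dnaHistogram(ev), stdConstraints)
  fr <- phaseFractions(fit)
  expect_equal(fr[["g1"]], 1, tolerance = 0.02)
  expect_lt(fr[["s"]], 0.02)
  expect_lt(fr[["g2m"]], 0.02)
})

test_that("phase fractions are recovered within 0.03 and the curve conserves mass", {
  truth <- c(0.55, 0.35, 0.10)
  ev <- simulateDnaEvents(20000, truth, g1Mean = 100, cv = 0.03, seed = 42)
  fit <- fitDeanJettFox(dnaHistogram(ev), stdConstraints)
  fr <- phaseFractions(fit)
  expect_lt(max(abs(unname(fr) - truth)), 0.03)
  expect_lt(abs(sum(fit@fittedCurve) - 20000) / 20000, 0.01)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_lt(fit@g1[["mean"]], fit@g2[["mean"]])
})

test_that("phase-fraction recovery is unbiased over repeated simulations", {
  truth <- c(0.6, 0.3, 0.1)
  errs <- t(vapply(1:25, function(s) {
    ev <- simulateDnaEvents(20000, truth, g1Mean = 100, cv = 0.03,
                            seed = 400 + s)
    unname(phaseFractions(fitDeanJettFox(dnaHistogram(ev),
                                         stdConstraints))) - truth
  }, numeric(3)))
  expect_true(all(abs(colMeans(errs)) < 0.02))
})

test_that("the G1 mean stays identifiable under the constraints", {
  for (cv in c(0.03, 0.06)) {
    ev <- simulateDnaEvents(20000, c(0.6, 0.3, 0.1), g1Mean = 100, cv = cv,
                            seed = 43)
    fit <- fitDeanJettFox(dnaHistogram(ev), stdConstraints)
    expect_lt(abs(fit@g1[["mean"]] - 100) / 100, 0.02)
  }
})

test_that("S-phase recovery degrades as the measurement CV grows", {
  sErr <- vapply(c(0.03, 0.06, 0.10), function(cv) {
    errs <- vapply(1:5, function(s) {
      ev <- simulateDnaEvents(20000, c(0.6, 0.3, 0.1), g1Mean = 100,
                              cv = cv, seed = 500 + s)
      fr <- phaseFractions(fitDeanJettFox(dnaHistogram(ev), stdConstraints))
      abs(fr[["s"]] - 0.3)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(sErr) > -0.005))   # non-decreasing up to noise
  expect_gt(sErr[3], sErr[1])
})

test_that("constraint validation and low-count warnings fire", {
  expect_error(djfConstraints(c(120, 80), c(160, 240)), "lo < hi")
  expect_error(djfConstraints(c(80, 120), c(100, 240)), "above g1Range")
  ev <- simulateDnaEvents(20000, c(0.6, 0.3, 0.1), g1Mean = 100, seed = 44)
  expect_error(fitDeanJettFox(dnaHistogram(ev),
                              djfConstraints(c(900, 1000), c(1500, 1600))),
               "does not overlap")
  small <- simulateDnaEvents(300, c(0.6, 0.3, 0.1), seed = 45)
  expect_warning(fitDeanJettFox(dnaHistogram(small), stdConstraints),
                 "300 events")
})

test_that("quadratic S compartment remains a valid fit", {
  ev <- simulateDnaEvents(20000, c(0.5, 0.4, 0.1), g1Mean = 100, cv = 0.03,
                          seed = 46)
  fit <- fitDeanJettFox(dnaHistogram(ev), stdConstraints, sPolyOrder = 2L)
  expect_lt(max(abs(unname(phaseFractions(fit)) - c(0.5, 0.4, 0.1))), 0.05)
})

test_that("phase fraction tables convert and summarise correctly", {
  mkFit <- function(fr) new("DjfFit",
    g1 = c(mean = 100, sd = 3, weight = fr[1]),
    g2 = c(mean = 200, sd = 6, weight = fr[3]), sWeight = fr[2],
    phaseFractions = c(g1 = fr[1], s = fr[2], g2m = fr[3]),
    fittedCurve = numeric(0), rss = 0)
  tab <- phaseFractionTable(mkFit(c(0.5, 0.3, 0.2)))
  expect_equal(unlist(tab$samples[1, c("pctG1", "pctS", "pctG2M")],
                      use.names = FALSE), c(50, 30, 20))
  # identical fits: zero s.e.m.
  tab3 <- phaseFractionTable(list(mkFit(c(0.5, 0.3, 0.2)),
                                  mkFit(c(0.5, 0.3, 0.2)),
                                  mkFit(c(0.5, 0.3, 0.2))))
  expect_true(all(tab3$groups$sem == 0))
  # mixed fits, two groups: hand-computed means
  fits <- list(a1 = mkFit(c(0.6, 0.3, 0.1)), a2 = mkFit(c(0.5, 0.4, 0.1)),
               b1 = mkFit(c(0.4, 0.3, 0.3)))
  tab <- phaseFractionTable(fits, groups = c("a", "a", "b"))
  g1a <- tab$groups[tab$groups$group == "a" & tab$groups$phase == "G1", ]
  expect_equal(g1a$mean, 55)
  expect_equal(g1a$n, 2)
  expect_error(phaseFractionTable(list()), "at least one")
})
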