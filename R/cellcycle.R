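#' Bin DNA-content events into a histogram
#'
#' @param values measured fluorescence values (a.u.), or the data.frame
#'   returned by [simulateDnaEvents()].
#' @param nBins number of equal-width bins.
#' @param limits optional (lo, hi); defaults to the data range padded by 2%.
#' @return a [DnaHistogram-class].
#' @export
dnaHistogram <- function(values, nBins = 256L, limits = NULL) {
  if (is.data.frame(values)) values <- values$value
  if (is.null(limits)) {
    r <- range(values)
    pad <- 0.02 * diff(r)
    limits <- c(r[1] - pad, r[2] + pad)
  }
  edges <- seq(limits[1], limits[2], length.out = nBins + 1)
  counts <- as.numeric(table(cut(values, edges, include.lowest = TRUE)))
  new("DnaHistogram", binEdges = edges, counts = counts,
      nEvents = length(values))
}

# DJF model density on bin centres. S compartment: a polynomial (order 0 =
# flat) on (mu1, mu2) convolved with a Gaussian whose sd interpolates
# sigma1 -> sigma2 across the interval, evaluated by 64-point quadrature.
djfDensity <- function(x, mu1, sigma1, mu2, sigma2, sCoef = NULL, nq = 64L) {
  g1 <- dnorm(x, mu1, sigma1)
  g2 <- dnorm(x, mu2, sigma2)
  u <- mu1 + (seq_len(nq) - 0.5) / nq * (mu2 - mu1)
  t <- (u - mu1) / (mu2 - mu1)
  w <- rep(1, nq)
  if (!is.null(sCoef)) w <- 1 + sCoef[1] * t + sCoef[2] * t^2
  w <- pmax(w, 0)
  w <- w / sum(w)
  sig <- sigma1 + (sigma2 - sigma1) * t
  s <- rowSums(vapply(seq_len(nq),
                      function(j) w[j] * dnorm(x, u[j], sig[j]),
                      numeric(length(x))))
  list(g1 = g1, g2 = g2, s = s)
}

#' Fit the Dean-Jett-Fox model to a DNA-content histogram
#'
#' Deconvolves a univariate DNA-content histogram into G0/G1 and G2/M
#' Gaussian peaks plus a broadened S-phase compartment (flat between the two
#' peak means, convolved with a Gaussian whose width interpolates between
#' the peak widths; an optional second-order polynomial S shape is
#' available). Parameters are fitted by bounded nonlinear least squares on
#' the bin counts, with the G1 mean constrained to `g1Range`, the G2 mean to
#' `g2Range`, and the G2 mean initialised at twice the G1 mean.
#' Initialisation is deterministic: the G1 mean starts at the highest-count
#' bin centre inside `g1Range`, sds at 5% of the means, and component
#' weights from the histogram mass split at the midpoint of the two means.
#'
#' @param hist a [DnaHistogram-class] (>= 500 events recommended; fewer
#'   triggers a warning).
#' @param constraints a [DjfConstraints-class].
#' @param sPolyOrder 0 (default, flat S) or 2 (quadratic S shape).
#' @return a [DjfFit-class] with normalised phase fractions (g1, s, g2m).
#' @examples
#' ev <- simulateDnaEvents(5000, c(0.6, 0.3, 0.1), g1Mean = 100, seed = 1)
#' fit <- fitDeanJettFox(dnaHistogram(ev), djfConstraints(c(80, 120), c(160, 240)))
#' phaseFractions(fit)
#' @export
fitDeanJettFox <- function(hist, constraints, sPolyOrder = 0L) {
  validObject(hist)
  validObject(constraints)
  if (hist@nEvents < 500)
    warning("only ", hist@nEvents, " events; fit may be unstable")
  dx <- diff(hist@binEdges[1:2])
  g1r <- constraints@g1Range
  g2r <- constraints@g2Range
  # extend the support with empty bins across the full constrained window:
  # the instrument recorded no events there, which is what pins absent
  # components (e.g. G2/M in a pure-G1 sample) to zero weight
  counts <- hist@counts
  edges <- hist@binEdges
  lo <- min(edges[1], max(0, 0.6 * g1r[1]))
  hi <- max(edges[length(edges)], 1.35 * g2r[2])
  nLo <- ceiling((edges[1] - lo) / dx)
  nHi <- ceiling((hi - edges[length(edges)]) / dx)
  edges <- c(edges[1] - rev(seq_len(nLo)) * dx, edges,
             edges[length(edges)] + seq_len(nHi) * dx)
  counts <- c(rep(0, nLo), counts, rep(0, nHi))
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  inG1 <- which(mid >= g1r[1] & mid <= g1r[2])
  if (!length(inG1) || sum(counts[inG1]) == 0)
    stop("g1Range does not overlap the histogram support")
  mu1 <- mid[inG1[which.max(counts[inG1])]]
  mu2 <- min(max(2 * mu1, g2r[1]), g2r[2])
  sigma1 <- 0.05 * mu1
  sigma2 <- 0.05 * mu2
  cut <- (mu1 + mu2) / 2
  nBelow <- sum(counts[mid < cut])
  nAbove <- hist@nEvents - nBelow
  start <- c(mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
             A1 = 0.8 * nBelow, A2 = 0.8 * nAbove,
             As = 0.2 * hist@nEvents)
  lower <- c(g1r[1], dx, g2r[1], dx, 0, 0, 0)
  upper <- c(g1r[2], 0.25 * mean(g1r), g2r[2], 0.25 * mean(g2r),
             rep(2 * hist@nEvents, 3))
  quad <- sPolyOrder == 2
  if (quad) {
    start <- c(start, c1 = 0, c2 = 0)
    lower <- c(lower, -2, -2)
    upper <- c(upper, 2, 2)
  }
  modelCounts <- function(p) {
    dens <- djfDensity(mid, p[["mu1"]], p[["sigma1"]], p[["mu2"]],
                       p[["sigma2"]],
                       sCoef = if (quad) c(p[["c1"]], p[["c2"]]) else NULL)
    dx * (p[["A1"]] * dens$g1 + p[["A2"]] * dens$g2 + p[["As"]] * dens$s)
  }
  fit <- minpack.lm::nls.lm(par = start,
    fn = function(p) counts - modelCounts(p),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  curve <- modelCounts(p)
  wts <- c(g1 = p[["A1"]], s = p[["As"]], g2m = p[["A2"]])
  fr <- wts / sum(wts)
  new("DjfFit",
      g1 = c(mean = p[["mu1"]], sd = p[["sigma1"]], weight = fr[["g1"]]),
      g2 = c(mean = p[["mu2"]], sd = p[["sigma2"]], weight = fr[["g2m"]]),
      sWeight = fr[["s"]], phaseFractions = fr,
      fittedCurve = curve[(nLo + 1):(nLo + length(hist@counts))],
      rss = sum((counts - curve)^2))
}

#' Tabulate phase fractions across samples and groups
#'
#' Converts per-sample Dean-Jett-Fox fits to percentages on the 0-100 scale
#' and summarises each group as mean +/- s.e.m. per phase.
#'
#' @param fits list of [DjfFit-class] objects (optionally named).
#' @param groups per-sample group labels (defaults to one group).
#' @return list with `samples` (sample, group, pctG1, pctS, pctG2M) and
#'   `groups` (group, phase, mean, sem, n).
#' @export
phaseFractionTable <- function(fits, groups = NULL) {
  if (is(fits, "DjfFit")) fits <- list(fits)
  if (length(fits) < 1) stop("need at least one fit")
  if (is.null(groups)) groups <- rep("all", length(fits))
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("sample", seq_along(fits))
  samples <- data.frame(sample = nm, group = groups,
    pctG1 = vapply(fits, function(f) 100 * f@phaseFractions[["g1"]],
                   numeric(1)),
    pctS = vapply(fits, function(f) 100 * f@phaseFractions[["s"]],
                  numeric(1)),
    pctG2M = vapply(fits, function(f) 100 * f@phaseFractions[["g2m"]],
                    numeric(1)))
  long <- do.call(rbind, lapply(c("pctG1", "pctS", "pctG2M"), function(ph)
    data.frame(group = samples$group, phase = sub("pct", "", ph),
               value = samples[[ph]])))
  groupsTab <- do.call(rbind, lapply(split(long, list(long$group, long$phase),
                                           drop = TRUE), function(d)
    data.frame(group = d$group[1], phase = d$phase[1], mean = mean(d$value),
               sem = if (nrow(d) > 1) sd(d$value) / sqrt(nrow(d)) else 0,
               n = nrow(d))))
  rownames(groupsTab) <- NULL
  list(samples = samples, groups = groupsTab)
}
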