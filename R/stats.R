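#' Mann-Whitney U test
#'
#' U from rank sums with midrank tie handling; the reported U is that of the
#' first group (`U_a + U_b = n_a * n_b`). The two-sided p-value is exact
#' (full enumeration of the null distribution) when the smaller group has at
#' most 8 values and there are no ties, and a normal approximation with tie
#' correction otherwise.
#'
#' @param groupA,groupB numeric vectors, both non-empty.
#' @return list with `U`, `p`, and `method` ("exact" or "normal").
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  na <- length(groupA)
  nb <- length(groupB)
  r <- rank(c(groupA, groupB))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(groupA, groupB))
  hasTies <- any(ties > 1)
  if (!hasTies && min(na, nb) <= 8) {
    # exact two-sided p from the null distribution of U
    pLo <- pwilcox(U, na, nb)
    pHi <- 1 - pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(pLo, pHi))
    method <- "exact"
  } else {
    N <- na + nb
    mu <- na * nb / 2
    tieTerm <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * (N + 1 - tieTerm))
    z <- if (sigma > 0) (U - mu) / sigma else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Per-embryo marker-positive fractions with a group summary
#'
#' Computes the percentage of marker-positive cells among the GFP+ cells of
#' each embryo, then the group mean and s.e.m. across embryos (the embryo is
#' the unit of replication for count-based metrics). Embryos without GFP+
#' cells are excluded with a warning.
#'
#' @param positive logical per-cell marker flags.
#' @param embryo per-cell embryo identifiers.
#' @param gfp logical per-cell GFP flags (default: all TRUE, i.e. the cells
#'   are already the GFP+ population).
#' @return list with `perEmbryo` (embryo, nGfp, pctPositive), `mean`, `sem`
#'   and `n` (number of embryos summarised); percentages on the 0-100 scale.
#' @export
fractionPositive <- function(positive, embryo, gfp = TRUE) {
  n <- length(positive)
  gfp <- rep_len(gfp, n)
  if (length(embryo) != n) stop("every cell must be assigned to an embryo")
  ids <- unique(embryo)
  rows <- lapply(ids, function(e) {
    sel <- embryo == e & gfp
    if (!any(sel)) {
      warning("embryo '", e, "' has no GFP+ cells; excluded")
      return(NULL)
    }
    data.frame(embryo = e, nGfp = sum(sel),
               pctPositive = 100 * mean(positive[sel]))
  })
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("no embryo with GFP+ cells")
  list(perEmbryo = per, mean = mean(per$pctPositive),
       sem = if (nrow(per) > 1) sd(per$pctPositive) / sqrt(nrow(per)) else 0,
       n = nrow(per))
}
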