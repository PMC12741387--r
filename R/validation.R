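## Spearman rank correlation, self-implemented so the statistic the
## pipeline reports can be checked against an independent oracle
## (rank-then-Pearson via base R) in the test suite.

## Midranks: average rank for ties, computed from the sort order.
.midranks <- function(x) {
  n <- length(x)
  o <- order(x)
  r <- numeric(n)
  i <- 1L
  xs <- x[o]
  while (i <= n) {
    j <- i
    while (j < n && xs[j + 1L] == xs[i]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes Spearman's rho as the Pearson correlation of the midranks of
#' `x` and `y` (average ranks for ties), with a two-sided p-value from
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.  At `|rho| = 1` the approximation degenerates and
#' the p-value is reported at the distribution's limit (the smallest
#' representable positive number, keeping it inside (0, 1\]).  For small
#' samples an exact permutation p-value is available.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite values.
#' @param exact logical; if `TRUE` (allowed for `n <= 10`), the p-value is
#'   computed by full enumeration of the `n!` permutations of `y`.
#' @return A [CorrelationResult-class] with slots `rho`, `p.value`, `n`.
#' @examples
#' spearmanRank(1:4, c(10, 20, 30, 40))  # rho = 1
#' @export
spearmanRank <- function(x, y, exact = FALSE) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  rho <- .rankPearson(x, y)
  if (exact) {
    if (n > 10L)
      stop("exact permutation p-value limited to n <= 10", call. = FALSE)
    perms <- .permutations(n)
    stat <- apply(perms, 1L, function(p) .rankPearson(x, y[p]))
    p <- mean(abs(stat) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  new("CorrelationResult", rho = rho, p.value = p, n = as.integer(n))
}

## Pearson correlation of midranks via the sum formula.
.rankPearson <- function(x, y) {
  rx <- .midranks(x)
  ry <- .midranks(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx2 <- sum(dx^2)
  sy2 <- sum(dy^2)
  if (sx2 == 0 || sy2 == 0)
    stop("zero variance in ranks: correlation undefined", call. = FALSE)
  r <- sum(dx * dy) / sqrt(sx2 * sy2)
  ## perfectly (anti)concordant ranks can land a few ulps off +-1 through
  ## the sqrt; snap so perfect monotone data report exactly +-1
  if (abs(r) > 1 - 8 * .Machine$double.eps) r <- sign(r)
  max(-1, min(1, r))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Validate the EF against a species-richness layer
#'
#' Reproduces the pipeline's sanity check: the per-ecoregion zonal mean of
#' the species-richness raster (same pixel-center rule as the indicator
#' stage) is paired with the min-scaled EF of each retained ecoregion and
#' passed to the Spearman rank correlation.  A positive rho indicates that
#' ecoregions weighted as more ecologically important also carry higher
#' species richness.
#'
#' @param ef_table data.frame from [computeEFTable()].
#' @param richness continuous [GridRaster-class].
#' @param regions an [EcoregionSet-class].
#' @return A [CorrelationResult-class].
#' @export
validateEF <- function(ef_table, richness, regions) {
  stopifnot(is(regions, "EcoregionSet"))
  if (nrow(ef_table) == 0L)
    stop("ef_table is empty", call. = FALSE)
  zm <- zonalMean(richness, regions)
  rich <- zm[as.character(ef_table$eco_id)]
  ok <- !is.na(rich)
  if (sum(ok) < 3L)
    stop("fewer than 3 ecoregions with both EF and richness", call. = FALSE)
  spearmanRank(ef_table$ef[ok], as.numeric(rich[ok]))
}
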