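#' Min-max normalization to [0, 1]
#'
#' Maps `x` to `(x - min) / (max - min)` so the smallest value becomes
#' exactly 0 and the largest exactly 1; rank order is preserved.  The
#' scale statistics come from the supplied values themselves, i.e. from
#' the set of ecoregions being normalized.
#'
#' Degenerate spread (`max == min`) is an error, not a silent fill: a
#' constant indicator column would make the factor undefined.
#'
#' @param values numeric vector of at least two finite values.
#' @return Numeric vector in \[0, 1\] of the same length.
#' @examples
#' minmaxScale(c(2, 4, 6))   # 0, 0.5, 1
#' @export
minmaxScale <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("need at least two values to normalize", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (hi == lo)
    stop("degenerate spread: max == min, normalization undefined",
         call. = FALSE)
  (values - lo) / (hi - lo)
}

#' Normalize the four indicator columns of an indicator table
#'
#' Min-max normalizes `sgf_raw`, `sw_raw`, `gep_raw` and `sra_raw`
#' independently, computing the scale over valid rows only (invalid
#' ecoregions are excluded before the factor is computed, so they must
#' not distort the scale).  Invalid rows keep `NA` in the normalized
#' columns.
#'
#' @param tab data.frame from [assembleIndicators()].
#' @return `tab` with columns `sgf`, `sw`, `gep`, `sra` added.
#' @export
normalizeIndicators <- function(tab) {
  need <- c("eco_id", "sgf_raw", "sw_raw", "gep_raw", "sra_raw", "valid")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("indicator table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ok <- which(tab$valid)
  if (length(ok) < 2L)
    stop("need at least two valid ecoregions to normalize", call. = FALSE)
  for (ind in c("sgf", "sw", "gep", "sra")) {
    raw <- tab[[paste0(ind, "_raw")]]
    norm <- rep(NA_real_, nrow(tab))
    norm[ok] <- tryCatch(minmaxScale(raw[ok]), error = function(e)
      stop("indicator '", ind, "': ", conditionMessage(e), call. = FALSE))
    tab[[ind]] <- norm
  }
  tab
}
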