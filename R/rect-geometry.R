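## Exact geometry kernel for axis-aligned rectangle polygons.
##
## Every geometry handled by this package is a union of axis-aligned
## rectangles in lon/lat, stored as an n x 4 matrix with columns
## xmin, ymin, xmax, ymax.  Rectangles admit closed-form areas,
## intersections and unions (by coordinate compression), which is what
## makes every downstream stage of the pipeline testable against an
## analytic oracle.

## Authalic Earth radius [m]; spherical areas computed with it agree with
## equal-area projections of the real datasets to well under the tolerances
## used anywhere in the package.
.EARTH_RADIUS <- 6371007.2

.emptyRects <- function() {
  matrix(numeric(0), ncol = 4L,
         dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax")))
}

.asRects <- function(m) {
  if (is.null(m) || length(m) == 0L) return(.emptyRects())
  m <- matrix(as.numeric(m), ncol = 4L)
  colnames(m) <- c("xmin", "ymin", "xmax", "ymax")
  m
}

.checkRects <- function(m, what = "rectangle matrix") {
  if (!is.matrix(m) || ncol(m) != 4L || !is.numeric(m))
    stop(what, " must be a numeric matrix with 4 columns", call. = FALSE)
  if (anyNA(m) || any(!is.finite(m)))
    stop(what, " contains non-finite coordinates", call. = FALSE)
  if (any(m[, 3L] <= m[, 1L]) || any(m[, 4L] <= m[, 2L]))
    stop(what, " has degenerate rectangles (max <= min)", call. = FALSE)
  invisible(m)
}

## Map lon/lat rectangles into the cylindrical equal-area frame
## (x = R * lon_rad, y = R * sin(lat_rad)).  Axis-aligned rectangles map to
## axis-aligned rectangles and planar area in the image equals spherical
## surface area exactly, so union/intersection arithmetic stays exact.
.equalAreaRects <- function(m) {
  if (nrow(m) == 0L) return(m)
  out <- m
  out[, c(1L, 3L)] <- .EARTH_RADIUS * m[, c(1L, 3L)] * pi / 180
  out[, c(2L, 4L)] <- .EARTH_RADIUS * sin(m[, c(2L, 4L)] * pi / 180)
  out
}

.frameRects <- function(m, planar) {
  if (planar) m else .equalAreaRects(m)
}

.rectAreas <- function(m) {
  if (nrow(m) == 0L) return(numeric(0))
  unname((m[, 3L] - m[, 1L]) * (m[, 4L] - m[, 2L]))
}

## Area of the union of a set of rectangles, exact via coordinate
## compression: overlay all x and y breakpoints, mark which elementary
## cells are covered, sum their areas.
.rectUnionArea <- function(m) {
  n <- nrow(m)
  if (n == 0L) return(0)
  if (n == 1L) return(.rectAreas(m))
  xs <- sort(unique(c(m[, 1L], m[, 3L])))
  ys <- sort(unique(c(m[, 2L], m[, 4L])))
  nx <- length(xs) - 1L
  ny <- length(ys) - 1L
  covered <- matrix(FALSE, nrow = nx, ncol = ny)
  for (i in seq_len(n)) {
    ix <- which(xs >= m[i, 1L] & xs < m[i, 3L])
    iy <- which(ys >= m[i, 2L] & ys < m[i, 4L])
    covered[ix, iy] <- TRUE
  }
  dx <- diff(xs)
  dy <- diff(ys)
  sum(outer(dx, dy) * covered)
}

## Pairwise clip of two rectangle sets; returns the rectangles of the
## intersection (possibly overlapping if inputs self-overlap).
.rectClip <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(.emptyRects())
  out <- vector("list", nrow(a) * nrow(b))
  k <- 0L
  for (i in seq_len(nrow(a))) {
    xmin <- pmax(a[i, 1L], b[, 1L])
    ymin <- pmax(a[i, 2L], b[, 2L])
    xmax <- pmin(a[i, 3L], b[, 3L])
    ymax <- pmin(a[i, 4L], b[, 4L])
    keep <- xmax > xmin & ymax > ymin
    if (any(keep)) {
      k <- k + 1L
      out[[k]] <- cbind(xmin[keep], ymin[keep], xmax[keep], ymax[keep])
    }
  }
  if (k == 0L) return(.emptyRects())
  .asRects(do.call(rbind, out[seq_len(k)]))
}

## Area of intersection(A, union(B)) — clip then union, so self-overlaps
## in B are dissolved and never double-counted.
.rectIntersectionArea <- function(a, b) {
  .rectUnionArea(.rectClip(a, b))
}
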