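#' Build a contour tibble from coordinates
#'
#' A contour is an ordered, implicitly closed polygon of boundary points for
#' one cell, stored as a tibble with columns `x` and `y` (physical units,
#' x right / y up). The closing edge from the last point back to the first is
#' implicit and the last point must not repeat the first.
#'
#' @param x,y Numeric coordinate vectors of equal length (>= 3), or `x` may be
#'   a two-column matrix / data frame with columns `x` and `y`.
#' @param cell_id Optional integer label of the source cell.
#' @return A `loco_contour` tibble with columns `x`, `y`.
#' @export
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 65)[-65]
#' circ <- contour_xy(cos(theta), sin(theta))
#' contour_area(circ)
contour_xy <- function(x, y = NULL, cell_id = NA_integer_) {
  if (is.null(y)) {
    df <- as.data.frame(x)
    if (!all(c("x", "y") %in% names(df))) {
      names(df)[1:2] <- c("x", "y")
    }
    x <- df$x
    y <- df$y
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) >= 2 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]
    y <- y[-length(y)]
  }
  # drop consecutive duplicate vertices (zero-length edges)
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    abort("a contour needs at least 3 distinct points")
  }
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("loco_contour", class(out))
  attr(out, "cell_id") <- cell_id
  out
}

#' Signed area, perimeter and centroid of a contour
#'
#' `contour_area()` is the shoelace signed area (positive for
#' counter-clockwise traversal in the x-right / y-up convention).
#'
#' @param contour A contour tibble (see [contour_xy()]).
#' @return A scalar.
#' @export
contour_area <- function(contour) {
  x <- contour$x
  y <- contour$y
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @rdname contour_area
#' @export
contour_perimeter <- function(contour) {
  x <- contour$x
  y <- contour$y
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

segment_lengths <- function(contour) {
  x <- contour$x
  y <- contour$y
  sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Checks all non-adjacent edge pairs for proper or improper crossings, with a
#' bounding-box prefilter. Shared endpoints of adjacent edges are allowed.
#'
#' @param contour A contour tibble.
#' @return `TRUE` if no two non-adjacent edges intersect.
#' @export
is_simple_contour <- function(contour) {
  x <- contour$x
  y <- contour$y
  n <- length(x)
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  xmin <- pmin(x, x2); xmax <- pmax(x, x2)
  ymin <- pmin(y, y2); ymax <- pmax(y, y2)
  # candidate pairs: bounding boxes overlap, edges not adjacent
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    if (i == 1) j <- j[j != n] # edge n is adjacent to edge 1
    j <- j[xmin[j] <= xmax[i] & xmax[j] >= xmin[i] &
             ymin[j] <= ymax[i] & ymax[j] >= ymin[i]]
    if (!length(j)) next
    d1 <- (x2[i] - x[i]) * (y[j] - y[i]) - (y2[i] - y[i]) * (x[j] - x[i])
    d2 <- (x2[i] - x[i]) * (y2[j] - y[i]) - (y2[i] - y[i]) * (x2[j] - x[i])
    d3 <- (x2[j] - x[j]) * (y[i] - y[j]) - (y2[j] - y[j]) * (x[i] - x[j])
    d4 <- (x2[j] - x[j]) * (y2[i] - y[j]) - (y2[j] - y[j]) * (x2[i] - x[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
    # collinear overlap (touching counts as non-simple only if crossing);
    # treat exact touching of non-adjacent edges as non-simple too
    if (any(d1 == 0 & d2 == 0 & d3 == 0 & d4 == 0 &
              pmin(xmax[i], xmax[j]) >= pmax(xmin[i], xmin[j]) &
              pmin(ymax[i], ymax[j]) >= pmax(ymin[i], ymin[j]))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Resample a contour at uniform arc-length spacing
#'
#' Places `n_points` points equally spaced in cumulative arc length along the
#' polygon, starting at the first vertex. Orientation and perimeter are
#' preserved (perimeter to within one part in 1e4 for contours sampled densely
#' relative to their curvature).
#'
#' @param contour A contour tibble.
#' @param n_points Number of output points (>= 16).
#' @return A contour tibble with `n_points` rows.
#' @export
resample_contour <- function(contour, n_points = 1000) {
  if (n_points < 16) abort("n_points must be >= 16")
  x <- c(contour$x, contour$x[1])
  y <- c(contour$y, contour$y[1])
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  total <- s[length(s)]
  if (total <= 0) abort("degenerate contour: zero perimeter")
  si <- seq(0, total, length.out = n_points + 1)[-(n_points + 1)]
  out <- contour_xy(approx(s, x, xout = si, ties = "ordered")$y,
                    approx(s, y, xout = si, ties = "ordered")$y,
                    cell_id = attr(contour, "cell_id"))
  attr(out, "scale") <- attr(contour, "scale")
  out
}

#' Canonicalise a contour: counter-clockwise orientation, area pi
#'
#' Reverses clockwise contours and rescales uniformly about the origin so the
#' enclosed area equals pi, i.e. lengths are expressed in units of the
#' equivalent-circle radius. With this normalisation an L-value of 0.15 reads
#' directly as a radial lobe amplitude of 15% of the cell radius. The centroid
#' is deliberately not moved: translation is absorbed by the elliptic Fourier
#' offset term.
#'
#' @param contour A contour tibble.
#' @param check_simple If `TRUE` (default), error on self-intersecting input.
#' @return The canonicalised contour; the applied multiplicative scale factor
#'   is stored in `attr(, "scale")` (and compounds with any previous scale).
#' @export
#' @examples
#' sq <- contour_xy(c(0, 0, 2, 2), c(0, 2, 2, 0)) # clockwise square
#' can <- canonicalise_contour(sq)
#' contour_area(can) # pi
canonicalise_contour <- function(contour, check_simple = TRUE) {
  a <- contour_area(contour)
  if (a < 0) {
    contour <- contour_xy(rev(contour$x), rev(contour$y),
                          cell_id = attr(contour, "cell_id"))
    a <- -a
  }
  if (a == 0) abort("degenerate contour: zero area")
  if (check_simple && !is_simple_contour(contour)) {
    abort("contour is self-intersecting; cannot canonicalise")
  }
  s <- sqrt(pi / a)
  out <- contour_xy(contour$x * s, contour$y * s,
                    cell_id = attr(contour, "cell_id"))
  prev <- attr(contour, "scale")
  attr(out, "scale") <- if (is.null(prev)) s else prev * s
  out
}

#' @rdname canonicalise_contour
#' @export
contour_scale <- function(contour) {
  s <- attr(contour, "scale")
  if (is.null(s)) 1 else s
}

#' Read and write contour CSV files
#'
#' The on-disk format is a plain CSV with header `x,y`, one vertex per row,
#' closing edge implicit.
#'
#' @param path File path.
#' @param cell_id Optional cell label to attach on read.
#' @export
read_contour_csv <- function(path, cell_id = NA_integer_) {
  df <- read.csv(path, comment.char = "#")
  contour_xy(df$x, df$y, cell_id = cell_id)
}

#' @rdname read_contour_csv
#' @param contour A contour tibble to write.
#' @export
write_contour_csv <- function(contour, path) {
  write.csv(data.frame(x = contour$x, y = contour$y), path, row.names = FALSE)
  invisible(path)
}
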