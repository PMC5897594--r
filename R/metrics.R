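#' Pixel-centre analysis grids
#'
#' A grid is a list with pixel-centre coordinate vectors `x` (ascending) and
#' `y`. For synthetic shapes the default grid is square, `n x n`, with the
#' shape spanning about `span` of the field; for image-derived cells the
#' natural grid is the source image itself (see [analyze_image()]).
#'
#' @param contour A contour tibble the grid should cover.
#' @param n Grid side length in pixels (default 512).
#' @param span Fraction of the field the shape extent occupies (default 0.6).
#' @export
make_raster_grid <- function(contour, n = 512, span = 0.6) {
  cx <- (max(contour$x) + min(contour$x)) / 2
  cy <- (max(contour$y) + min(contour$y)) / 2
  half <- max(max(contour$x) - min(contour$x),
              max(contour$y) - min(contour$y)) / 2 / span
  list(x = seq(cx - half, cx + half, length.out = n),
       y = seq(cy - half, cy + half, length.out = n))
}

#' Rasterise a closed contour on a pixel-centre grid
#'
#' Even-odd scanline fill sampled at pixel centres: a pixel is inside when a
#' leftward ray from its centre crosses the polygon an odd number of times.
#'
#' @param contour A contour tibble.
#' @param grid A grid from [make_raster_grid()] (or list with `x`, `y`).
#' @return A logical matrix indexed `[x, y]`.
#' @export
rasterise_contour <- function(contour, grid) {
  x1 <- contour$x; y1 <- contour$y
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  gx <- grid$x; gy <- grid$y
  out <- matrix(FALSE, length(gx), length(gy))
  if (!length(x1)) return(out)
  lo <- pmin(y1, y2); hi <- pmax(y1, y2)
  # rows each edge crosses (half-open [lo, hi) rule avoids double counting)
  i0 <- findInterval(lo, gy, left.open = TRUE) + 1
  i1 <- findInterval(hi, gy, left.open = TRUE)
  valid <- i1 >= i0
  if (!any(valid)) return(out)
  reps <- pmax(0L, i1 - i0 + 1L)
  e <- rep.int(seq_along(x1), reps)
  ri <- unlist(lapply(which(valid), function(k) i0[k]:i1[k]), use.names = FALSE)
  yc <- gy[ri]
  xc <- x1[e] + (yc - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
  ord <- order(ri, xc)
  ri <- ri[ord]; xc <- xc[ord]
  splits <- split(xc, ri)
  for (nm in names(splits)) {
    cross <- splits[[nm]]
    cnt <- findInterval(gx, cross)
    out[, as.integer(nm)] <- (cnt %% 2L) == 1L
  }
  out
}

#' Areal mismatch between a mask and a reconstruction
#'
#' The XOR (symmetric difference) area between the original cell mask and a
#' reconstructed contour rasterised on the same grid, as a fraction of the
#' original cell area.
#'
#' @param original Logical mask of the original cell (matrix).
#' @param reconstruction A contour tibble, or a logical mask already on the
#'   grid.
#' @param grid The pixel-centre grid (required when `reconstruction` is a
#'   contour).
#' @return A scalar fraction (0 for identical shapes; 1 for an empty
#'   reconstruction).
#' @export
xor_difference <- function(original, reconstruction, grid = NULL) {
  n_orig <- sum(original)
  if (n_orig == 0) abort("empty original mask")
  recon <- if (is.matrix(reconstruction)) {
    reconstruction
  } else {
    if (is.null(grid)) abort("grid required to rasterise the reconstruction")
    rasterise_contour(reconstruction, grid)
  }
  sum(xor(original, recon)) / n_orig
}

#' XOR, marginal-difference and cut-off profile of a cell
#'
#' Computes `XOR(n)` for n = 1..`n_max` from truncated lobe-mode
#' reconstructions rasterised against the original shape, with the
#' convention `XOR(0) = 1` (empty reconstruction), so that the marginal
#' difference `md(n) = XOR(n-1) - XOR(n)` decomposes the explained area
#' completely. The smallest n at which XOR reaches zero on the analysis grid
#' is recorded as the natural mode cut-off.
#'
#' @param fit A `loco_efa` object.
#' @param n_max Largest mode to include (default: all reported modes).
#' @param grid Pixel-centre grid; default is a 512 x 512 synthetic grid with
#'   the shape spanning ~60% of the field.
#' @param original Logical mask of the original cell on `grid`; by default
#'   the fit's own (canonical) contour is rasterised. For image-derived
#'   cells pass the segmented pixel mask and the source grid, plus
#'   `to_grid = function(ct) ...` mapping canonical contours back to grid
#'   units.
#' @param to_grid Optional function applied to each reconstruction before
#'   rasterisation (e.g. undoing the area normalisation).
#' @return An `xor_profile` tibble with columns `n` (0..n_max), `xor`,
#'   `marginal`; attributes `cutoff` and `cd`.
#' @export
xor_profile <- function(fit, n_max = max(fit$spectrum$l), grid = NULL,
                        original = NULL, to_grid = identity) {
  if (is.null(grid)) grid <- make_raster_grid(fit$contour)
  if (is.null(original)) original <- rasterise_contour(fit$contour, grid)
  n_samples <- ceiling(4 * sqrt(length(grid$x)^2 + length(grid$y)^2))
  xors <- c(1, vapply(seq_len(n_max), function(n) {
    rec <- to_grid(loco_reconstruct(fit, n_use = n, n_samples = n_samples))
    xor_difference(original, rec, grid)
  }, numeric(1)))
  out <- tibble::tibble(
    n = 0:n_max,
    xor = xors,
    marginal = c(NA_real_, -diff(xors))
  )
  class(out) <- c("xor_profile", class(out))
  zero <- which(out$xor == 0 & out$n >= 1)
  attr(out, "cutoff") <- if (length(zero)) out$n[zero[1]] else NA_integer_
  attr(out, "cd") <- cumulative_difference(out)
  out
}

#' Cumulative difference
#'
#' The area under the XOR curve summed from mode 2 onwards,
#' `cd = sum_{n=2}^{N} XOR(n)`: a scalar measure of lobe richness that grows
#' when protrusions become more numerous or larger. Mode 1 is excluded so
#' that mere size/anisotropy does not register.
#'
#' @param profile An `xor_profile` tibble.
#' @param n_max Upper mode limit (default 50; terms beyond the computed
#'   profile or past the cut-off contribute 0).
#' @return A scalar.
#' @export
cumulative_difference <- function(profile, n_max = 50) {
  if (max(profile$n) < 2) abort("profile must reach at least mode 2")
  sum(profile$xor[profile$n >= 2 & profile$n <= n_max])
}

#' Mode with the largest marginal difference
#'
#' @param profile An `xor_profile` tibble.
#' @param min_mode Smallest mode considered (default 2).
#' @export
argmax_marginal <- function(profile, min_mode = 2) {
  sub <- profile[profile$n >= min_mode & !is.na(profile$marginal), ]
  sub$n[which.max(sub$marginal)]
}

#' Shannon entropy of a lobe spectrum
#'
#' `E = -sum f_l log2 f_l` with `f_l = L_l / sum(L)` over modes 1..`l_max`,
#' the relative proportion of each lobe amplitude. Zero-amplitude modes
#' contribute nothing; a single-mode spectrum has E = 0 and a spectrum
#' uniform over k modes has E = log2 k bits. A squared-amplitude variant is
#' available via `weights = "power"`.
#'
#' @param spectrum A `loco_spectrum` tibble or `loco_efa` object.
#' @param l_max Number of modes analysed (default 50).
#' @param weights `"amplitude"` (default) uses `L_l`; `"power"` uses
#'   `L_l^2`.
#' @return Entropy in bits.
#' @export
shape_entropy <- function(spectrum, l_max = 50,
                          weights = c("amplitude", "power")) {
  weights <- match.arg(weights)
  if (inherits(spectrum, "loco_efa")) spectrum <- spectrum$spectrum
  L <- spectrum$L[spectrum$l <= l_max]
  if (weights == "power") L <- L^2
  tot <- sum(L)
  if (tot <= 0) abort("all-zero spectrum: entropy undefined")
  f <- L[L > 0] / tot
  -sum(f * log2(f))
}
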