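#' Gielis superformula shapes
#'
#' Generates closed contours from the superformula
#' `r(theta) = (|cos(m theta / 4) / a|^{n2} + |sin(m theta / 4) / b|^{n3})^{-1/n1}`,
#' sampled at uniform theta, then resampled by arc length and canonicalised
#' to area pi. With `n2 = n3` and integer `m` the shape has exact m-fold
#' symmetry, so its lobe spectrum is selective: only modes that are multiples
#' of m (plus mode 1) are populated.
#'
#' @param m Symmetry count (0 gives a circle).
#' @param n1,n2,n3 Superformula exponents (`n1 != 0`).
#' @param a,b Axis scales (> 0).
#' @param n_points Output sampling density (uniform in theta: polar shapes
#'   keep their native angular parameterisation, see [efa()]).
#' @param canonicalise If `TRUE` (default) normalise to area pi.
#' @return A contour tibble.
#' @export
#' @examples
#' star <- superformula_shape(m = 6, n1 = 6, n2 = 14, n3 = 14)
#' dominant_mode(loco_efa(star, n_modes = 20, normalise = FALSE))
superformula_shape <- function(m, n1, n2, n3, a = 1, b = 1,
                               n_points = 1000, canonicalise = TRUE) {
  if (a <= 0 || b <= 0) abort("a and b must be positive")
  if (n1 == 0) abort("n1 must be nonzero")
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  r <- (abs(cos(m * theta / 4) / a)^n2 +
          abs(sin(m * theta / 4) / b)^n3)^(-1 / n1)
  if (!all(is.finite(r)) || any(r <= 0)) {
    abort("superformula parameters yield non-finite or non-positive radius")
  }
  ct <- contour_xy(r * cos(theta), r * sin(theta))
  if (canonicalise) {
    ct <- canonicalise_contour(ct, check_simple = FALSE)
  }
  ct
}

#' Curated superformula star parameters
#'
#' A version-pinned table of parameter sets producing k-lobed stars
#' (k = 3..9) at three protrusion amplitudes. The contract is behavioural:
#' the dominant lobe mode of each shape equals `lobes`, and amplitude level
#' orders the L peak height.
#'
#' @return A tibble with columns `lobes`, `amplitude` ("low", "medium",
#'   "high"), `m`, `n1`, `n2`, `n3`.
#' @export
star_shape_params <- function() {
  grid <- expand.grid(lobes = 3:9,
                      amplitude = c("low", "medium", "high"),
                      stringsAsFactors = FALSE)
  n2 <- c(low = 6, medium = 14, high = 30)[grid$amplitude]
  tibble::tibble(
    lobes = grid$lobes, amplitude = grid$amplitude,
    m = grid$lobes, n1 = 6, n2 = unname(n2), n3 = unname(n2)
  )
}

#' @rdname star_shape_params
#' @param lobes Number of protrusions (3..9).
#' @param amplitude One of "low", "medium", "high".
#' @param n_points Sampling density.
#' @export
star_shape <- function(lobes, amplitude = "medium", n_points = 1000) {
  tab <- star_shape_params()
  row <- tab[tab$lobes == lobes & tab$amplitude == amplitude, ]
  if (nrow(row) != 1) abort("no curated parameters for this lobes/amplitude combination")
  superformula_shape(row$m, row$n1, row$n2, row$n3, n_points = n_points)
}

#' Cosine-lobed circle
#'
#' The calibration fixture `r(theta) = 1 + epsilon cos(l theta)`,
#' canonicalised to area pi. After area normalisation its lobe spectrum obeys
#' `L_l = epsilon` up to an epsilon^2-order correction, which is what makes
#' L values readable as fraction-of-radius amplitudes.
#'
#' @param epsilon Radial modulation amplitude, in `[0, 1)`.
#' @param lobes Lobe count l (>= 2).
#' @param n_points Sampling density.
#' @param phase Angular offset of the modulation (radians).
#' @return A contour tibble.
#' @export
cosine_lobed_circle <- function(epsilon, lobes, n_points = 1000, phase = 0) {
  if (epsilon < 0 || epsilon >= 1) abort("epsilon must be in [0, 1)")
  if (epsilon > 0 && lobes < 2) abort("lobes must be >= 2")
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  r <- 1 + epsilon * cos(lobes * (theta - phase))
  ct <- contour_xy(r * cos(theta), r * sin(theta))
  canonicalise_contour(ct, check_simple = FALSE)
}

#' Synthetic confluent tissue label image
#'
#' Seeded-Voronoi raster: `n_cells` seeds are placed on a jittered hexagonal
#' grid and every pixel inside the field is labelled by its nearest seed,
#' giving convex, 4-connected confluent regions surrounded by a background
#' margin. Reproducible for a fixed seed.
#'
#' @param n_cells Number of cells (>= 1).
#' @param field_size Side length of the square field in pixels.
#' @param jitter Seed displacement as a fraction of the seed spacing
#'   (default 0.3).
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @param margin Background margin width in pixels (default 2).
#' @return A `label_image` matrix with IDs 1..n_cells.
#' @export
synthetic_tissue <- function(n_cells, field_size = 256, jitter = 0.3,
                             seed = NULL, margin = 2) {
  if (n_cells < 1) abort("n_cells must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  inner <- field_size - 2 * margin
  spacing <- sqrt(inner^2 / n_cells)
  if (spacing < 4) abort("field too small for this many cells")
  ncol_s <- max(1, round(inner / spacing))
  nrow_s <- ceiling(n_cells / ncol_s)
  gx <- (rep(seq_len(ncol_s), times = nrow_s) - 0.5) * inner / ncol_s
  gy <- (rep(seq_len(nrow_s), each = ncol_s) - 0.5) * inner / nrow_s
  gx <- gx + rep(c(0, inner / ncol_s / 2), length.out = nrow_s)[rep(seq_len(nrow_s), each = ncol_s)]
  keep <- seq_len(n_cells)
  sx <- margin + (gx[keep] + runif(n_cells, -jitter, jitter) * spacing) %% inner
  sy <- margin + (gy[keep] + runif(n_cells, -jitter, jitter) * spacing) %% inner
  px <- seq_len(field_size) - 0.5
  d2 <- outer(px, sx, function(x, s) (x - s)^2)
  m <- matrix(0L, field_size, field_size)
  for (row in seq_len(field_size)) {
    # row index -> y-up coordinate
    yc <- field_size - row + 0.5
    dist2 <- sweep(d2, 2, (yc - sy)^2, "+") # field_size x n_cells over x
    lab <- max.col(-dist2, ties.method = "first")
    m[row, ] <- lab
  }
  m[seq_len(margin), ] <- 0L
  m[field_size - seq_len(margin) + 1, ] <- 0L
  m[, seq_len(margin)] <- 0L
  m[, field_size - seq_len(margin) + 1] <- 0L
  label_image(m)
}
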