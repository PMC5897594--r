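#' Split elliptic Fourier harmonics into counter-rotating rotors
#'
#' Each harmonic ellipse is rewritten as the sum of one counter-clockwise and
#' one clockwise rotating circle (a rotor pair):
#' `z_n(t) = lambda+ e^{i(n w t + phi+)} + lambda- e^{i(phi- - n w t)}`.
#' The split is exact:
#' `lambda+ = sqrt((a+d)^2 + (c-b)^2) / 2`, `phi+ = atan2(c-b, a+d)`,
#' `lambda- = sqrt((a-d)^2 + (c+b)^2) / 2`, `phi- = atan2(c+b, a-d)`.
#'
#' @param coef An `efa_coef` object (or its coefficient tibble).
#' @return A tibble with columns `n`, `lambda_plus`, `lambda_minus`,
#'   `phi_plus`, `phi_minus`.
#' @export
decompose_rotors <- function(coef) {
  cf <- if (inherits(coef, "efa_coef")) coef$coef else coef
  tibble::tibble(
    n = cf$n,
    lambda_plus = sqrt((cf$a + cf$d)^2 + (cf$c - cf$b)^2) / 2,
    lambda_minus = sqrt((cf$a - cf$d)^2 + (cf$c + cf$b)^2) / 2,
    phi_plus = atan2(cf$c - cf$b, cf$a + cf$d),
    phi_minus = atan2(cf$c + cf$b, cf$a - cf$d)
  )
}

#' Reassemble harmonic coefficients from a rotor pair table
#'
#' Inverse of [decompose_rotors()]; used for round-trip checks and
#' reconstruction bookkeeping.
#'
#' @param rotors A rotor tibble.
#' @return A coefficient tibble with columns `n, a, b, c, d`.
#' @export
rotors_to_coef <- function(rotors) {
  lp <- rotors$lambda_plus; lm <- rotors$lambda_minus
  pp <- rotors$phi_plus; pm <- rotors$phi_minus
  tibble::tibble(
    n = rotors$n,
    a = lp * cos(pp) + lm * cos(pm),
    b = -lp * sin(pp) + lm * sin(pm),
    c = lp * sin(pp) + lm * sin(pm),
    d = lp * cos(pp) - lm * cos(pm)
  )
}

wrap_angle <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  ifelse(out == -pi, pi, out)
}

#' Canonicalise the contour starting point in rotor space
#'
#' The same outline admits infinitely many elliptic Fourier representations,
#' one per choice of starting point along the contour. Re-parameterising
#' `t -> t + tau` shifts the rotor phases by `phi+_n -> phi+_n + n w tau` and
#' `phi-_n -> phi-_n - n w tau`. This function picks the unique shift that
#' zeroes the phase of the dominant (counter-clockwise) rotor of harmonic 1,
#' making the representation independent of where the traced contour happened
#' to start. The residual mode-1 reference phase `zeta` (0 after
#' canonicalisation) enters the L amplitude formula.
#'
#' @param rotors A rotor tibble from [decompose_rotors()].
#' @return The phase-shifted rotor tibble with attribute `zeta`.
#' @export
canonical_phase <- function(rotors) {
  r1 <- rotors[rotors$n == 1, ]
  if (nrow(r1) == 0 || max(r1$lambda_plus, r1$lambda_minus) <= 0) {
    abort("degenerate first harmonic: no dominant rotor")
  }
  if (r1$lambda_minus > r1$lambda_plus) {
    abort("clockwise-dominant first harmonic; canonicalise the contour to counter-clockwise first")
  }
  delta <- -r1$phi_plus # = w * tau
  out <- rotors
  out$phi_plus <- wrap_angle(rotors$phi_plus + rotors$n * delta)
  out$phi_minus <- wrap_angle(rotors$phi_minus - rotors$n * delta)
  attr(out, "zeta") <- 0
  out
}

#' Reassign rotors to lobe-number modes
#'
#' For a counter-clockwise base traversal, a counter-clockwise rotor at
#' harmonic n modulates the radius with n - 1 maxima, a clockwise rotor at
#' harmonic n with n + 1 maxima. Lobe mode l therefore collects the CCW rotor
#' of harmonic l + 1 and the CW rotor of harmonic l - 1. Mode 1 is special:
#' the dominant CCW rotor of harmonic 1 is the base circle (kept as
#' `r0`/`phase0`), the CCW rotor of harmonic 2 is its 1-fold modulation and
#' the CW rotor of harmonic 1 feeds mode 2. Offsets feed no mode. Modes are
#' carried internally up to N + 1 so that no rotor at the truncation boundary
#' is lost; reported spectra use modes 1..N-1.
#'
#' @param rotors A (canonicalised) rotor tibble.
#' @return A tibble with one row per lobe mode `l` = 1..N+1: `r_ccw`, `r_cw`,
#'   `phase_ccw`, `phase_cw`, and base-circle columns `r0`, `phase0` (nonzero
#'   only for l = 1); attribute `zeta` propagated.
#' @export
assign_modes <- function(rotors) {
  N <- max(rotors$n)
  zeta <- attr(rotors, "zeta")
  if (is.null(zeta)) zeta <- 0
  lp <- rotors$lambda_plus[order(rotors$n)]
  lm <- rotors$lambda_minus[order(rotors$n)]
  pp <- rotors$phi_plus[order(rotors$n)]
  pm <- rotors$phi_minus[order(rotors$n)]
  l <- seq_len(N + 1)
  get <- function(v, idx, default = 0) {
    ifelse(idx >= 1 & idx <= N, v[pmax(pmin(idx, N), 1)], default)
  }
  out <- tibble::tibble(
    l = l,
    r_ccw = get(lp, l + 1),
    phase_ccw = get(pp, l + 1),
    r_cw = ifelse(l >= 2, get(lm, l - 1), 0),
    phase_cw = ifelse(l >= 2, get(pm, l - 1), 0),
    r0 = ifelse(l == 1, lp[1], 0),
    phase0 = ifelse(l == 1, pp[1], 0)
  )
  attr(out, "zeta") <- zeta
  attr(out, "n_harmonics") <- N
  out
}

#' Scalar lobe amplitudes from assigned modes
#'
#' Combines the two rotors of each mode by the law of cosines,
#' `L_l = sqrt(r_ccw^2 + r_cw^2 + 2 r_ccw r_cw cos(Delta_l))` with
#' `Delta_l = phase_ccw + phase_cw - 2 zeta`, the alignment of the two rotors
#' as seen from the mode-1 starting point. `Delta_l` is invariant both to
#' rigid rotation of the contour and to the choice of starting point, so the
#' spectrum is too. `L_1` is the base-circle radius (about 1 after area
#' normalisation). The single-rotor limit `L_l -> r` holds when the other
#' radius vanishes.
#'
#' @param modes A mode tibble from [assign_modes()].
#' @param n_modes Number of modes to report (default N - 1 where N is the
#'   number of harmonics analysed).
#' @return A `loco_spectrum` tibble with columns `l`, `L`, `r_ccw`, `r_cw`,
#'   `phase_ccw`, `phase_cw`.
#' @export
compute_L <- function(modes, n_modes = attr(modes, "n_harmonics") - 1) {
  zeta <- attr(modes, "zeta")
  if (is.null(zeta)) zeta <- 0
  delta <- modes$phase_ccw + modes$phase_cw - 2 * zeta
  L <- sqrt(pmax(0, modes$r_ccw^2 + modes$r_cw^2 +
                   2 * modes$r_ccw * modes$r_cw * cos(delta)))
  L[modes$l == 1] <- modes$r0[modes$l == 1]
  out <- tibble::tibble(
    l = modes$l, L = L,
    r_ccw = modes$r_ccw, r_cw = modes$r_cw,
    phase_ccw = modes$phase_ccw, phase_cw = modes$phase_cw
  )
  out <- out[out$l <= n_modes, ]
  class(out) <- c("loco_spectrum", class(out))
  attr(out, "zeta") <- zeta
  out
}

#' Lobe contribution elliptic Fourier analysis of a single contour
#'
#' Full pipeline for one cell outline: canonicalise (counter-clockwise, area
#' pi), decompose into elliptic Fourier harmonics, split each harmonic into
#' counter-rotating rotors, fix the starting-point phase, reassign rotors to
#' lobe-number modes, and compute the L amplitude spectrum. `L_l` measures
#' the amplitude of l-fold radial features as a fraction of the
#' equivalent-circle radius: an area-normalised outline
#' `r(theta) = 1 + 0.15 cos(6 theta)` has `L_6 = 0.15`.
#'
#' @param contour A contour tibble; it is resampled and canonicalised unless
#'   already in canonical form.
#' @param n_modes Number of lobe modes to report (default 50; uses
#'   `n_modes + 1` elliptic Fourier harmonics).
#' @param n_points Arc-length resampling density before analysis.
#' @param normalise If `TRUE` (default) resample by arc length and
#'   canonicalise the contour first. Use `FALSE` for shapes that are already
#'   canonical (e.g. the output of the polar generators, whose native
#'   angular sampling is then kept).
#' @param parameterisation Passed to [efa()].
#' @return An object of class `loco_efa`: list with `spectrum` (a
#'   `loco_spectrum` tibble), `modes` (full mode table incl. the truncation
#'   boundary), `rotors`, `efa` (the `efa_coef`), `contour` (canonical),
#'   `zeta`, `scale`, `cell_id`.
#' @export
#' @examples
#' shape <- cosine_lobed_circle(0.15, 6)
#' fit <- loco_efa(shape, n_modes = 10)
#' tidy(fit)
#' glance(fit)
loco_efa <- function(contour, n_modes = 50, n_points = 1000,
                     normalise = TRUE,
                     parameterisation = c("uniform", "arc_length")) {
  if (normalise) {
    contour <- resample_contour(contour, n_points)
    contour <- canonicalise_contour(contour, check_simple = FALSE)
  }
  coef <- efa(contour, n_harmonics = n_modes + 1,
              parameterisation = parameterisation)
  rotors <- decompose_rotors(coef)
  rotors <- canonical_phase(rotors)
  modes <- assign_modes(rotors)
  spectrum <- compute_L(modes, n_modes = n_modes)
  structure(
    list(
      spectrum = spectrum,
      modes = modes,
      rotors = rotors,
      efa = coef,
      contour = contour,
      zeta = attr(rotors, "zeta"),
      scale = contour_scale(contour),
      cell_id = attr(contour, "cell_id")
    ),
    class = "loco_efa"
  )
}

#' @export
print.loco_efa <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("LOCO-EFA fit: %d modes, dominant lobe mode %d (L = %.4f)\n",
              nrow(x$spectrum), g$dominant_mode, g$L_dominant))
  print(x$spectrum, n = 8)
  invisible(x)
}

#' @export
tidy.loco_efa <- function(x, ...) x$spectrum

#' @export
glance.loco_efa <- function(x, ...) {
  sp <- x$spectrum
  hi <- sp[sp$l >= 2, ]
  dom <- hi$l[which.max(hi$L)] # ties: lowest mode wins (which.max takes first)
  tibble::tibble(
    n_modes = nrow(sp),
    L1 = sp$L[sp$l == 1],
    dominant_mode = dom,
    L_dominant = max(hi$L),
    perimeter = x$efa$perimeter,
    scale = x$scale
  )
}

#' Dominant lobe mode of a spectrum
#'
#' The argmax over modes l >= 2 of `L_l`; exact ties break to the lowest
#' mode.
#'
#' @param spectrum A `loco_spectrum` tibble or `loco_efa` object.
#' @export
dominant_mode <- function(spectrum) {
  if (inherits(spectrum, "loco_efa")) spectrum <- spectrum$spectrum
  hi <- spectrum[spectrum$l >= 2, ]
  hi$l[which.max(hi$L)]
}

#' Reconstruct a contour from the first lobe modes
#'
#' Sums, over lobe modes 1..`n_use`, the rotor terms each mode owns (plus the
#' offset). Adding mode l changes only the l-fold radial feature content, so
#' a k-lobed shape is recovered exactly when mode k enters. With
#' `n_use = "all"` every rotor up to the truncation boundary is included and
#' the result equals the full elliptic Fourier reconstruction.
#'
#' @param fit A `loco_efa` object.
#' @param n_use Number of modes to include (1..n_modes), or `"all"`.
#' @param n_samples Sampling density of the output contour.
#' @return A contour tibble (in canonical units).
#' @export
loco_reconstruct <- function(fit, n_use, n_samples = 1000) {
  modes <- fit$modes
  max_l <- max(modes$l)
  if (identical(n_use, "all")) n_use <- max_l
  if (n_use < 1 || n_use > max_l) abort("n_use out of range")
  tt <- seq(0, 2 * pi, length.out = n_samples + 1)[-(n_samples + 1)]
  xs <- rep(fit$efa$offset[1], n_samples)
  ys <- rep(fit$efa$offset[2], n_samples)
  for (l in seq_len(n_use)) {
    mo <- modes[modes$l == l, ]
    if (mo$r0 > 0) { # base circle (mode 1 only): frequency +1
      ang <- tt + mo$phase0
      xs <- xs + mo$r0 * cos(ang)
      ys <- ys + mo$r0 * sin(ang)
    }
    if (mo$r_ccw > 0) { # CCW rotor of harmonic l + 1
      ang <- (l + 1) * tt + mo$phase_ccw
      xs <- xs + mo$r_ccw * cos(ang)
      ys <- ys + mo$r_ccw * sin(ang)
    }
    if (l >= 2 && mo$r_cw > 0) { # CW rotor of harmonic l - 1
      ang <- mo$phase_cw - (l - 1) * tt
      xs <- xs + mo$r_cw * cos(ang)
      ys <- ys + mo$r_cw * sin(ang)
    }
  }
  out <- contour_xy(xs, ys, cell_id = fit$cell_id)
  attr(out, "scale") <- fit$scale
  out
}

#' Write a lobe spectrum as CSV
#'
#' Rows `(l, L, r_ccw, r_cw, phase_ccw, phase_cw)` with a header comment
#' carrying `zeta` and the area-normalisation scale.
#'
#' @param fit A `loco_efa` object.
#' @param path File path.
#' @export
write_spectrum_csv <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# zeta=%.17g scale=%.17g", fit$zeta, fit$scale), con)
  write.csv(as.data.frame(fit$spectrum), con, row.names = FALSE)
  invisible(path)
}
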