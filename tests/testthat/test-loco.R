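test_that("rotor split is an exact round trip", {
  # hand values: ellipse a=2, d=1 -> radii (a+d)/2, (a-d)/2
  cf <- tibble::tibble(n = 1:2, a = c(2, 1), b = c(0, 0), c = c(0, 0),
                       d = c(1, 1))
  rot <- decompose_rotors(cf)
  expect_equal(rot$lambda_plus[1], 1.5)
  expect_equal(rot$lambda_minus[1], 0.5)
  # pure CCW circle: a = d, b = -c
  expect_equal(rot$lambda_plus[2], 1)
  expect_equal(rot$lambda_minus[2], 0)

  set.seed(7)
  for (i in 1:50) {
    cf <- tibble::tibble(n = 1:4, a = rnorm(4), b = rnorm(4), c = rnorm(4),
                         d = rnorm(4))
    back <- rotors_to_coef(decompose_rotors(cf))
    expect_equal(as.matrix(back), as.matrix(cf), tolerance = 1e-12)
  }
})

test_that("canonical phase is invariant to the starting vertex", {
  st <- star_shape(7, "medium", n_points = 800)
  ref <- canonical_phase(decompose_rotors(efa(st, 16)))
  for (k in seq(100, 700, by = 100)) {
    shifted <- cyclic_shift_contour(st, k)
    out <- canonical_phase(decompose_rotors(efa(shifted, 16)))
    expect_equal(out$lambda_plus, ref$lambda_plus, tolerance = 1e-9)
    expect_equal(out$lambda_minus, ref$lambda_minus, tolerance = 1e-9)
    live <- ref$lambda_plus > 1e-8
    expect_equal(wrapped <- sin(out$phi_plus[live] - ref$phi_plus[live]),
                 rep(0, sum(live)), tolerance = 1e-9)
  }
  expect_equal(attr(ref, "zeta"), 0)

  # circle: phi+ of harmonic 1 is zero after canonicalisation
  th <- seq(0.3, 0.3 + 2 * pi, length.out = 513)[-513]
  circ <- contour_xy(cos(th), sin(th))
  out <- canonical_phase(decompose_rotors(efa(circ, 4)))
  expect_equal(out$phi_plus[1], 0, tolerance = 1e-12)

  # degenerate: all-zero first harmonic
  zero <- tibble::tibble(n = 1:3, lambda_plus = 0, lambda_minus = 0,
                         phi_plus = 0, phi_minus = 0)
  expect_error(canonical_phase(zero), "degenerate")
})

test_that("pure rotors land on the lobe mode the radial oracle counts", {
  eps <- 0.08
  for (spec in list(list(h = 5, dir = -1), list(h = 7, dir = +1))) {
    ct <- circle_plus_rotor(spec$h, spec$dir, eps)
    # oracle: the composite curve has 6 radial maxima either way
    expect_equal(count_radial_maxima(ct$x, ct$y), 6)
    fit <- loco_efa(ct, n_modes = 12, normalise = FALSE)
    L <- fit$spectrum$L
    expect_equal(L[6], eps, tolerance = 1e-4)
    expect_true(all(L[setdiff(2:12, 6)] < 1e-8))
  }

  # circle: all modes l >= 2 empty
  circ <- cosine_lobed_circle(0, 3, n_points = 512)
  fit <- loco_efa(circ, n_modes = 10, normalise = FALSE)
  expect_true(all(fit$spectrum$L[-1] < 1e-6))
})

test_that("L combines rotor radii and phases by the law of cosines", {
  mk <- function(r_ccw, r_cw, p_ccw = 0, p_cw = 0) {
    modes <- tibble::tibble(
      l = 1:2, r_ccw = c(0, r_ccw), phase_ccw = c(0, p_ccw),
      r_cw = c(0, r_cw), phase_cw = c(0, p_cw), r0 = c(1, 0),
      phase0 = 0
    )
    attr(modes, "zeta") <- 0
    attr(modes, "n_harmonics") <- 3
    compute_L(modes)$L[2]
  }
  expect_equal(mk(0.15, 0), 0.15)
  expect_equal(mk(0, 0.15), 0.15)
  expect_equal(mk(0.1, 0.1, 0, 0), 0.2)
  expect_equal(mk(0.1, 0.1, pi, 0), 0, tolerance = 1e-12)
  expect_equal(mk(0.1, 0.1, pi / 2, 0), sqrt(0.02), tolerance = 1e-12)
})

test_that("the area-normalised cosine calibration recovers epsilon", {
  for (eps in c(0.05, 0.1, 0.15, 0.2)) {
    for (l in c(3, 5, 6, 9)) {
      fit <- loco_efa(cosine_lobed_circle(eps, l, n_points = 600),
                      n_modes = 12, normalise = FALSE)
      expect_lt(abs(fit$spectrum$L[l] - eps), 0.02 * eps + 0.003)
    }
  }
})

test_that("the spectrum is invariant to rotation and starting point", {
  st <- star_shape(6, "high", n_points = 720)
  ref <- loco_efa(st, n_modes = 30, normalise = FALSE)$spectrum$L
  for (ang in c(0.37, 1.9, pi)) {
    L <- loco_efa(rotate_contour(st, ang), n_modes = 30,
                  normalise = FALSE)$spectrum$L
    expect_lt(max(abs(L - ref)), 1e-9)
  }
  for (k in c(77, 360)) {
    L <- loco_efa(cyclic_shift_contour(st, k), n_modes = 30,
                  normalise = FALSE)$spectrum$L
    expect_lt(max(abs(L - ref)), 1e-6)
  }
})

test_that("lobe modes conserve rotor content up to the truncation boundary", {
  cell <- star_shape(8, "medium", n_points = 640)
  fit <- loco_efa(cell, n_modes = 20, normalise = FALSE)
  # every rotor appears exactly once across the mode table
  modes <- fit$modes
  rot <- fit$rotors
  N <- max(rot$n)
  expect_equal(modes$r_ccw[match(1:(N - 1), modes$l)],
               rot$lambda_plus[match(2:N, rot$n)])
  expect_equal(modes$r_cw[match(2:(N + 1), modes$l)],
               rot$lambda_minus[match(1:N, rot$n)])
  expect_equal(modes$r0[modes$l == 1], rot$lambda_plus[rot$n == 1])
  # so the all-mode reconstruction equals the full elliptic Fourier one
  full <- loco_reconstruct(fit, "all", n_samples = 400)
  ref <- efa_reconstruct(fit$efa, n_samples = 400)
  expect_lt(max(abs(full$x - ref$x), abs(full$y - ref$y)), 1e-9)
})

test_that("truncated lobe reconstructions add feature content mode by mode", {
  st <- star_shape(6, "medium", n_points = 600)
  fit <- loco_efa(st, n_modes = 12, normalise = FALSE)
  grid <- make_raster_grid(fit$contour, n = 256)
  orig <- rasterise_contour(fit$contour, grid)
  xors <- vapply(1:8, function(nu) {
    xor_difference(orig, loco_reconstruct(fit, nu, n_samples = 1500), grid)
  }, numeric(1))
  # the largest single-mode improvement happens when mode 6 enters
  expect_equal(which.max(-diff(xors)) + 1, 6)
  # circle reconstitutes from mode 1 alone
  circ <- cosine_lobed_circle(0, 4, n_points = 512)
  fc <- loco_efa(circ, n_modes = 6, normalise = FALSE)
  r1 <- loco_reconstruct(fc, 1, n_samples = 256)
  expect_lt(max(abs(sqrt(r1$x^2 + r1$y^2) - 1)), 1e-3)
  expect_error(loco_reconstruct(fc, 99), "out of range")
})

test_that("tidiers and accessors expose the fit", {
  fit <- loco_efa(star_shape(5, "low", n_points = 400), n_modes = 15,
                  normalise = FALSE)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("l", "L", "r_ccw", "r_cw", "phase_ccw", "phase_cw"))
  gl <- glance(fit)
  expect_equal(gl$dominant_mode, 5)
  expect_equal(nrow(gl), 1)
  expect_equal(dominant_mode(fit), 5)
})
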