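test_that("incremental energy changes match full Hamiltonian recomputes", {
  set.seed(11)
  par <- cpm_params(J = 2.5, A = 30, P = 40, lambda_a = 1, lambda_p = 0.3,
                    temperature = 5)
  lat <- matrix(sample(0:3, 32 * 32, replace = TRUE), 32, 32)
  worst <- 0
  for (i in 1:500) {
    r <- sample(32, 1)
    c <- sample(32, 1)
    new <- sample(0:3, 1)
    if (lat[r, c] == new) next
    dH <- cpm_delta_H(lat, par, r, c, new, n_cells = 3)
    lat2 <- lat
    lat2[r, c] <- new
    full <- cpm_energy(lat2, par, n_cells = 3) -
      cpm_energy(lat, par, n_cells = 3)
    worst <- max(worst, abs(dH - full))
    if (i %% 7 == 0) lat <- lat2 # walk through configuration space
  }
  expect_lt(worst, 1e-9)

  # single-site cell retracting to background: pure area-term algebra
  par2 <- cpm_params(J = 0, A = 1, P = 0, lambda_a = 2, lambda_p = 0,
                     temperature = 1)
  lat <- matrix(0L, 9, 9)
  lat[5, 5] <- 1L
  dH <- cpm_delta_H(lat, par2, 5, 5, 0, n_cells = 1)
  A <- par2$A
  expect_equal(dH, 2 * (A^2 - (A - 1)^2))

  # J = 0 and zero stiffness: every event is free
  par3 <- cpm_params(J = 0, A = 5, P = 0, lambda_a = 0, lambda_p = 0,
                     temperature = 1)
  expect_equal(cpm_delta_H(lat, par3, 5, 5, 0, n_cells = 1), 0)
  expect_equal(cpm_delta_H(lat, par3, 4, 5, 1, n_cells = 1), 0)
})

test_that("shape-bias terms follow the lobe, elongation and roundness contracts", {
  par <- cpm_params(nu = 3, n_lobes = 5, chi = 0, mu = 0, A = pi * 100)
  # extension exactly on a target direction: -nu
  expect_equal(cpm_delta_shape(10, 0, 0, 0, par), -3)
  # halfway between targets: +nu
  th <- pi / 5
  expect_equal(cpm_delta_shape(10 * cos(th), 10 * sin(th), 0, 0, par), 3)
  # retraction flips the sign
  expect_equal(cpm_delta_shape(10, 0, 0, 0, par, extending = FALSE), 3)

  pare <- cpm_params(nu = 0, chi = 2, mu = 0, A = pi * 100)
  expect_equal(cpm_delta_shape(10, 0, 0, 0, pare, elong_angle = 0), -2)
  expect_equal(cpm_delta_shape(0, 10, 0, 0, pare, elong_angle = 0), 2)
  # bipolar: both ends of the axis are favoured equally
  expect_equal(cpm_delta_shape(-10, 0, 0, 0, pare, elong_angle = 0), -2)

  parr <- cpm_params(nu = 0, chi = 0, mu = 1.5, A = pi * 100) # R = 10
  expect_equal(cpm_delta_shape(10, 0, 0, 0, parr), 0) # at preferred radius
  expect_equal(cpm_delta_shape(12, 0, 0, 0, parr), 1.5 * 4) # beyond: penalty
  expect_equal(cpm_delta_shape(8, 0, 0, 0, parr), -1.5 * 4) # inside: gain
  expect_equal(cpm_delta_shape(8, 0, 0, 0, parr, extending = FALSE), 1.5 * 4)
})

test_that("the acceptance rule is Metropolis with a yield offset", {
  par <- cpm_params(temperature = 2, yield = 1)
  expect_equal(cpm_accept_prob(-2, par), 1) # dH <= -Y: always
  expect_equal(cpm_accept_prob(-1, par), 1) # boundary dH = -Y
  expect_equal(cpm_accept_prob(0, par), exp(-1 / 2))
  par0 <- cpm_params(temperature = 2, yield = 0)
  expect_equal(cpm_accept_prob(0, par0), 1)
  # detailed balance at Y = 0: forward/reverse ratio is the Boltzmann factor
  for (dH in c(0.5, 1, 3)) {
    expect_equal(cpm_accept_prob(dH, par0) / cpm_accept_prob(-dH, par0),
                 exp(-dH / par0$temperature))
  }
  # T -> 0: uphill moves freeze out
  parT <- cpm_params(temperature = 1e-6, yield = 0)
  expect_lt(cpm_accept_prob(0.1, parT), 1e-300)
  set.seed(1)
  expect_true(all(cpm_accept(rep(-5, 20), par)))
})

test_that("target-vector updates recover imposed lobe phases and axes", {
  # rasterise a five-lobed cell at a known phase, ask for it back
  mk_cell <- function(phase) {
    g <- list(x = 1:64, y = 1:64)
    ct <- cosine_lobed_circle(0.25, 5, n_points = 400, phase = phase)
    mask <- rasterise_contour(contour_xy(ct$x * 14 + 32, ct$y * 14 + 32), g)
    matrix(as.integer(t(mask)), 64, 64)
  }
  par <- cpm_params(n_lobes = 5)
  base <- cpm_update_vectors(mk_cell(0), par)$phase
  for (dphi in c(0.3, 0.9)) {
    got <- cpm_update_vectors(mk_cell(dphi), par)$phase
    # recovered phase shifts with the rotation, modulo the 2 pi / 5 spacing
    diffp <- (got - base - dphi) %% (2 * pi / 5)
    expect_lt(min(diffp, 2 * pi / 5 - diffp), 0.06)
  }
  # perfectly aligned cell is a fixed point
  again <- cpm_update_vectors(mk_cell(0), par, phase = base)$phase
  expect_lt(abs(again - base), 1e-9)
  # a radially featureless (4-fold symmetric square) cell has no 5-fold
  # correlation signal at all: the current phase is retained
  lat <- matrix(0L, 16, 16)
  lat[7:11, 7:11] <- 1L
  kept <- cpm_update_vectors(lat, par, phase = 0.77)$phase
  expect_equal(kept, 0.77)
  # elongation axis of an axis-aligned bar
  bar <- matrix(0L, 40, 40)
  bar[18:22, 5:35] <- 1L
  ax <- cpm_update_vectors(bar, par)$elong
  expect_lt(min(abs(ax), abs(abs(ax) - pi)), 1e-6)
})

test_that("simulations are reproducible and respect their constraints", {
  par <- cpm_params(J = 4, A = 80, lambda_a = 1, lambda_p = 0.2, nu = 0,
                    mu = 2, temperature = 6)
  a <- cpm_run(par, n_cells = 2, field = 40, steps = 60, seed = 42)
  b <- cpm_run(par, n_cells = 2, field = 40, steps = 60, seed = 42)
  expect_identical(unclass(a$lattice)[, ], unclass(b$lattice)[, ])
  expect_equal(sum(a$area), sum(unclass(a$lattice) > 0))
  # per-cell area bookkeeping equals a full recount
  for (id in 1:2) {
    expect_equal(a$area[id], sum(unclass(a$lattice) == id))
  }
  expect_error(cpm_run(par, n_cells = 2, field = 40, steps = 0), "steps")
})

test_that("a cell with no lobe bias relaxes to a near-circle, with bias to n lobes", {
  par0 <- cpm_params(J = 4, A = 400, lambda_a = 1, lambda_p = 0.3, nu = 0,
                     chi = 0, mu = 3, temperature = 6)
  run0 <- cpm_run(par0, n_cells = 1, field = 60, steps = 1500, seed = 33)
  ct <- extract_contours(run0$lattice, min_pixels = 50)$contour[[1]]
  f0 <- loco_efa(ct, n_modes = 20)
  expect_lt(max(f0$spectrum$L[-1]), 0.05)

  par6 <- cpm_params_sixlobe()
  run6 <- cpm_run(par6, n_cells = 1, field = 60, steps = 3000, seed = 7)
  ct6 <- extract_contours(run6$lattice, min_pixels = 50)$contour[[1]]
  f6 <- loco_efa(ct6, n_modes = 12)
  expect_equal(dominant_mode(f6), 6)
})

test_that("config files round-trip the parameter names", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# six-lobed cell", "J = 4", "A = 500", "P = 213",
               "lambda_a = 1", "lambda_p = 0.2", "nu = 40", "n_lobes = 6",
               "chi = 0", "mu = 2", "temperature = 10", "yield = 0",
               "steps = 100", "seed = 3"), path)
  cfg <- read_cpm_config(path)
  expect_s3_class(cfg$params, "cpm_params")
  expect_equal(cfg$params$nu, 40)
  expect_equal(cfg$params$n_lobes, 6)
  expect_equal(cfg$steps, 100)
  expect_equal(cfg$seed, 3)
})
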