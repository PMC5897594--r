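test_that("xor_difference handles the limiting cases", {
  st <- star_shape(5, "medium", n_points = 400)
  grid <- make_raster_grid(st, n = 128)
  mask <- rasterise_contour(st, grid)
  expect_equal(xor_difference(mask, mask), 0)
  empty <- matrix(FALSE, 128, 128)
  expect_equal(xor_difference(mask, empty), 1)
  expect_error(xor_difference(empty, mask), "empty original")
})

test_that("XOR profiles identify feature-carrying modes", {
  st <- star_shape(6, "medium", n_points = 600)
  fit <- loco_efa(st, n_modes = 20, normalise = FALSE)
  prof <- xor_profile(fit, n_max = 20)
  expect_equal(prof$xor[prof$n == 0], 1)
  expect_true(all(prof$xor >= 0 & prof$xor <= 2))
  expect_equal(argmax_marginal(prof), 6)
  # marginal differences decompose the explained area exactly
  expect_equal(sum(prof$marginal[-1]), 1 - prof$xor[nrow(prof)])

  # circle: one mode suffices up to rasterisation error
  circ <- cosine_lobed_circle(0, 4, n_points = 512)
  pc <- xor_profile(loco_efa(circ, n_modes = 5, normalise = FALSE), n_max = 3)
  expect_lt(pc$xor[pc$n == 1], 0.002)
})

test_that("marginal-difference peaks grow with protrusion amplitude", {
  peaks <- vapply(c("low", "medium", "high"), function(a) {
    fit <- loco_efa(star_shape(5, a, n_points = 500), n_modes = 12,
                    normalise = FALSE)
    prof <- xor_profile(fit, n_max = 12,
                        grid = make_raster_grid(fit$contour, n = 256))
    max(prof$marginal[prof$n >= 2], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("cumulative difference ranks lobe richness", {
  cds <- vapply(c(0.08, 0.15, 0.25), function(eps) {
    fit <- loco_efa(cosine_lobed_circle(eps, 6, n_points = 600),
                    n_modes = 15, normalise = FALSE)
    attr(xor_profile(fit, n_max = 15,
                     grid = make_raster_grid(fit$contour, n = 256)), "cd")
  }, numeric(1))
  expect_true(all(diff(cds) > 0))

  circ <- cosine_lobed_circle(0, 4, n_points = 512)
  pc <- xor_profile(loco_efa(circ, n_modes = 5, normalise = FALSE), n_max = 5)
  expect_lt(attr(pc, "cd"), 0.01)
  expect_error(cumulative_difference(tibble::tibble(n = 0:1, xor = c(1, 0))),
               "mode 2")
})

test_that("the natural cut-off is finite on the source grid", {
  # rasterise a star, re-extract it, and analyse on the raster's own grid
  st <- star_shape(6, "medium", n_points = 600)
  g <- list(x = 1:96, y = 1:96)
  mask <- rasterise_contour(contour_xy(st$x * 14 + 48, st$y * 14 + 48), g)
  img <- label_image(t(mask)[96:1, ] * 1L)
  ct <- extract_contours(img)$contour[[1]]
  fit <- loco_efa(ct, n_modes = 50)
  gg <- list(x = seq(floor(min(ct$x)) - 2, ceiling(max(ct$x)) + 2),
             y = seq(floor(min(ct$y)) - 2, ceiling(max(ct$y)) + 2))
  prof <- xor_profile(fit, grid = gg,
                      original = rasterise_contour(ct, gg),
                      to_grid = function(c2) contour_xy(c2$x / fit$scale,
                                                        c2$y / fit$scale))
  cutoff <- attr(prof, "cutoff")
  expect_false(is.na(cutoff))
  expect_true(all(prof$xor[prof$n >= cutoff] == 0))
  expect_equal(argmax_marginal(prof), 6)
})

test_that("entropy has the exact limiting values and variants", {
  one <- tibble::tibble(l = 1:10, L = c(1, rep(0, 9)))
  expect_equal(shape_entropy(one), 0)
  unif8 <- tibble::tibble(l = 1:8, L = rep(0.3, 8))
  expect_equal(shape_entropy(unif8), 3)
  expect_equal(shape_entropy(unif8, weights = "power"), 3)
  expect_error(shape_entropy(tibble::tibble(l = 1:3, L = 0)), "all-zero")
  # truncation at l_max
  sp <- tibble::tibble(l = 1:10, L = c(rep(1, 4), rep(0, 5), 5))
  expect_equal(shape_entropy(sp, l_max = 4), 2)
})

test_that("entropy reads distributed spectra as more complex than concentrated ones", {
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  # elongated-simple cell: mode 2 carries nearly everything, cd stays small
  ell <- canonicalise_contour(contour_xy(2 * cos(th), 0.5 * sin(th)))
  fell <- loco_efa(ell, n_modes = 50, normalise = FALSE)
  expect_lt(attr(xor_profile(fell), "cd"), 0.05)
  # shape with comparable-amplitude contributions spread over many modes:
  # judged more complex by entropy even though each lobe is shallow
  r <- 1 + 0.06 * (cos(3 * th) + cos(5 * th + 1.2) + cos(7 * th - 0.5) +
                     cos(9 * th + 2.1))
  fdist <- loco_efa(canonicalise_contour(contour_xy(r * cos(th),
                                                    r * sin(th))),
                    n_modes = 50, normalise = FALSE)
  expect_lt(shape_entropy(fell), shape_entropy(fdist))

  # regular five-lobe star vs distorted five-lobed shape of comparable cd
  freg <- loco_efa(cosine_lobed_circle(0.15, 5), n_modes = 50,
                   normalise = FALSE)
  rd <- 1 + 0.13 * cos(5 * th) + 0.05 * cos(2 * th + 1) +
    0.05 * cos(3 * th - 0.7) + 0.04 * cos(7 * th + 2)
  fdis <- loco_efa(canonicalise_contour(contour_xy(rd * cos(th),
                                                   rd * sin(th))),
                   n_modes = 50, normalise = FALSE)
  cd_reg <- attr(xor_profile(freg), "cd")
  cd_dis <- attr(xor_profile(fdis), "cd")
  expect_lt(abs(cd_dis - cd_reg), 0.35 * cd_reg)
  expect_gt(shape_entropy(fdis), shape_entropy(freg))
})
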