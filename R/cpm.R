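#' Parameters for the extended cellular Potts model
#'
#' Bundles the coupling energy `J` (per unlike second-order neighbour pair),
#' target area `A` (grid points) and perimeter `P` with their stiffnesses
#' `lambda_a`, `lambda_p`, the lobe propensity `nu` with the specified lobe
#' count `n_lobes`, the elongation propensity `chi`, the roundness stiffness
#' `mu` (quadratic restoring force towards the equivalent-circle radius
#' `R = sqrt(A / pi)`), the simulation temperature `T` and the yield `Y`
#' (energy a membrane fluctuation must overcome before Boltzmann acceptance
#' applies).
#'
#' @param J,A,P,lambda_a,lambda_p,nu,n_lobes,chi,mu,temperature,yield Model
#'   parameters; see Details.
#' @return A `cpm_params` list.
#' @export
cpm_params <- function(J = 2, A = 500, P = NULL, lambda_a = 1,
                       lambda_p = 0.05, nu = 0, n_lobes = 6, chi = 0,
                       mu = 0, temperature = 8, yield = 0) {
  if (temperature <= 0) abort("temperature must be > 0")
  if (A <= 0) abort("target area A must be > 0")
  if (any(c(lambda_a, lambda_p, mu) < 0)) abort("stiffnesses must be >= 0")
  if (is.null(P)) {
    # second-order-neighbour perimeter of a circle of area A is about
    # 6 sites per unit of circumference length
    P <- round(6 * 2 * sqrt(pi * A) / 2)
  }
  structure(list(J = J, A = A, P = P, lambda_a = lambda_a,
                 lambda_p = lambda_p, nu = nu, n_lobes = n_lobes, chi = chi,
                 mu = mu, temperature = temperature, yield = yield),
            class = "cpm_params")
}

#' Read CPM parameters from a key=value config file
#'
#' Recognised keys: `J, A, P, lambda_a, lambda_p, nu, n_lobes, chi, mu,
#' temperature, yield, steps, seed, n_cells, field`. Lines starting with `#`
#' are comments.
#'
#' @param path Config file path.
#' @return A list with `params` (a `cpm_params`) and any run keys present.
#' @export
read_cpm_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  names(vals) <- keys
  par_keys <- intersect(keys, c("J", "A", "P", "lambda_a", "lambda_p", "nu",
                                "n_lobes", "chi", "mu", "temperature",
                                "yield"))
  params <- do.call(cpm_params, as.list(vals[par_keys]))
  run <- as.list(vals[setdiff(keys, par_keys)])
  c(list(params = params), run)
}

#' Metropolis-with-yield acceptance rule
#'
#' Copy events that decrease the energy by at least the yield `Y` are always
#' accepted; otherwise acceptance follows the Boltzmann probability
#' `exp(-(dH + Y) / T)`.
#'
#' @param delta_H Energy change of the proposed copy event (vectorised).
#' @param params A `cpm_params` (or anything with `temperature` and
#'   `yield`).
#' @return `cpm_accept()`: logical, accept the event? `cpm_accept_prob()`:
#'   the acceptance probability itself (1 for `delta_H <= -Y`), so detailed
#'   balance can be checked analytically: at `Y = 0` the forward/reverse
#'   probability ratio is `exp(-delta_H / T)`.
#' @export
cpm_accept <- function(delta_H, params) {
  runif(length(delta_H)) < cpm_accept_prob(delta_H, params)
}

#' @rdname cpm_accept
#' @export
cpm_accept_prob <- function(delta_H, params) {
  ifelse(delta_H <= -params$yield, 1,
         exp(-(delta_H + params$yield) / params$temperature))
}

#' Full configurational energy and incremental energy changes
#'
#' `cpm_energy()` evaluates the adhesion + area + perimeter Hamiltonian of a
#' lattice; `cpm_delta_H()` the incremental change of copying `new_id` into
#' site `(row, col)`. Both use the 8-site second-order neighbourhood, with
#' out-of-field sites counting as medium.
#'
#' @param lattice Integer matrix of cell IDs (0 = medium).
#' @param params A `cpm_params`.
#' @param n_cells Number of cells (defaults to `max(lattice)`).
#' @export
cpm_energy <- function(lattice, params, n_cells = max(lattice)) {
  cpm_energy_cpp(unclass_matrix(lattice), n_cells, params$J, params$A,
                 params$P, params$lambda_a, params$lambda_p)
}

#' @rdname cpm_energy
#' @param row,col 1-based site indices.
#' @param new_id Proposed new ID for the site.
#' @export
cpm_delta_H <- function(lattice, params, row, col, new_id,
                        n_cells = max(lattice)) {
  cpm_delta_base_cpp(unclass_matrix(lattice), n_cells, row, col, new_id,
                     params$J, params$A, params$P, params$lambda_a,
                     params$lambda_p)
}

#' Shape-bias energy terms for one cell in a copy event
#'
#' The lobe term `-s nu cos(n theta)` (theta measured from the nearest of
#' the n equally spaced target directions), the elongation term
#' `-s chi cos(2 alpha)` and the roundness term
#' `s mu sign(r - R) (r - R)^2`, for a cell with centre of mass
#' `(com_x, com_y)` and the evaluated grid point at `(x, y)`;
#' `s = +1` for extension, `-1` for retraction.
#'
#' @param x,y Evaluated grid point.
#' @param com_x,com_y Cell centre of mass.
#' @param params A `cpm_params`.
#' @param lobe_phase,elong_angle Current target-vector angles (radians).
#' @param extending `TRUE` for the cell gaining the site.
#' @export
cpm_delta_shape <- function(x, y, com_x, com_y, params, lobe_phase = 0,
                            elong_angle = 0, extending = TRUE) {
  cpm_delta_shape_cpp(x, y, com_x, com_y, lobe_phase, params$n_lobes,
                      params$nu, elong_angle, params$chi, params$mu,
                      sqrt(params$A / pi), if (extending) 1 else -1)
}

#' Re-fit target lobe and elongation vectors to the current cell shapes
#'
#' The lobe-direction phase is set to the offset maximising the circular
#' cross-correlation between each cell's radial boundary profile and
#' `cos(n (beta - offset))`; the elongation vector is the principal axis of
#' the cell's second area moment. Circular cells keep their current phase.
#'
#' @param lattice Integer ID matrix.
#' @param params A `cpm_params`.
#' @param phase,elong Current per-cell angles (recycled to `n_cells`).
#' @param n_cells Number of cells.
#' @return A list with `phase`, `elong` and `fragmented` (count of cells
#'   failing the 4-connectivity audit).
#' @export
cpm_update_vectors <- function(lattice, params, phase = 0, elong = 0,
                               n_cells = max(lattice)) {
  cpm_update_vectors_cpp(unclass_matrix(lattice), n_cells, params$n_lobes,
                         c(0, rep_len(phase, n_cells)),
                         c(0, rep_len(elong, n_cells)))
}

unclass_matrix <- function(m) {
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Run an extended cellular Potts simulation
#'
#' Cells are seeded as small squares at random positions (or from a supplied
#' initial lattice) and evolved by Metropolis dynamics. One time step is one
#' Monte Carlo step: as many elementary copy-event evaluations as lattice
#' sites. Lobe and elongation target vectors are dynamically re-fitted every
#' `update_every` (default 100) steps so each cell accommodates its lobe
#' positions to its neighbours. Fragmentation (a cell failing the
#' 4-connectivity audit) is logged as a warning count but the simulation
#' continues.
#'
#' @param params A `cpm_params`.
#' @param n_cells Number of cells to seed.
#' @param field Lattice side length (scalar) or c(rows, cols).
#' @param steps Number of Monte Carlo steps (>= 1).
#' @param seed RNG seed; the single R RNG stream drives site choice,
#'   neighbour choice and acceptance.
#' @param init Optional initial integer lattice (overrides random seeding).
#' @param snapshot_every Keep a lattice snapshot every so many steps
#'   (0 = none; the final lattice is always kept).
#' @param update_every Target-vector update interval in steps.
#' @return A `cpm_trajectory`: list with `lattice` (final `label_image`),
#'   `snapshots`, `snapshot_steps`, `area`, `perimeter`, `phase`,
#'   `fragmentation_events`, `params`, `seed`, `steps`.
#' @export
#' @examples
#' \donttest{
#' par6 <- cpm_params(A = 300, nu = 30, n_lobes = 6, mu = 1)
#' run <- cpm_run(par6, n_cells = 1, field = 48, steps = 300, seed = 1)
#' }
cpm_run <- function(params, n_cells, field, steps, seed = NULL,
                    init = NULL, snapshot_every = 0, update_every = 100) {
  if (steps < 1) abort("steps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (length(field) == 1) field <- c(field, field)
  if (is.null(init)) {
    init <- matrix(0L, field[1], field[2])
    side <- max(2, floor(sqrt(params$A) / 2))
    placed <- 0
    guard <- 0
    while (placed < n_cells && guard < 10000) {
      guard <- guard + 1
      r <- sample.int(field[1] - side, 1)
      c <- sample.int(field[2] - side, 1)
      block <- init[r:(r + side - 1), c:(c + side - 1)]
      if (all(block == 0)) {
        placed <- placed + 1
        init[r:(r + side - 1), c:(c + side - 1)] <- placed
      }
    }
    if (placed < n_cells) abort("field too small to place all cells")
  }
  res <- cpm_run_cpp(unclass_matrix(init), n_cells, params$J, params$A,
                     params$P, params$lambda_a, params$lambda_p, params$nu,
                     params$n_lobes, params$chi, params$mu,
                     params$temperature, params$yield, steps,
                     snapshot_every, update_every)
  if (res$fragmentation_events > 0) {
    warn(sprintf("connectivity audit: %d fragmentation event(s) logged",
                 res$fragmentation_events))
  }
  structure(
    list(lattice = label_image(res$lattice),
         snapshots = lapply(res$snapshots, label_image),
         snapshot_steps = res$snapshot_steps,
         area = res$area, perimeter = res$perimeter, phase = res$phase,
         fragmentation_events = res$fragmentation_events,
         params = params, seed = seed, steps = steps, n_cells = n_cells),
    class = "cpm_trajectory"
  )
}

#' @export
print.cpm_trajectory <- function(x, ...) {
  cat(sprintf("CPM trajectory: %d cell(s), %d x %d lattice, %d steps\n",
              x$n_cells, nrow(x$lattice), ncol(x$lattice), x$steps))
  cat(sprintf("  final areas: %s\n",
              paste(round(x$area), collapse = " ")))
  invisible(x)
}
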