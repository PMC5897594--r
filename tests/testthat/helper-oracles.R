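# Independent oracles used across the suite.

# Discrete Fourier rotor radii of a closed contour sampled uniformly in its
# parameter: |c_k| for e^{+ikt} (counter-clockwise) and e^{-ikt} (clockwise).
dft_rotors <- function(ct, n_max) {
  z <- complex(real = ct$x, imaginary = ct$y)
  m <- length(z)
  tt <- 2 * pi * (seq_len(m) - 1) / m
  list(
    lambda_plus = vapply(seq_len(n_max),
                         function(k) Mod(mean(z * exp(-1i * k * tt))),
                         numeric(1)),
    lambda_minus = vapply(seq_len(n_max),
                          function(k) Mod(mean(z * exp(1i * k * tt))),
                          numeric(1))
  )
}

# Number of local maxima of the radial profile |z(t)| of a closed curve
# (circular boundary conditions), ignoring sub-tolerance ripples.
count_radial_maxima <- function(x, y, tol = 1e-6) {
  r <- sqrt(x^2 + y^2)
  r <- r - mean(r)
  d <- diff(c(r, r[1]))
  up <- d > tol
  dn <- d < -tol
  # a maximum = an up-run followed by a down-run (circularly)
  sig <- rep(0L, length(d))
  sig[up] <- 1L
  sig[dn] <- -1L
  sig <- sig[sig != 0]
  if (!length(sig)) return(0L)
  sum(sig == 1L & c(sig[-1], sig[1]) == -1L)
}

# A unit circle plus one pure rotor at harmonic n: CCW (dir = +1) or
# CW (dir = -1), amplitude eps, sampled at m parameter values.
circle_plus_rotor <- function(n, dir, eps, m = 2048) {
  tt <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  z <- exp(1i * tt) + eps * exp(1i * dir * n * tt)
  contour_xy(Re(z), Im(z))
}

# cd of a fitted contour on the default synthetic grid
cd_of <- function(fit) attr(xor_profile(fit), "cd")

rotate_contour <- function(ct, angle) {
  out <- contour_xy(cos(angle) * ct$x - sin(angle) * ct$y,
                    sin(angle) * ct$x + cos(angle) * ct$y,
                    cell_id = attr(ct, "cell_id"))
  attr(out, "scale") <- attr(ct, "scale")
  out
}

cyclic_shift_contour <- function(ct, k) {
  n <- nrow(ct)
  idx <- c((k + 1):n, seq_len(k))
  out <- contour_xy(ct$x[idx], ct$y[idx])
  attr(out, "scale") <- attr(ct, "scale")
  out
}
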