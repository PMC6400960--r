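#' Mono-exponential fluorescence decay on the gate grid
#'
#' Samples `A * exp(-t_g / tau)` on the gates of `axis`, normalized so the
#' time-integrated counts equal `amplitude` (the pixel's CW intensity is
#' defined as the time sum of its histogram).
#'
#' @param amplitude total counts (>= 0).
#' @param tau lifetime, ns (> 0 unless `amplitude == 0`).
#' @param axis a [temporal_axis()].
#' @return numeric vector of length `n_gates` summing to `amplitude`.
#' @export
simulate_decay <- function(amplitude, tau, axis) {
  stopifnot(inherits(axis, "temporal_axis"))
  assert_scalar_num(amplitude, "amplitude", lower = 0)
  if (amplitude == 0) return(numeric(axis$n_gates))
  assert_scalar_num(tau, "tau")
  if (tau <= 0) stop("`tau` must be positive when amplitude > 0")
  d <- exp(-(axis$t - axis$origin) / tau)
  d * (amplitude / sum(d))
}

#' Convolve a decay with the instrument response function
#'
#' Discrete linear convolution truncated to the gate window. For a unit-sum
#' IRF the output sum never exceeds the input sum, with equality when no mass
#' is pushed past the last gate.
#'
#' @param decay numeric vector (length `n_gates`).
#' @param irf an `irf` object with matching kernel length.
#' @return numeric vector of length `n_gates`.
#' @export
convolve_irf <- function(decay, irf) {
  stopifnot(inherits(irf, "irf"))
  k <- irf$kernel
  if (length(decay) != length(k))
    stop("decay length (", length(decay), ") must match IRF kernel length (",
         length(k), ")")
  n <- length(decay)
  # full linear convolution, keep the first n samples
  out <- stats::convolve(c(decay, numeric(n)), rev(c(k, numeric(n))),
                         type = "open")[seq_len(n)]
  out[abs(out) < 1e-14 * max(abs(out), 1)] <- 0  # FFT dust on exact zeros
  pmax(out, 0)
}

#' Per-pixel temporal point spread functions of a scene
#'
#' For every foreground pixel builds its mono-exponential decay, convolves it
#' with the IRF, and renormalizes the resulting TPSF so its time sum equals
#' the pixel's CW intensity exactly (photon conservation; any IRF tail pushed
#' past the window is folded back by the normalization). Exploits the small
#' number of distinct lifetimes per scene: one kernel per unique lifetime.
#'
#' @param scene a [lifetime_scene()].
#' @param irf an `irf`.
#' @param axis a [temporal_axis()].
#' @return object of class `tpsf_cube`: `cube` (`npix x n_gates` matrix,
#'   pixels column-major), `side`, `axis`.
#' @export
simulate_tpsf_cube <- function(scene, irf, axis = temporal_axis()) {
  stopifnot(inherits(scene, "lifetime_scene"))
  side <- nrow(scene$intensity)
  npix <- side * side
  cube <- matrix(0, npix, axis$n_gates)
  amp <- as.vector(scene$intensity)
  tau <- as.vector(scene$lifetime)
  fg <- amp > 0
  if (any(fg)) {
    taus <- unique(tau[fg])
    kern <- matrix(0, length(taus), axis$n_gates)
    for (i in seq_along(taus)) {
      d <- simulate_decay(1, taus[i], axis)
      h <- convolve_irf(d, irf)
      kern[i, ] <- h / sum(h)
    }
    cube[fg, ] <- kern[match(tau[fg], taus), , drop = FALSE] * amp[fg]
  }
  structure(list(cube = cube, side = side, axis = axis), class = "tpsf_cube")
}

#' @export
print.tpsf_cube <- function(x, ...) {
  cat(sprintf("<tpsf_cube> %dx%dx%d, total %.4g counts\n",
              x$side, x$side, x$axis$n_gates, sum(x$cube)))
  invisible(x)
}

#' Project a TPSF cube to single-pixel pattern measurements
#'
#' Each measurement trace is the pattern-weighted sum of all pixel TPSFs:
#' `data[g, k] = sum_ij pattern_k[i, j] * cube[i, j, g]`. For a
#' complementary-pair bank the signed +1/-1 weights (positive minus negative
#' pattern) are used instead.
#'
#' @param tpsf a `tpsf_cube`.
#' @param bank a [build_hadamard_bank()] pattern bank of matching side.
#' @return object of class `measurement_set`: `data` (`n_gates x k` matrix),
#'   `axis`, `bank_id`, `irf_id`, `noisy`.
#' @export
project_measurements <- function(tpsf, bank) {
  stopifnot(inherits(tpsf, "tpsf_cube"), inherits(bank, "pattern_bank"))
  if (bank$side != tpsf$side)
    stop("bank side (", bank$side, ") does not match cube side (", tpsf$side, ")")
  W <- if (bank$source == "hadamard_pair") bank$H_rows else bank$P
  data <- t(W %*% tpsf$cube)  # (k x npix)(npix x g) -> transpose to g x k
  structure(list(data = data, axis = tpsf$axis, bank_id = bank$bank_id,
                 irf_id = NA_character_, noisy = FALSE),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %d gates x %d patterns (%s), bank %s\n",
              nrow(x$data), ncol(x$data),
              if (x$noisy) "noisy" else "noiseless", x$bank_id))
  invisible(x)
}

#' Apply Poisson photon-counting noise to a measurement set
#'
#' Replaces every entry by a Poisson draw with that entry as its mean.
#' Zero-mean entries stay exactly zero. Seeded and reproducible.
#'
#' @param m a noiseless `measurement_set` with nonnegative entries.
#' @param rng_seed integer seed.
#' @return a noisy `measurement_set` with integer counts.
#' @export
add_poisson_noise <- function(m, rng_seed) {
  stopifnot(inherits(m, "measurement_set"))
  if (any(m$data < 0))
    stop("Poisson noise requires nonnegative measurement means")
  noisy <- with_seed(rng_seed, {
    matrix(stats::rpois(length(m$data), as.vector(m$data)),
           nrow(m$data), ncol(m$data))
  })
  m$data <- noisy
  m$noisy <- TRUE
  m
}

#' Simulate one full measurement sample from a scene
#'
#' Full generator chain: per-pixel decay, IRF convolution, Hadamard-weighted
#' projection, optional Poisson noise. Returns the paired network/solver input
#' and its ground truth.
#'
#' @param scene a [lifetime_scene()].
#' @param bank a pattern bank.
#' @param irf an `irf`.
#' @param axis a [temporal_axis()].
#' @param rng_seed seed for the noise draw.
#' @param noisy add Poisson noise (default `TRUE`).
#' @return list with elements `measurements` (a `measurement_set` whose
#'   `irf_id` records the IRF used) and `scene`.
#' @export
simulate_sample <- function(scene, bank, irf, axis = temporal_axis(),
                            rng_seed = 1L, noisy = TRUE) {
  tpsf <- simulate_tpsf_cube(scene, irf, axis)
  m <- project_measurements(tpsf, bank)
  m$irf_id <- sprintf("irf_fwhm%.3g_t0%.3g", irf$fwhm, irf$t0)
  if (noisy) m <- add_poisson_noise(m, rng_seed)
  list(measurements = m, scene = scene)
}

#' Exact inversion of complete-bank measurements
#'
#' With a complete bank (`k == order == side^2`) the per-gate linear system is
#' square and the binarized patterns relate to the signed Hadamard rows by
#' `P = (H + 1) / 2`, so `H x = 2 s - sum(x)` where `sum(x)` is the full-field
#' (DC pattern) measurement. Orthogonality `H H^T = order * I` then recovers
#' every gate image in closed form. Serves as the noiseless reconstruction
#' oracle against which iterative solvers are checked.
#'
#' @param m a `measurement_set` acquired with a complete bank.
#' @param bank the complete [build_hadamard_bank()] used.
#' @return a `tpsf_cube`.
#' @export
invert_complete_bank <- function(m, bank) {
  stopifnot(inherits(m, "measurement_set"), inherits(bank, "pattern_bank"))
  if (bank$k != bank$order)
    stop("complete-bank inversion needs k == order (got k = ", bank$k, ")")
  S <- t(m$data)                      # k x gates
  if (bank$source == "hadamard_pair") {
    X <- crossprod(bank$H_rows, S) / bank$order
  } else {
    dc <- which(rowSums(bank$H_rows) == bank$order)[1]
    if (is.na(dc)) stop("complete positive bank must contain the full-field pattern")
    tot <- S[dc, ]                    # sum over pixels per gate
    X <- crossprod(bank$H_rows, sweep(2 * S, 2, tot, "-")) / bank$order
  }
  structure(list(cube = X, side = bank$side, axis = m$axis), class = "tpsf_cube")
}

#' Bin a measurement set along the gate axis
#'
#' Sums `factor` adjacent gates, preserving total counts, and rescales the
#' temporal axis accordingly. Useful to trade temporal resolution for
#' reconstruction speed.
#'
#' @param m a `measurement_set`.
#' @param factor integer binning factor dividing `n_gates`.
#' @return a `measurement_set` with `n_gates / factor` gates.
#' @export
bin_gates <- function(m, factor) {
  stopifnot(inherits(m, "measurement_set"))
  factor <- as.integer(factor)
  if (factor == 1L) return(m)
  G <- nrow(m$data)
  if (G %% factor != 0) stop("`factor` must divide the number of gates")
  grp <- rep(seq_len(G %/% factor), each = factor)
  m$data <- rowsum(m$data, grp, reorder = TRUE)
  m$axis <- temporal_axis(G %/% factor, m$axis$gate_width * factor, m$axis$origin)
  m
}
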