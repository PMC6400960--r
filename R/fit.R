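#' Configuration of the least-squares lifetime fit
#'
#' @param tail_start gates after the TPSF peak at which the tail fit begins.
#' @param min_counts floor for gates included in the fit; interpreted as
#'   `max(min_counts, min_counts_frac * peak)` per pixel.
#' @param min_counts_frac fractional floor relative to the TPSF peak.
#' @param bg_threshold fraction of the maximum CW intensity below which a
#'   pixel is treated as background (lifetime forced to 0).
#' @param tau_max upper bound (ns) on a physically plausible fitted lifetime;
#'   fits beyond it are flagged invalid and reported as 0, like failed fits.
#' @param weighted weight the log-linear regression by counts (the Poisson
#'   maximum-likelihood weighting for log-transformed count data); `FALSE`
#'   gives plain ordinary least squares.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(tail_start = 5L, min_counts = 5, min_counts_frac = 0.01,
                       bg_threshold = 0.1, tau_max = 5, weighted = TRUE) {
  assert_scalar_num(tail_start, "tail_start", lower = 0)
  assert_scalar_num(min_counts, "min_counts", lower = 0)
  assert_scalar_num(min_counts_frac, "min_counts_frac", lower = 0, upper = 1)
  assert_scalar_num(bg_threshold, "bg_threshold")
  if (bg_threshold <= 0 || bg_threshold >= 1)
    stop("`bg_threshold` must lie strictly between 0 and 1")
  assert_scalar_num(tau_max, "tau_max")
  if (tau_max <= 0) stop("`tau_max` must be positive")
  structure(list(tail_start = as.integer(tail_start), min_counts = min_counts,
                 min_counts_frac = min_counts_frac, bg_threshold = bg_threshold,
                 tau_max = tau_max, weighted = isTRUE(weighted)),
            class = "fit_config")
}

#' Gate index of the 5% rising edge of a trace
#'
#' First gate (0-based) at which the trace reaches 5% of its own maximum,
#' searched from gate 0. Used to align measured traces to simulated ones and
#' cancel laser jitter.
#'
#' @param trace numeric vector with a positive maximum.
#' @param frac rising-point fraction (default 0.05).
#' @return integer 0-based gate index.
#' @export
rising_edge_index <- function(trace, frac = 0.05) {
  m <- max(trace)
  if (!is.finite(m) || m <= 0) stop("trace must have a positive maximum")
  which(trace >= frac * m)[1] - 1L
}

#' Gate shift aligning a trace's rising edge to a reference
#'
#' Returns the integer shift that brings the 5% rising point of `trace` onto
#' that of `reference` (negative when the trace lags). Apply with
#' [apply_gate_shift()], which pads with zeros rather than wrapping.
#'
#' @param trace measured trace (positive maximum).
#' @param reference reference trace (positive maximum).
#' @param frac rising-point fraction.
#' @return integer shift in gates.
#' @export
align_rising_edge <- function(trace, reference, frac = 0.05) {
  rising_edge_index(reference, frac) - rising_edge_index(trace, frac)
}

#' Shift a measurement set along the gate axis, zero-padded
#'
#' @param m a `measurement_set` (or plain gate x pattern matrix).
#' @param shift integer gate shift; positive moves traces to later gates.
#' @return object of the same kind as `m`.
#' @export
apply_gate_shift <- function(m, shift) {
  shift_mat <- function(D, s) {
    G <- nrow(D)
    out <- matrix(0, G, ncol(D))
    if (s >= 0) {
      if (s < G) out[(s + 1):G, ] <- D[seq_len(G - s), , drop = FALSE]
    } else {
      s <- -s
      if (s < G) out[seq_len(G - s), ] <- D[(s + 1):G, , drop = FALSE]
    }
    out
  }
  shift <- as.integer(shift)
  if (inherits(m, "measurement_set")) {
    m$data <- shift_mat(m$data, shift); m
  } else shift_mat(m, shift)
}

#' Fit a mono-exponential lifetime to a TPSF by log-linear least squares
#'
#' Selects tail gates from `peak + tail_start` to the last gate whose counts
#' reach the configured floor, and regresses `log(counts)` on gate time by
#' least squares (counts-weighted by default, the Poisson-appropriate
#' weighting for log counts); the lifetime is `-1/slope`. Exact on noiseless
#' exponential tails. Fewer than 3 usable gates yields `tau = 0` flagged
#' invalid.
#'
#' @param tpsf nonnegative numeric vector, not all zero.
#' @param axis a [temporal_axis()].
#' @param cfg a [fit_config()].
#' @return list: `tau` (ns), `r2`, `n_gates_used`, `valid`.
#' @export
fit_lifetime <- function(tpsf, axis, cfg = fit_config()) {
  if (any(tpsf < 0)) stop("TPSF must be nonnegative")
  if (all(tpsf == 0)) stop("TPSF is all zero")
  peak <- which.max(tpsf)
  floor_counts <- max(cfg$min_counts, cfg$min_counts_frac * tpsf[peak])
  start <- peak + cfg$tail_start
  idx_ok <- which(tpsf >= floor_counts)
  last <- if (length(idx_ok)) max(idx_ok) else 0L
  use <- integer(0)
  if (start <= last) {
    use <- start:last
    use <- use[tpsf[use] >= floor_counts]   # exclude sub-floor dips inside the window
  }
  if (length(use) < 3)
    return(list(tau = 0, r2 = NA_real_, n_gates_used = length(use), valid = FALSE))
  x <- axis$t[use]; y <- log(tpsf[use])
  w <- if (cfg$weighted) tpsf[use] else rep(1, length(use))
  xc <- x - sum(w * x) / sum(w); yc <- y - sum(w * y) / sum(w)
  slope <- sum(w * xc * yc) / sum(w * xc * xc)
  ssres <- sum(w * (yc - slope * xc)^2)
  sstot <- sum(w * yc^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else 1
  tau <- if (slope < 0) -1 / slope else 0
  valid <- slope < 0 && tau <= cfg$tau_max
  if (!valid) tau <- 0
  list(tau = tau, r2 = r2, n_gates_used = length(use), valid = valid)
}

new_recon_result <- function(intensity, lifetime, method, diagnostics = list(),
                             scene_id = NA_character_) {
  structure(list(intensity = intensity, lifetime = lifetime, method = method,
                 diagnostics = diagnostics, scene_id = scene_id),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  fg <- x$lifetime > 0
  cat(sprintf("<recon_result> %s: %dx%d, total %.4g counts, fg tau %s ns\n",
              x$method, nrow(x$intensity), ncol(x$intensity), sum(x$intensity),
              if (any(fg)) paste(signif(range(x$lifetime[fg]), 3), collapse = "-")
              else "-"))
  invisible(x)
}

#' Classical reconstruction: TV inversion then lifetime fitting
#'
#' The classical two-step workflow: (1) TV-regularized inversion of
#' `P x(t) = s(t)` for every time gate, yielding the TPSF cube; (2) per-pixel
#' log-linear least-squares lifetime fitting on the reconstructed TPSFs. The
#' intensity image is obtained from a dedicated TV inversion of the
#' time-summed measurement vector (the same linear system aggregated over all
#' gates, so every detected photon constrains one well-posed solve); the
#' per-pixel time sum of the cube is available as
#' `diagnostics$intensity_timesum`. Pixels whose intensity falls below
#' `bg_threshold` times the image maximum are background and get lifetime
#' exactly 0.
#'
#' @param m a `measurement_set`.
#' @param bank pattern bank used for acquisition.
#' @param tv_cfg a [tv_config()].
#' @param fit_cfg a [fit_config()].
#' @param gate_bin optional gate binning factor applied before inversion
#'   (counts-preserving; trades temporal resolution for speed).
#' @param reference_trace optional full-field reference trace; when given, the
#'   measured gate axis is first shifted so the 5% rising point of the
#'   full-field (first) measurement matches the reference.
#' @param track_objective record the TV objective per outer iteration.
#' @return a `recon_result` with method `"tvrecon"`; diagnostics carry the
#'   per-pixel fit R^2 and gates used, plus solver iteration counts.
#' @export
reconstruct_tv <- function(m, bank, tv_cfg = tv_config(), fit_cfg = fit_config(),
                           gate_bin = 1L, reference_trace = NULL,
                           track_objective = FALSE) {
  stopifnot(inherits(m, "measurement_set"))
  if (!is.null(reference_trace)) {
    sh <- align_rising_edge(m$data[, 1], reference_trace)
    m <- apply_gate_shift(m, sh)
  }
  stot <- matrix(colSums(m$data), nrow = 1)
  m <- bin_gates(m, gate_bin)
  if (gate_bin > 1) {
    # keep the fit window's *time* offset: tail_start is calibrated in raw
    # gates, so rescale it to the binned axis
    fit_cfg$tail_start <- as.integer(ceiling(fit_cfg$tail_start / gate_bin))
  }
  tpsf <- assemble_tpsfs(m, bank, tv_cfg, track_objective = track_objective)
  side <- bank$side
  int_solve <- tv_solve_gates(stot, bank, tv_cfg)
  intensity <- matrix(int_solve$X[, 1], side, side)
  fg <- intensity >= fit_cfg$bg_threshold * max(intensity)
  lifetime <- matrix(0, side, side)
  r2 <- matrix(NA_real_, side, side)
  gates_used <- matrix(0L, side, side)
  for (p in which(as.vector(fg))) {
    f <- fit_lifetime(tpsf$cube[p, ], tpsf$axis, fit_cfg)
    lifetime[p] <- f$tau
    r2[p] <- f$r2
    gates_used[p] <- f$n_gates_used
  }
  new_recon_result(intensity, lifetime, "tvrecon",
                   diagnostics = c(list(r2 = r2, gates_used = gates_used,
                                        foreground = fg,
                                        intensity_timesum =
                                          matrix(rowSums(tpsf$cube), side, side)),
                                   attr(tpsf, "diagnostics")))
}
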