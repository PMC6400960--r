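#' Configuration of the total-variation gate solver
#'
#' Parameters of the augmented-Lagrangian (ADMM) solver for the per-gate
#' inverse problem `P x = s` with anisotropic total-variation regularization:
#' `min_x TV(x) + mu/2 ||P x - s||^2`.
#'
#' @param mu data-fidelity weight (> 0).
#' @param beta gradient-splitting penalty (> 0).
#' @param tol relative-change stopping tolerance on the iterate.
#' @param max_iter maximum outer iterations.
#' @param nonneg project the image onto `x >= 0` each outer iteration.
#' @param n_cg inner conjugate-gradient steps per x-update.
#' @param isotropic use isotropic TV (joint shrinkage of the two gradient
#'   components); `FALSE` gives anisotropic TV.
#' @return object of class `tv_config`.
#' @export
tv_config <- function(mu = 8, beta = 2^5, tol = 1e-4, max_iter = 100L,
                      nonneg = TRUE, n_cg = 6L, isotropic = TRUE) {
  assert_scalar_num(mu, "mu"); assert_scalar_num(beta, "beta")
  assert_scalar_num(tol, "tol"); assert_scalar_num(max_iter, "max_iter", lower = 1)
  if (mu <= 0 || beta <= 0 || tol <= 0) stop("mu, beta and tol must be positive")
  structure(list(mu = mu, beta = beta, tol = tol,
                 max_iter = as.integer(max_iter), nonneg = isTRUE(nonneg),
                 n_cg = as.integer(n_cg), isotropic = isTRUE(isotropic)),
            class = "tv_config")
}

# forward-difference index maps (Neumann boundary) for a side x side grid,
# pixels column-major
tv_diff_ops <- function(side) {
  npix <- side * side
  p <- seq_len(npix)
  i <- ((p - 1L) %% side) + 1L        # row
  j <- ((p - 1L) %/% side) + 1L       # col
  list(
    right = ifelse(j < side, p + side, p),   # horizontal neighbour (same where j==side -> diff 0)
    left  = ifelse(j > 1L, p - side, NA_integer_),
    down  = ifelse(i < side, p + 1L, p),
    up    = ifelse(i > 1L, p - 1L, NA_integer_),
    j = j, i = i, side = side, npix = npix
  )
}

dh_fwd <- function(X, ops) X[ops$right, , drop = FALSE] - X
dv_fwd <- function(X, ops) X[ops$down, , drop = FALSE] - X

# adjoints of the forward differences above
dh_adj <- function(Y, ops) {
  Z <- -Y
  has <- !is.na(ops$left)
  Z[has, ] <- Z[has, , drop = FALSE] + Y[ops$left[has], , drop = FALSE]
  Z
}
dv_adj <- function(Y, ops) {
  Z <- -Y
  has <- !is.na(ops$up)
  Z[has, ] <- Z[has, , drop = FALSE] + Y[ops$up[has], , drop = FALSE]
  Z
}

soft_shrink <- function(X, kappa) sign(X) * pmax(abs(X) - kappa, 0)

# columnwise conjugate gradient for (mu AtA + beta L) X = RHS, warm-started
tv_cg <- function(X, RHS, AtA, ops, mu, beta, n_cg) {
  applyM <- function(V)
    mu * (AtA %*% V) +
      beta * (dh_adj(dh_fwd(V, ops), ops) + dv_adj(dv_fwd(V, ops), ops))
  R <- RHS - applyM(X)
  P <- R
  rs <- colSums(R * R)
  rs0 <- pmax(rs, .Machine$double.xmin)
  for (it in seq_len(n_cg)) {
    if (all(rs / rs0 < 1e-12)) break
    MP <- applyM(P)
    alpha <- rs / pmax(colSums(P * MP), .Machine$double.xmin)
    X <- X + sweep(P, 2, alpha, "*")
    R <- R - sweep(MP, 2, alpha, "*")
    rs_new <- colSums(R * R)
    P <- R + sweep(P, 2, rs_new / pmax(rs, .Machine$double.xmin), "*")
    rs <- rs_new
  }
  X
}

#' Solve all time gates of a measurement set by TV-regularized inversion
#'
#' Alternating-minimization augmented Lagrangian (ADMM) for anisotropic TV:
#' gradient splitting variables are updated by soft shrinkage, the image by a
#' few warm-started conjugate-gradient steps on the normal equations, and the
#' scaled multipliers by the constraint residual. All gates share the
#' factor-free operator applications, so the whole gate stack is solved in one
#' batched run. Deterministic (zero initialization).
#'
#' @param S `n_gates x k` measurement matrix (one gate per row).
#' @param bank the [build_hadamard_bank()] used for acquisition.
#' @param cfg a [tv_config()].
#' @param track_objective record the primal objective
#'   `TV(x) + mu/2 ||P x - s||^2` (summed over gates) each outer iteration.
#' @return list: `X` (`npix x n_gates` image stack), `iterations`,
#'   `objective` (numeric vector or `NULL`), `rel_change`.
#' @export
tv_solve_gates <- function(S, bank, cfg = tv_config(), track_objective = FALSE) {
  stopifnot(inherits(bank, "pattern_bank"), inherits(cfg, "tv_config"))
  if (!all(is.finite(S))) stop("measurements must be finite")
  W <- if (bank$source == "hadamard_pair") bank$H_rows else bank$P
  if (all(W == 0)) stop("pattern bank is all-zero")
  if (ncol(S) != nrow(W))
    stop("signal width (", ncol(S), ") must equal bank size (", nrow(W), ")")
  ops <- tv_diff_ops(bank$side)
  G <- nrow(S)
  B <- t(S)                                  # k x G
  AtA <- crossprod(W)                        # npix x npix
  AtB <- crossprod(W, B)                     # npix x G
  mu <- cfg$mu; beta <- cfg$beta

  X <- matrix(0, ops$npix, G)
  Y1 <- matrix(0, ops$npix, G); Y2 <- Y1
  U1 <- Y1; U2 <- Y1
  obj <- if (track_objective) numeric(0) else NULL
  rel <- Inf; it <- 0L
  while (it < cfg$max_iter) {
    it <- it + 1L
    RHS <- mu * AtB + beta * (dh_adj(Y1 - U1, ops) + dv_adj(Y2 - U2, ops))
    Xnew <- tv_cg(X, RHS, AtA, ops, mu, beta, cfg$n_cg)
    if (cfg$nonneg) Xnew[Xnew < 0] <- 0
    DH <- dh_fwd(Xnew, ops); DV <- dv_fwd(Xnew, ops)
    if (cfg$isotropic) {
      A1 <- DH + U1; A2 <- DV + U2
      nrm <- sqrt(A1 * A1 + A2 * A2)
      scl <- ifelse(nrm > 0, pmax(nrm - 1 / beta, 0) / nrm, 0)
      Y1 <- scl * A1
      Y2 <- scl * A2
    } else {
      Y1 <- soft_shrink(DH + U1, 1 / beta)
      Y2 <- soft_shrink(DV + U2, 1 / beta)
    }
    U1 <- U1 + DH - Y1
    U2 <- U2 + DV - Y2
    rel <- sqrt(sum((Xnew - X)^2)) / max(sqrt(sum(X^2)), .Machine$double.xmin)
    X <- Xnew
    if (track_objective) {
      R <- W %*% X - B
      tv_term <- if (cfg$isotropic) sum(sqrt(DH * DH + DV * DV))
                 else sum(abs(DH)) + sum(abs(DV))
      obj <- c(obj, tv_term + mu / 2 * sum(R * R))
    }
    if (rel < cfg$tol) break
  }
  list(X = X, iterations = it, objective = obj, rel_change = rel)
}

#' Solve a single time gate
#'
#' Convenience wrapper around [tv_solve_gates()] for one gate signal.
#'
#' @param signal length-`k` measurement vector for one gate.
#' @param bank pattern bank.
#' @param cfg a [tv_config()].
#' @return `side x side` reconstructed image matrix.
#' @export
solve_gate <- function(signal, bank, cfg = tv_config()) {
  res <- tv_solve_gates(matrix(signal, nrow = 1), bank, cfg)
  matrix(res$X[, 1], bank$side, bank$side)
}

#' Assemble the TPSF cube from a measurement set
#'
#' Runs the TV gate solver over every gate of `m` and stacks the per-gate
#' images into a cube. Negative values are clipped at zero when the solver
#' does not enforce nonnegativity.
#'
#' @param m a `measurement_set`.
#' @param bank pattern bank.
#' @param cfg a [tv_config()].
#' @param track_objective see [tv_solve_gates()].
#' @return a `tpsf_cube` with attribute `diagnostics` (iterations, objective,
#'   relative change at stop).
#' @export
assemble_tpsfs <- function(m, bank, cfg = tv_config(), track_objective = FALSE) {
  stopifnot(inherits(m, "measurement_set"))
  if (nrow(m$data) < 2) stop("need at least 2 gates")
  res <- tv_solve_gates(m$data, bank, cfg, track_objective = track_objective)
  X <- res$X
  if (!cfg$nonneg) X[X < 0] <- 0
  structure(list(cube = X, side = bank$side, axis = m$axis),
            class = "tpsf_cube",
            diagnostics = list(iterations = res$iterations,
                               objective = res$objective,
                               rel_change = res$rel_change))
}
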