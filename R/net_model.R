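#' Configuration of the direct reconstruction network
#'
#' Architecture and training hyperparameters for the convolutional network
#' that maps a raw `n_gates x n_meas` time-resolved compressed measurement to
#' paired 32 x 32 intensity (counts) and lifetime (ns) images. The loss is
#' `MSE(intensity) + lifetime_loss_weight * MSE(lifetime)`; the lifetime term
#' gets a large weight because its numeric range (ns) is tiny compared with
#' photon counts. The learning rate halves every `lr_halving_period` epochs
#' from `base_lr`, and training stops early when the validation lifetime MAE
#' has not improved for `patience` consecutive epochs.
#'
#' @param n_gates raw time gates of the input (default 256).
#' @param n_meas number of compressed measurements (512, or e.g. 400 for the
#'   reduced pattern-pair acquisition; only the first mapping resizes).
#' @param img_side output image side (default 32).
#' @param gate_pool fixed temporal average-pooling factor applied to the input
#'   gates before the measurement-to-pixel mapping (must divide `n_gates`).
#' @param res_channels channels of the residual blocks.
#' @param recon_c1,recon_c2 channel widths inside each reconstruction block.
#' @param recon_k1,recon_k3 kernel sizes of the first/last reconstruction-block
#'   convolutions.
#' @param mix_kernel kernel size of the common-segment mixing convolution.
#' @param conv1d_kernel,conv1d_stride,conv1d_filters 1D convolution along the
#'   gate axis at the entry of the lifetime segment.
#' @param intensity_gain,lifetime_gain fixed (non-learned) output scales
#'   mapping unit-scale network activations onto counts / ns.
#' @param skip_connections add output-level residual shortcuts: a per-channel
#'   linear time-sum readout for intensity and a temporal-centroid readout
#'   (learnable scale and offset) for lifetime, both fed by the common
#'   segment's pre-normalization gate images. The convolutional heads then
#'   learn corrections rather than the full mapping, which is what makes
#'   small-sample CPU training converge.
#' @param gate_width,irf_t0 acquisition constants (ns) used to initialize the
#'   centroid readout's scale and offset; defaults match the forward model.
#' @param lifetime_loss_weight weight of the lifetime MSE term (default 1e5).
#' @param base_lr initial learning rate (default 1e-3).
#' @param lr_halving_period epochs between learning-rate halvings (default 10).
#' @param patience early-stopping patience in epochs (default 10).
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param rng_seed seed for parameter initialization and batch shuffling.
#' @return object of class `net_config`.
#' @export
net_config <- function(n_gates = 256L, n_meas = 512L, img_side = 32L,
                       gate_pool = 8L, res_channels = 8L,
                       recon_c1 = 8L, recon_c2 = 4L,
                       recon_k1 = 5L, recon_k3 = 3L, mix_kernel = 1L,
                       conv1d_kernel = 9L, conv1d_stride = 4L,
                       conv1d_filters = 4L,
                       intensity_gain = 400, lifetime_gain = 1,
                       skip_connections = TRUE,
                       gate_width = 0.040, irf_t0 = 1.0,
                       lifetime_loss_weight = 1e5,
                       base_lr = 1e-3, lr_halving_period = 10L,
                       patience = 10L, batch_size = 16L, max_epochs = 30L,
                       rng_seed = 42L) {
  cfg <- lapply(
    list(n_gates = n_gates, n_meas = n_meas, img_side = img_side,
         gate_pool = gate_pool, res_channels = res_channels,
         recon_c1 = recon_c1, recon_c2 = recon_c2, recon_k1 = recon_k1,
         recon_k3 = recon_k3, mix_kernel = mix_kernel,
         conv1d_kernel = conv1d_kernel, conv1d_stride = conv1d_stride,
         conv1d_filters = conv1d_filters, intensity_gain = intensity_gain,
         lifetime_gain = lifetime_gain,
         skip_connections = skip_connections,
         gate_width = gate_width, irf_t0 = irf_t0,
         lifetime_loss_weight = lifetime_loss_weight, base_lr = base_lr,
         lr_halving_period = lr_halving_period, patience = patience,
         batch_size = batch_size, max_epochs = max_epochs,
         rng_seed = rng_seed),
    function(x) if (is.numeric(x) && x == round(x) &&
                    abs(x) < .Machine$integer.max) as.integer(x) else x)
  cfg$intensity_gain <- as.numeric(intensity_gain)
  cfg$lifetime_gain <- as.numeric(lifetime_gain)
  cfg$skip_connections <- isTRUE(skip_connections)
  cfg$gate_width <- as.numeric(gate_width)
  cfg$irf_t0 <- as.numeric(irf_t0)
  cfg$lifetime_loss_weight <- as.numeric(lifetime_loss_weight)
  cfg$base_lr <- as.numeric(base_lr)
  if (cfg$lifetime_loss_weight <= 0) stop("lifetime_loss_weight must be > 0")
  if (cfg$base_lr <= 0) stop("base_lr must be > 0")
  if (cfg$n_meas < 1) stop("n_meas must be >= 1")
  if (cfg$n_gates %% cfg$gate_pool != 0)
    stop("gate_pool must divide n_gates")
  cfg$g_pooled <- cfg$n_gates %/% cfg$gate_pool
  if (cfg$g_pooled < cfg$conv1d_kernel)
    stop("conv1d kernel longer than the pooled gate axis")
  structure(cfg, class = "net_config")
}

#' Learning rate at a given epoch
#'
#' `base_lr * 0.5^(floor(epoch / lr_halving_period))`, epochs counted from 0.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [net_config()].
#' @return numeric learning rate.
#' @export
lr_at_epoch <- function(epoch, cfg) {
  cfg$base_lr * 0.5^(epoch %/% cfg$lr_halving_period)
}

res_init <- function(cin, c) {
  blk <- list(convA = conv2d_init(cin, c, 3L), bnA = bn_init(c),
              convB = conv2d_init(c, c, 3L), bnB = bn_init(c))
  if (cin != c) blk$proj <- conv2d_init(cin, c, 1L)
  blk
}

recon_init <- function(cin, cout, cfg) {
  list(conv1 = conv2d_init(cin, cfg$recon_c1, cfg$recon_k1),
       bn1 = bn_init(cfg$recon_c1),
       conv2 = conv2d_init(cfg$recon_c1, cfg$recon_c2, 1L),
       bn2 = bn_init(cfg$recon_c2),
       conv3 = conv2d_init(cfg$recon_c2, cout, cfg$recon_k3))
}

#' Build an untrained direct reconstruction network
#'
#' Three segments: (1) a common segment — a measurement-to-pixel fully
#' connected mapping shared across all gates, a transpose bringing the pixel
#' maps in front, and a mixing convolution with batch normalization and
#' rectifier; (2) an intensity segment — one residual block and one
#' reconstruction block; (3) a lifetime segment — a 1D convolution along the
#' gate axis, two residual blocks and two reconstruction blocks.
#'
#' When a pattern bank is supplied, the fully connected mapping is initialized
#' at the bank's least-norm pseudo-inverse instead of random weights, so the
#' common segment starts as the exact linear inverse of the acquisition and
#' gradient descent only has to learn denoising and lifetime extraction. This
#' physics-informed initialization is what makes small-sample CPU training
#' converge in few epochs.
#'
#' @param cfg a [net_config()].
#' @param bank optional [build_hadamard_bank()] with `k == cfg$n_meas`,
#'   enabling pseudo-inverse initialization of the common segment.
#' @return object of class `netflics_model` (untrained parameter store).
#' @export
build_model <- function(cfg = net_config(), bank = NULL) {
  stopifnot(inherits(cfg, "net_config"))
  G <- cfg$g_pooled
  fc_W0 <- NULL
  if (!is.null(bank)) {
    stopifnot(inherits(bank, "pattern_bank"))
    if (bank$k != cfg$n_meas || bank$side != cfg$img_side)
      stop("bank shape does not match the network configuration")
    W <- if (bank$source == "hadamard_pair") bank$H_rows else bank$P
    fc_W0 <- t(t(W) %*% solve(tcrossprod(W)))   # n_meas x npix
  }
  with_seed(cfg$rng_seed, {
    c1dL <- (G - cfg$conv1d_kernel) %/% cfg$conv1d_stride + 1L
    fc0 <- fc_init(cfg$n_meas, cfg$img_side^2)
    if (!is.null(fc_W0)) {
      fc0$scale <- mean(abs(fc_W0))
      fc0$W <- fc_W0 / fc0$scale
    }
    mix0 <- conv2d_init(G, G, cfg$mix_kernel)
    # identity-initialized mixing: the centre tap starts as the unit map so
    # the heads see the (pseudo-inverse) gate images unscrambled at epoch 0
    ctr <- (cfg$mix_kernel^2 + 1L) %/% 2L
    mix0$W[] <- 0
    mix0$W[((ctr - 1L) * G + 1L):(ctr * G), ] <- diag(G)
    params <- list(
      fc = fc0,
      mix = list(conv = mix0, bn = bn_init(G)),
      int = list(res1 = res_init(G, cfg$res_channels),
                 recon1 = recon_init(cfg$res_channels, 1L, cfg)),
      tau = list(c1d = conv1d_init(G, cfg$conv1d_kernel, cfg$conv1d_stride,
                                   cfg$conv1d_filters),
                 bn1d = bn_init(c1dL * cfg$conv1d_filters),
                 res1 = res_init(c1dL * cfg$conv1d_filters, cfg$res_channels),
                 res2 = res_init(cfg$res_channels, cfg$res_channels),
                 recon1 = recon_init(cfg$res_channels, cfg$recon_c2, cfg),
                 recon2 = recon_init(cfg$recon_c2, 1L, cfg))
    )
    if (cfg$skip_connections) {
      bin <- cfg$gate_width * cfg$gate_pool
      params$skip <- list(
        w_int = rep(cfg$gate_pool, G),            # time-sum readout weights
                                                  # (gate images hold pooled means)
        alpha = bin,                              # centroid scale: ns per bin
        c0 = cfg$irf_t0 / bin,                    # centroid offset, in bins
        kappa = 10                                # brightness soft-gate (counts)
      )
    }
    structure(list(params = params, cfg = cfg, history = NULL,
                   best_epoch = NA_integer_, trained = FALSE),
              class = "netflics_model")
  })
}

#' @export
print.netflics_model <- function(x, ...) {
  np <- length(unlist(x$params))
  cat(sprintf("<netflics_model> %s, input %dx%d -> 2 x %dx%d, %d parameters\n",
              if (x$trained) "trained" else "untrained",
              x$cfg$n_gates, x$cfg$n_meas, x$cfg$img_side, x$cfg$img_side, np))
  if (x$trained)
    cat(sprintf("  best epoch %d of %d (val lifetime MAE %.4f ns)\n",
                x$best_epoch, nrow(x$history),
                min(x$history$val_lifetime_mae)))
  invisible(x)
}

# block forward/backward ------------------------------------------------------

res_fwd <- function(M, blk, g3, g1, training, run, key) {
  a1 <- conv2d_fwd(M, blk$convA, g3)
  b1 <- bn_collect(a1$out, blk$bnA, training, run, paste0(key, ".bnA"))
  r1 <- relu_fwd(b1$out)
  a2 <- conv2d_fwd(r1$out, blk$convB, g3)
  b2 <- bn_collect(a2$out, blk$bnB, training, run, paste0(key, ".bnB"))
  skip <- if (!is.null(blk$proj)) conv2d_fwd(M, blk$proj, g1) else NULL
  s <- b2$out + if (is.null(skip)) M else skip$out
  r2 <- relu_fwd(s)
  list(out = r2$out,
       cache = list(a1 = a1, b1 = b1, r1 = r1, a2 = a2, b2 = b2,
                    skip = skip, r2 = r2))
}

res_bwd <- function(dY, cache, blk, g3, g1) {
  ds <- relu_bwd(dY, cache$r2$cache)
  gb2 <- bn_bwd(ds, cache$b2$cache)
  gc2 <- conv2d_bwd(gb2$dM, cache$a2$cache, blk$convB, g3)
  dr1 <- relu_bwd(gc2$dM, cache$r1$cache)
  gb1 <- bn_bwd(dr1, cache$b1$cache)
  gc1 <- conv2d_bwd(gb1$dM, cache$a1$cache, blk$convA, g3)
  dM <- gc1$dM
  grads <- list(convA = list(W = gc1$dW, b = gc1$db),
                bnA = list(gamma = gb1$dgamma, beta = gb1$dbeta),
                convB = list(W = gc2$dW, b = gc2$db),
                bnB = list(gamma = gb2$dgamma, beta = gb2$dbeta))
  if (!is.null(blk$proj)) {
    gp <- conv2d_bwd(ds, cache$skip$cache, blk$proj, g1)
    dM <- dM + gp$dM
    grads$proj <- list(W = gp$dW, b = gp$db)
  } else {
    dM <- dM + ds
  }
  list(dM = dM, grads = grads)
}

recon_fwd <- function(M, blk, gk1, g1, gk3, training, run, key, final_relu) {
  a1 <- conv2d_fwd(M, blk$conv1, gk1)
  b1 <- bn_collect(a1$out, blk$bn1, training, run, paste0(key, ".bn1"))
  r1 <- relu_fwd(b1$out)
  a2 <- conv2d_fwd(r1$out, blk$conv2, g1)
  b2 <- bn_collect(a2$out, blk$bn2, training, run, paste0(key, ".bn2"))
  r2 <- relu_fwd(b2$out)
  a3 <- conv2d_fwd(r2$out, blk$conv3, gk3)
  r3 <- if (final_relu) relu_fwd(a3$out) else NULL
  list(out = if (final_relu) r3$out else a3$out,
       cache = list(a1 = a1, b1 = b1, r1 = r1, a2 = a2, b2 = b2, r2 = r2,
                    a3 = a3, r3 = r3))
}

recon_bwd <- function(dY, cache, blk, gk1, g1, gk3) {
  if (!is.null(cache$r3)) dY <- relu_bwd(dY, cache$r3$cache)
  gc3 <- conv2d_bwd(dY, cache$a3$cache, blk$conv3, gk3)
  dr2 <- relu_bwd(gc3$dM, cache$r2$cache)
  gb2 <- bn_bwd(dr2, cache$b2$cache)
  gc2 <- conv2d_bwd(gb2$dM, cache$a2$cache, blk$conv2, g1)
  dr1 <- relu_bwd(gc2$dM, cache$r1$cache)
  gb1 <- bn_bwd(dr1, cache$b1$cache)
  gc1 <- conv2d_bwd(gb1$dM, cache$a1$cache, blk$conv1, gk1)
  list(dM = gc1$dM,
       grads = list(conv1 = list(W = gc1$dW, b = gc1$db),
                    bn1 = list(gamma = gb1$dgamma, beta = gb1$dbeta),
                    conv2 = list(W = gc2$dW, b = gc2$db),
                    bn2 = list(gamma = gb2$dgamma, beta = gb2$dbeta),
                    conv3 = list(W = gc3$dW, b = gc3$db)))
}

bn_collect <- function(M, par, training, run, key) {
  r <- bn_fwd(M, par, training)
  if (training && !is.null(run)) run[[key]] <- r$new_run
  r
}

net_geoms <- function(cfg, B) {
  side <- cfg$img_side
  ks <- unique(c(cfg$mix_kernel, 3L, 1L, cfg$recon_k1, cfg$recon_k3))
  g <- lapply(ks, function(k) geom_cached(side, k, B))
  names(g) <- paste0("k", ks)
  g
}

pool_gates_array <- function(X, pool) {
  if (pool == 1L) return(X)
  d <- dim(X)
  if (d[2] %% pool != 0) stop("gate_pool must divide the gate count")
  out <- array(0, c(d[1], d[2] %/% pool, d[3]))
  for (p in seq_len(pool))
    out <- out + X[, seq(p, d[2], by = pool), , drop = FALSE] / pool
  out
}

# Forward pass. X: array (B, n_gates, n_meas); already_pooled skips gate
# pooling for pre-pooled training tensors.
net_forward <- function(model, X, training = FALSE, run = NULL,
                        already_pooled = FALSE) {
  cfg <- model$cfg; par <- model$params
  if (!already_pooled) X <- pool_gates_array(X, cfg$gate_pool)
  B <- dim(X)[1]
  geoms <- net_geoms(cfg, B)
  g3 <- geoms[["k3"]]; g1 <- geoms[["k1"]]
  gk1 <- geoms[[paste0("k", cfg$recon_k1)]]
  gk3 <- geoms[[paste0("k", cfg$recon_k3)]]
  gmix <- geoms[[paste0("k", cfg$mix_kernel)]]

  fc <- fc_fwd(X, par$fc)
  M0 <- fc$out
  skip <- NULL
  if (cfg$skip_connections) {
    eps <- 1
    tvec <- seq_len(nrow(M0)) - 1
    Mc <- pmax(M0, 0)
    s <- colSums(Mc)
    m <- as.vector(tvec %*% Mc)
    tc <- m / (s + eps)
    gate <- s / (s + par$skip$kappa)    # background pixels collapse to 0
    skip <- list(int = as.vector(par$skip$w_int %*% M0),
                 tau = par$skip$alpha * (tc - par$skip$c0) * gate,
                 tc = tc, s = s, gate = gate, eps = eps, tvec = tvec,
                 pos = M0 > 0)
  }
  mx <- conv2d_fwd(M0, par$mix$conv, gmix)
  mb <- bn_collect(mx$out, par$mix$bn, training, run, "mix.bn")
  mr <- relu_fwd(mb$out)
  common <- mr$out

  ir <- res_fwd(common, par$int$res1, g3, g1, training, run, "int.res1")
  ik <- recon_fwd(ir$out, par$int$recon1, gk1, g1, gk3, training, run,
                  "int.recon1", final_relu = FALSE)
  int_out <- ik$out[1, ] * cfg$intensity_gain
  if (!is.null(skip)) int_out <- int_out + skip$int

  tc <- conv1d_fwd(common, par$tau$c1d)
  tb <- bn_collect(tc$out, par$tau$bn1d, training, run, "tau.bn1d")
  tr0 <- relu_fwd(tb$out)
  t1 <- res_fwd(tr0$out, par$tau$res1, g3, g1, training, run, "tau.res1")
  t2 <- res_fwd(t1$out, par$tau$res2, g3, g1, training, run, "tau.res2")
  t3 <- recon_fwd(t2$out, par$tau$recon1, gk1, g1, gk3, training, run,
                  "tau.recon1", final_relu = TRUE)
  t4 <- recon_fwd(t3$out, par$tau$recon2, gk1, g1, gk3, training, run,
                  "tau.recon2", final_relu = FALSE)
  tau_out <- t4$out[1, ] * cfg$lifetime_gain
  if (!is.null(skip)) tau_out <- tau_out + skip$tau

  list(int = int_out, tau = tau_out, B = B,
       cache = list(fc = fc, M0 = M0, skip = skip, mx = mx, mb = mb, mr = mr,
                    ir = ir, ik = ik, tc = tc, tb = tb, tr0 = tr0, t1 = t1,
                    t2 = t2, t3 = t3, t4 = t4, geoms = geoms))
}

# Backward pass; d_int/d_tau are gradients w.r.t. the scaled outputs.
net_backward <- function(model, fw, d_int, d_tau) {
  cfg <- model$cfg; par <- model$params; ca <- fw$cache
  geoms <- ca$geoms
  g3 <- geoms[["k3"]]; g1 <- geoms[["k1"]]
  gk1 <- geoms[[paste0("k", cfg$recon_k1)]]
  gk3 <- geoms[[paste0("k", cfg$recon_k3)]]
  gmix <- geoms[[paste0("k", cfg$mix_kernel)]]

  dik <- matrix(d_int * cfg$intensity_gain, nrow = 1)
  gik <- recon_bwd(dik, ca$ik$cache, par$int$recon1, gk1, g1, gk3)
  gir <- res_bwd(gik$dM, ca$ir$cache, par$int$res1, g3, g1)
  d_common_int <- gir$dM

  dt4 <- matrix(d_tau * cfg$lifetime_gain, nrow = 1)
  gt4 <- recon_bwd(dt4, ca$t4$cache, par$tau$recon2, gk1, g1, gk3)
  gt3 <- recon_bwd(gt4$dM, ca$t3$cache, par$tau$recon1, gk1, g1, gk3)
  gt2 <- res_bwd(gt3$dM, ca$t2$cache, par$tau$res2, g3, g1)
  gt1 <- res_bwd(gt2$dM, ca$t1$cache, par$tau$res1, g3, g1)
  dtr0 <- relu_bwd(gt1$dM, ca$tr0$cache)
  gtb <- bn_bwd(dtr0, ca$tb$cache)
  gtc <- conv1d_bwd(gtb$dM, ca$tc$cache, par$tau$c1d)
  d_common_tau <- gtc$dM

  d_common <- d_common_int + d_common_tau
  dmr <- relu_bwd(d_common, ca$mr$cache)
  gmb <- bn_bwd(dmr, ca$mb$cache)
  gmx <- conv2d_bwd(gmb$dM, ca$mx$cache, par$mix$conv, gmix)
  dM0 <- gmx$dM
  skip_grads <- NULL
  if (!is.null(ca$skip)) {
    sk <- ca$skip; psk <- par$skip
    dw_int <- as.vector(ca$M0 %*% d_int)
    dM0 <- dM0 + outer(psk$w_int, d_int)
    dev <- sk$tc - psk$c0
    dalpha <- sum(d_tau * dev * sk$gate)
    dc0 <- -psk$alpha * sum(d_tau * sk$gate)
    sk_denom <- sk$s + psk$kappa
    dkappa <- -psk$alpha * sum(d_tau * dev * sk$s / sk_denom^2)
    dtc <- psk$alpha * d_tau * sk$gate
    dm <- dtc / (sk$s + sk$eps)
    ds <- -dtc * sk$tc / (sk$s + sk$eps) +
      psk$alpha * d_tau * dev * psk$kappa / sk_denom^2
    G_ <- length(sk$tvec)
    dMc <- outer(sk$tvec, dm) + rep(ds, each = G_)
    dM0 <- dM0 + dMc * sk$pos
    skip_grads <- list(w_int = dw_int, alpha = dalpha, c0 = dc0,
                       kappa = dkappa)
  }
  gfc <- fc_bwd(dM0, ca$fc$cache)

  c(if (!is.null(skip_grads)) list(skip = skip_grads), list(
    fc = list(W = gfc$dW, b = gfc$db),
    mix = list(conv = list(W = gmx$dW, b = gmx$db),
               bn = list(gamma = gmb$dgamma, beta = gmb$dbeta)),
    int = list(res1 = gir$grads, recon1 = gik$grads),
    tau = list(c1d = list(W = gtc$dW, b = gtc$db),
               bn1d = list(gamma = gtb$dgamma, beta = gtb$dbeta),
               res1 = gt1$grads, res2 = gt2$grads,
               recon1 = gt3$grads, recon2 = gt4$grads)
  ))
}

#' Training loss: weighted sum of intensity and lifetime mean squared errors
#'
#' `MSE(intensity) + weight * MSE(lifetime)`, both means taken over all pixels
#' of all samples in the batch.
#'
#' @param pred_int,true_int predicted/true intensity values (counts).
#' @param pred_tau,true_tau predicted/true lifetime values (ns).
#' @param weight lifetime weight (default 1e5).
#' @return scalar loss.
#' @export
net_loss <- function(pred_int, pred_tau, true_int, true_tau, weight = 1e5) {
  if (length(pred_int) != length(true_int) ||
      length(pred_tau) != length(true_tau))
    stop("prediction/target shape mismatch")
  mean((pred_int - true_int)^2) + weight * mean((pred_tau - true_tau)^2)
}
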