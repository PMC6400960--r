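.geom_cache <- new.env(parent = emptyenv())

geom_cached <- function(side, ksize, B) {
  key <- sprintf("%d_%d_%d", side, ksize, B)
  g <- .geom_cache[[key]]
  if (is.null(g)) {
    g <- conv_geom(side, ksize, B)
    .geom_cache[[key]] <- g
  }
  g
}

#' Assemble a training tensor from simulated samples
#'
#' Simulates one measurement per scene (full forward chain with Poisson
#' noise) and stacks inputs and ground-truth targets into dense arrays. The
#' measurement gates are average-pooled by the model's `gate_pool` on ingest
#' to keep the tensor small; targets use the scene ground truth with
#' background lifetime 0.
#'
#' @param scenes list of [lifetime_scene()].
#' @param bank pattern bank.
#' @param irf an `irf`.
#' @param axis a [temporal_axis()].
#' @param cfg a [net_config()] (for `gate_pool`).
#' @param rng_seed seed for the per-sample noise draws.
#' @param noisy add Poisson noise.
#' @return list: `X` (`n x g_pooled x k` array), `int`, `tau`
#'   (`n x npix` matrices, pixels column-major), `pooled = TRUE`.
#' @export
net_training_set <- function(scenes, bank, irf, axis = temporal_axis(),
                             cfg = net_config(), rng_seed = 1L, noisy = TRUE) {
  n <- length(scenes)
  if (n < 1) stop("empty scene list")
  npix <- cfg$img_side^2
  X <- array(0, c(n, cfg$g_pooled, bank$k))
  INT <- matrix(0, n, npix); TAU <- matrix(0, n, npix)
  noise_seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max - 1L, n))
  for (i in seq_len(n)) {
    s <- simulate_sample(scenes[[i]], bank, irf, axis,
                         rng_seed = noise_seeds[i], noisy = noisy)
    d <- s$measurements$data                       # gates x k
    Xp <- pool_gates_array(array(d, c(1, nrow(d), ncol(d))), cfg$gate_pool)
    X[i, , ] <- Xp[1, , ]
    INT[i, ] <- as.vector(scenes[[i]]$intensity)
    TAU[i, ] <- as.vector(scenes[[i]]$lifetime)
  }
  list(X = X, int = INT, tau = TAU, pooled = TRUE,
       ids = vapply(scenes, function(s) s$scene_id, character(1)))
}

rmsprop_init <- function(grads) rapply(grads, function(g) g * 0, how = "replace")

rmsprop_step <- function(par, grads, state, lr, rho = 0.9, eps = 1e-7) {
  for (nm in names(grads)) {
    if (is.list(grads[[nm]])) {
      r <- rmsprop_step(par[[nm]], grads[[nm]], state[[nm]], lr, rho, eps)
      par[[nm]] <- r$par; state[[nm]] <- r$state
    } else {
      state[[nm]] <- rho * state[[nm]] + (1 - rho) * grads[[nm]]^2
      par[[nm]] <- par[[nm]] - lr * grads[[nm]] / (sqrt(state[[nm]]) + eps)
    }
  }
  list(par = par, state = state)
}

apply_bn_runs <- function(params, run) {
  for (key in ls(run)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    new <- run[[key]]
    cur <- params[[path]]
    cur$run_mean <- new$run_mean
    cur$run_var <- new$run_var
    params[[path]] <- cur
  }
  params
}

net_eval_mae <- function(model, set, batch_size) {
  n <- dim(set$X)[1]
  se_int <- 0; se_tau <- 0; npx <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- net_forward(model, set$X[idx, , , drop = FALSE], training = FALSE,
                      already_pooled = isTRUE(set$pooled))
    ti <- as.vector(t(set$int[idx, , drop = FALSE]))
    tt <- as.vector(t(set$tau[idx, , drop = FALSE]))
    se_int <- se_int + sum(abs(fw$int - ti))
    se_tau <- se_tau + sum(abs(fw$tau - tt))
    npx <- npx + length(ti)
  }
  c(intensity = se_int / npx, lifetime = se_tau / npx)
}

#' Train the direct reconstruction network
#'
#' RMSprop minimization of [net_loss()] with the learning rate halved every
#' `lr_halving_period` epochs, per-epoch validation, and early stopping when
#' the validation lifetime MAE has not improved for `patience` consecutive
#' epochs. The returned model carries the parameters of the epoch with the
#' lowest validation lifetime MAE. Fully seeded: repeated runs give identical
#' histories.
#'
#' @param model an untrained [build_model()] result.
#' @param train_set,val_set tensors from [net_training_set()]; must be
#'   non-empty and disjoint.
#' @param verbose print one line per epoch.
#' @return the trained `netflics_model` with `history` (one row per epoch:
#'   learning rate, train loss, train/val intensity and lifetime MAE) and
#'   `best_epoch`.
#' @export
train_netflics <- function(model, train_set, val_set, verbose = FALSE) {
  stopifnot(inherits(model, "netflics_model"))
  cfg <- model$cfg
  n <- dim(train_set$X)[1]
  if (n < 1 || dim(val_set$X)[1] < 1) stop("training and validation sets must be non-empty")
  if (length(intersect(train_set$ids %||% character(0),
                       val_set$ids %||% character(0))) > 0)
    stop("training and validation sets share scenes")
  state <- NULL
  hist <- NULL
  best_mae <- Inf; best_epoch <- NA_integer_; best_params <- model$params
  for (epoch in seq_len(cfg$max_epochs) - 1L) {
    lr <- lr_at_epoch(epoch, cfg)
    order_idx <- with_seed(cfg$rng_seed + 7919L * (epoch + 1L), sample.int(n))
    tot_loss <- 0; ae_int <- 0; ae_tau <- 0; npx <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- order_idx[start:min(start + cfg$batch_size - 1, n)]
      Xb <- train_set$X[idx, , , drop = FALSE]
      ti <- as.vector(t(train_set$int[idx, , drop = FALSE]))
      tt <- as.vector(t(train_set$tau[idx, , drop = FALSE]))
      run <- new.env(parent = emptyenv())
      fw <- net_forward(model, Xb, training = TRUE, run = run,
                        already_pooled = isTRUE(train_set$pooled))
      N <- length(ti)
      d_int <- 2 * (fw$int - ti) / N
      d_tau <- 2 * cfg$lifetime_loss_weight * (fw$tau - tt) / N
      grads <- net_backward(model, fw, d_int, d_tau)
      if (is.null(state)) state <- rmsprop_init(grads)
      upd <- rmsprop_step(model$params, grads, state, lr)
      model$params <- apply_bn_runs(upd$par, run)
      state <- upd$state
      tot_loss <- tot_loss +
        net_loss(fw$int, fw$tau, ti, tt, cfg$lifetime_loss_weight) * length(idx)
      ae_int <- ae_int + sum(abs(fw$int - ti))
      ae_tau <- ae_tau + sum(abs(fw$tau - tt))
      npx <- npx + N
    }
    val <- net_eval_mae(model, val_set, cfg$batch_size)
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr, train_loss = tot_loss / n,
      train_intensity_mae = ae_int / npx, train_lifetime_mae = ae_tau / npx,
      val_intensity_mae = val["intensity"], val_lifetime_mae = val["lifetime"],
      row.names = NULL))
    if (verbose)
      message(sprintf(
        "epoch %2d lr %.2e loss %.3e train MAE %.1f/%.4f val MAE %.1f/%.4f",
        epoch, lr, tot_loss / n, ae_int / npx, ae_tau / npx,
        val["intensity"], val["lifetime"]))
    if (val["lifetime"] < best_mae) {
      best_mae <- val["lifetime"]; best_epoch <- epoch; best_params <- model$params
    } else if (epoch - best_epoch >= cfg$patience) {
      break
    }
  }
  model$params <- best_params
  model$history <- hist
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  model
}

#' Reconstruct intensity and lifetime images with the trained network
#'
#' Single forward pass, no post-processing: the raw network outputs are the
#' reconstruction.
#'
#' @param model a trained `netflics_model`.
#' @param measurements a `measurement_set`, a list of them, or a pre-pooled
#'   tensor list from [net_training_set()].
#' @return a `recon_result` (or list of them) with method tag `"netflics"`.
#' @export
predict_netflics <- function(model, measurements) {
  stopifnot(inherits(model, "netflics_model"))
  cfg <- model$cfg
  single <- inherits(measurements, "measurement_set")
  ids <- NULL
  if (single) measurements <- list(measurements)
  if (is.list(measurements) && !is.null(measurements$X)) {
    X <- measurements$X
    pooled <- isTRUE(measurements$pooled)
    ids <- measurements$ids
  } else {
    G <- nrow(measurements[[1]]$data)
    if (G != cfg$n_gates)
      stop("measurement has ", G, " gates; model expects ", cfg$n_gates)
    if (ncol(measurements[[1]]$data) != cfg$n_meas)
      stop("measurement has ", ncol(measurements[[1]]$data),
           " patterns; model expects ", cfg$n_meas)
    X <- array(0, c(length(measurements), G, cfg$n_meas))
    for (i in seq_along(measurements)) X[i, , ] <- measurements[[i]]$data
    pooled <- FALSE
  }
  n <- dim(X)[1]; side <- cfg$img_side; npix <- side^2
  out <- vector("list", n)
  bs <- cfg$batch_size
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    fw <- net_forward(model, X[idx, , , drop = FALSE], training = FALSE,
                      already_pooled = pooled)
    for (j in seq_along(idx)) {
      rows <- ((j - 1) * npix + 1):(j * npix)
      out[[idx[j]]] <- new_recon_result(
        matrix(fw$int[rows], side, side),
        matrix(fw$tau[rows], side, side),
        "netflics",
        scene_id = if (!is.null(ids)) ids[idx[j]] else NA_character_)
    }
  }
  if (single) out[[1]] else out
}

#' Save / load a trained model
#'
#' The parameter store is written with base-R serialization; a JSON sidecar
#' (`<path>.json`) records the configuration and training history for
#' inspection without loading the binary.
#'
#' @param model a `netflics_model`.
#' @param path output file path.
#' @return `save_model`: invisibly, `path`. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "netflics_model"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(config = unclass(model$cfg), best_epoch = model$best_epoch,
         history = model$history),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "netflics_model")) stop("file does not contain a model")
  m
}
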