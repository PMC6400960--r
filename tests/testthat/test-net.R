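test_that("configuration contracts: loss arithmetic and learning-rate schedule", {
  # loss = MSE(intensity) + weight * MSE(lifetime)
  n <- 10
  pi_ <- rep(1, n); ti <- rep(0, n)        # MSE_int = 1
  pt <- rep(sqrt(0.001), n); tt <- rep(0, n)  # MSE_tau = 0.001
  expect_equal(net_loss(pi_, pt, ti, tt, weight = 1e5), 101.0, tolerance = 1e-9)
  expect_equal(net_loss(ti, tt, ti, tt), 0)
  # doubling the weight doubles only the lifetime term
  expect_equal(net_loss(pi_, pt, ti, tt, weight = 2e5) -
                 net_loss(pi_, pt, ti, tt, weight = 1e5), 100, tolerance = 1e-9)
  cfg <- net_config()
  expect_identical(lr_at_epoch(0, cfg), 1e-3)
  expect_identical(lr_at_epoch(9, cfg), 1e-3)
  expect_identical(lr_at_epoch(10, cfg), 5e-4)
  expect_identical(lr_at_epoch(19, cfg), 5e-4)
  expect_identical(lr_at_epoch(20, cfg), 2.5e-4)
  expect_error(net_config(lifetime_loss_weight = 0), "> 0")
  expect_error(net_config(gate_pool = 7), "divide")
})

test_that("the network maps measurements to two image-sized outputs", {
  for (n_meas in c(512L, 400L)) {
    cfg <- net_config(n_meas = n_meas, rng_seed = 5L)
    model <- build_model(cfg)
    X <- array(abs(rnorm(2 * 256 * n_meas)), c(2, 256, n_meas))
    fw <- flics:::net_forward(model, X, training = FALSE)
    expect_length(fw$int, 2 * 1024)
    expect_length(fw$tau, 2 * 1024)
  }
})

test_that("inference is deterministic and batch-size invariant", {
  cfg <- fx_tiny_cfg()
  model <- build_model(cfg)
  set.seed(3)
  X <- array(abs(rnorm(5 * 8 * 16)), c(5, 8, 16))
  f1 <- flics:::net_forward(model, X, training = FALSE)
  f2 <- flics:::net_forward(model, X, training = FALSE)
  expect_identical(f1$int, f2$int)
  expect_identical(f1$tau, f2$tau)
  # forward of a subset equals the subset of the forward
  fa <- flics:::net_forward(model, X[1:2, , , drop = FALSE], training = FALSE)
  expect_equal(fa$tau, f1$tau[1:(2 * 64)], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through every segment", {
  cfg <- fx_tiny_cfg()
  model <- build_model(cfg)
  set.seed(1)
  B <- 3
  X <- array(rnorm(B * 8 * 16), c(B, 8, 16))
  ti <- rnorm(B * 64); tt <- rnorm(B * 64) * 0.1
  lossfun <- function(m) {
    fw <- flics:::net_forward(m, X, training = TRUE, run = new.env())
    net_loss(fw$int, fw$tau, ti, tt, 100)
  }
  fw <- flics:::net_forward(model, X, training = TRUE, run = new.env())
  gr <- flics:::net_backward(model, fw, 2 * (fw$int - ti) / length(ti),
                             200 * (fw$tau - tt) / length(tt))
  paths <- list(c("fc", "W"), c("mix", "conv", "W"), c("mix", "bn", "gamma"),
                c("int", "res1", "convA", "W"), c("int", "recon1", "conv1", "W"),
                c("tau", "c1d", "W"), c("tau", "bn1d", "beta"),
                c("tau", "res2", "convB", "W"), c("tau", "recon2", "conv3", "W"))
  for (pth in paths) {
    arr <- model$params[[pth]]
    idx <- withr::with_seed(42, sample(length(arr), min(3, length(arr))))
    for (i in idx) {
      m1 <- model; m1$params[[pth]][i] <- arr[i] + 1e-5
      m2 <- model; m2$params[[pth]][i] <- arr[i] - 1e-5
      num <- (lossfun(m1) - lossfun(m2)) / 2e-5
      expect_lt(abs(num - gr[[pth]][i]) /
                  max(abs(num), abs(gr[[pth]][i]), 1e-6), 1e-3)
    }
  }
})

test_that("a short training run reduces the loss and is fully reproducible", {
  cfg <- fx_tiny_cfg()
  side <- 8
  mkset <- function(n, seed, prefix) {
    set.seed(seed)
    X <- array(abs(rnorm(n * 8 * 16, mean = 2)), c(n, 8, 16))
    int <- matrix(runif(n * side^2, 0, 4), n)
    tau <- matrix(runif(n * side^2, 0, 1), n)
    list(X = X, int = int, tau = tau, pooled = TRUE,
         ids = paste0(prefix, seq_len(n)))
  }
  tr <- mkset(48, 1, "tr"); va <- mkset(12, 2, "va")
  m1 <- train_netflics(build_model(cfg), tr, va)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  expect_lte(nrow(m1$history), cfg$max_epochs)
  expect_equal(m1$best_epoch,
               m1$history$epoch[which.min(m1$history$val_lifetime_mae)])
  m2 <- train_netflics(build_model(cfg), tr, va)
  expect_identical(m1$history, m2$history)
  # early stopping bound: halts within patience + 1 epochs of the best
  expect_lte(nrow(m1$history), m1$best_epoch + cfg$patience + 1)
  # disjointness guard
  va_bad <- va; va_bad$ids[1] <- "tr1"
  expect_error(train_netflics(build_model(cfg), tr, va_bad), "share")
})

test_that("prediction returns tagged results and round-trips through disk", {
  cfg <- fx_tiny_cfg()
  model <- build_model(cfg)
  model$trained <- TRUE
  set.seed(4)
  Xl <- list(X = array(abs(rnorm(3 * 8 * 16)), c(3, 8, 16)), pooled = TRUE,
             ids = c("a", "b", "c"))
  res <- predict_netflics(model, Xl)
  expect_length(res, 3)
  expect_identical(res[[1]]$method, "netflics")
  expect_equal(dim(res[[2]]$intensity), c(8L, 8L))
  expect_identical(res[[3]]$scene_id, "c")
  res2 <- predict_netflics(model, Xl)
  expect_identical(res[[1]]$lifetime, res2[[1]]$lifetime)
  tf <- tempfile(fileext = ".rds")
  save_model(model, tf)
  expect_true(file.exists(paste0(tf, ".json")))
  back <- load_model(tf)
  res3 <- predict_netflics(back, Xl)
  expect_identical(res[[1]]$intensity, res3[[1]]$intensity)
  unlink(c(tf, paste0(tf, ".json")))
})
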