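test_that("zero signal yields the zero image and bad inputs are rejected", {
  bank <- fx_bank64()
  img <- solve_gate(numeric(64), bank, tv_config(max_iter = 10))
  expect_true(all(img == 0))
  expect_error(solve_gate(c(NA, numeric(63)), bank), "finite")
  bad <- bank; bad$P[] <- 0; bad$H_rows[] <- 0
  expect_error(solve_gate(numeric(64), bad), "all-zero")
})

test_that("complete-bank TV solve matches the Hadamard-transform oracle on 8x8 frames", {
  bank <- fx_bank64()
  set.seed(3)
  img <- matrix(0, 8, 8); img[3:6, 2:5] <- 50; img[5:7, 6:8] <- 120
  s <- as.vector(bank$P %*% as.vector(img))
  # oracle: closed-form inversion through the signed Hadamard relation
  ax <- temporal_axis(2, 1)
  m <- structure(list(data = rbind(s, s), axis = ax, bank_id = bank$bank_id,
                      irf_id = "d", noisy = FALSE), class = "measurement_set")
  oracle <- invert_complete_bank(m, bank)$cube[, 1]
  expect_equal(oracle, as.vector(img), tolerance = 1e-9)
  x <- solve_gate(s, bank, tv_config(mu = 64, tol = 1e-8, max_iter = 300))
  expect_lt(max(abs(as.vector(x) - as.vector(img))) / max(img), 1e-3)
})

test_that("a constant image is recovered from its complete-bank measurement", {
  bank <- fx_bank64()
  s <- as.vector(bank$P %*% rep(7, 64))
  x <- solve_gate(s, bank, tv_config(mu = 64, tol = 1e-9, max_iter = 200))
  expect_lt(max(abs(x - 7)) / 7, 1e-3)
})

test_that("the TV objective is non-increasing over outer iterations", {
  bank <- fx_bank64()
  set.seed(4)
  img <- matrix(rpois(64, 20), 8, 8)
  s <- as.vector(bank$P %*% as.vector(img)) + rnorm(64, sd = 2)
  res <- tv_solve_gates(matrix(s, 1), bank,
                        tv_config(mu = 1, max_iter = 60, tol = 1e-12),
                        track_objective = TRUE)
  o <- res$objective
  expect_true(all(diff(o) <= abs(o[-length(o)]) * 1e-9 + 1e-9))
})

test_that("fewer measurements give worse noiseless recovery in expectation", {
  b512 <- fx_bank512(); b1024 <- fx_bank1024()
  ax <- fx_axis(); irf <- fx_irf()
  scenes <- make_dataset(6, "test", rng_seed = 31)
  err <- function(bank) mean(vapply(scenes, function(s) {
    sm <- simulate_sample(s, bank, irf, ax, rng_seed = 1, noisy = FALSE)
    stot <- matrix(colSums(sm$measurements$data), 1)
    x <- tv_solve_gates(stot, bank, tv_config(max_iter = 60))$X[, 1]
    mean(abs(x - as.vector(s$intensity)))
  }, numeric(1)))
  expect_gt(err(b512), err(b1024))
})

test_that("gate order permutation permutes the assembled cube identically", {
  bank <- fx_bank64()
  set.seed(5)
  S <- matrix(rpois(6 * 64, 30), 6, 64)
  ax <- temporal_axis(6, 0.2)
  m <- structure(list(data = S, axis = ax, bank_id = bank$bank_id,
                      irf_id = "d", noisy = TRUE), class = "measurement_set")
  cube1 <- assemble_tpsfs(m, bank, tv_config(max_iter = 30))$cube
  perm <- c(3, 1, 6, 2, 5, 4)
  m2 <- m; m2$data <- S[perm, ]
  cube2 <- assemble_tpsfs(m2, bank, tv_config(max_iter = 30))$cube
  expect_equal(cube2, cube1[, perm], tolerance = 1e-12)
})

test_that("rising-edge alignment follows the 5% rule", {
  tr <- c(0, 0, 1, 20, 100, 80, 60)
  expect_identical(rising_edge_index(tr), 3L)   # first gate >= 5, 0-based
  expect_identical(align_rising_edge(tr, tr), 0L)
  delayed <- c(numeric(7), tr)
  expect_identical(align_rising_edge(delayed, tr), -7L)
  shifted <- apply_gate_shift(matrix(delayed, ncol = 1), -7L)
  expect_equal(shifted[seq_along(tr), 1], tr)
  expect_error(rising_edge_index(numeric(5)), "positive maximum")
})

test_that("log-linear fitting is exact on noiseless exponentials", {
  ax <- fx_axis()
  for (tau in c(0.3, 0.8, 1.5)) {
    f <- fit_lifetime(simulate_decay(1000, tau, ax), ax)
    expect_lt(abs(f$tau - tau) / tau, 1e-6)
    expect_equal(f$r2, 1, tolerance = 1e-9)
  }
  expect_error(fit_lifetime(numeric(256), ax), "all zero")
})

test_that("fitting stays exact after IRF convolution with a late tail window", {
  ax <- fx_axis(); irf <- fx_irf()
  cfg <- fit_config(tail_start = 20L)   # >= 3 x FWHM past the IRF peak
  for (tau in c(0.3, 1.5)) {
    tpsf <- convolve_irf(simulate_decay(1e6, tau, ax), irf)
    f <- fit_lifetime(tpsf, ax, cfg)
    expect_lt(abs(f$tau - tau) / tau, 1e-6)
  }
})

test_that("Poisson-noised fits of a bright pixel stay within 0.05 ns (median)", {
  ax <- fx_axis(); irf <- fx_irf()
  tpsf <- convolve_irf(simulate_decay(1600, 0.5, ax), irf)
  errs <- flics:::with_seed(99, {
    vapply(1:200, function(i) {
      noisy <- rpois(length(tpsf), tpsf)
      abs(fit_lifetime(noisy, ax)$tau - 0.5)
    }, numeric(1))
  })
  expect_lt(median(errs), 0.05)
})

test_that("implausible fits are invalidated rather than reported", {
  ax <- fx_axis()
  flat <- rep(100, 256)  # zero slope: no decay information
  f <- fit_lifetime(flat + c(numeric(255), 1e-9), ax)
  expect_identical(f$tau, 0)
  expect_false(f$valid)
})

test_that("full reconstruction round-trips a noiseless single-glyph scene", {
  ax <- fx_axis(); irf <- fx_irf(); bank <- fx_bank1024()
  g <- matrix(0, 10, 10); g[3:8, 3:8] <- 1
  s <- make_scene(list(g), level = "3", rng_seed = 301)
  tau_true <- unique(s$lifetime[s$mask])
  sm <- simulate_sample(s, bank, irf, ax, rng_seed = 1, noisy = FALSE)
  r <- reconstruct_tv(sm$measurements, bank, tv_config(mu = 64, max_iter = 60),
                      gate_bin = 4)
  expect_equal(dim(r$intensity), c(32L, 32L))
  expect_equal(dim(r$lifetime), c(32L, 32L))
  fg <- r$lifetime > 0
  expect_true(any(fg))
  expect_lt(max(abs(r$lifetime[fg] - tau_true)), 0.01)
  # background zeroing is exact
  expect_true(all(r$lifetime[r$intensity < 0.1 * max(r$intensity)] == 0))
})
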