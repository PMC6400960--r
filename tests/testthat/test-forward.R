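test_that("decay curves integrate to the requested amplitude with the exact ratio", {
  ax <- fx_axis()
  d <- simulate_decay(100, 1.0, ax)
  expect_equal(sum(d), 100, tolerance = 1e-12)
  ratios <- d[-1] / d[-length(d)]
  expect_equal(ratios, rep(exp(-0.04), length(ratios)), tolerance = 1e-12)
  expect_identical(simulate_decay(0, 1, ax), numeric(256))
  expect_error(simulate_decay(10, -1, ax), "positive")
})

test_that("IRF convolution is identity for a delta and conserves photons", {
  ax <- fx_axis()
  d <- simulate_decay(500, 0.8, ax)
  expect_equal(convolve_irf(d, delta_irf(ax)), d, tolerance = 1e-9)
  out <- convolve_irf(d, fx_irf())
  expect_lte(sum(out), sum(d) + 1e-9)
  # early decay, short tau: negligible truncation
  d2 <- simulate_decay(100, 0.3, ax)
  expect_equal(sum(convolve_irf(d2, fx_irf())), 100, tolerance = 1e-6)
  # hand-checked two-bin kernel
  k <- numeric(256); k[1:2] <- 0.5
  irf2 <- flics:::new_irf(k, 0.04, 0)
  x <- numeric(256); x[1] <- 1
  expect_equal(convolve_irf(x, irf2)[1:3], c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_error(convolve_irf(numeric(10), fx_irf()), "match")
})

test_that("TPSF cube conserves per-pixel CW intensity exactly", {
  s <- fx_scene()
  tp <- simulate_tpsf_cube(s, fx_irf(), fx_axis())
  expect_true(all(tp$cube >= 0))
  expect_equal(rowSums(tp$cube), as.vector(s$intensity), tolerance = 1e-9)
})

test_that("projection is the pattern-weighted sum and is linear", {
  s <- fx_scene()
  tp <- simulate_tpsf_cube(s, fx_irf(), fx_axis())
  bank <- fx_bank512()
  m <- project_measurements(tp, bank)
  expect_equal(dim(m$data), c(256L, 512L))
  # full-field pattern trace equals the summed TPSF
  expect_equal(m$data[, 1], colSums(tp$cube), tolerance = 1e-9)
  # linearity
  tp2 <- tp; tp2$cube <- 2 * tp$cube
  m2 <- project_measurements(tp2, bank)
  expect_equal(m2$data, 2 * m$data, tolerance = 1e-9)
  # zero cube
  tp0 <- tp; tp0$cube[] <- 0
  expect_true(all(project_measurements(tp0, bank)$data == 0))
})

test_that("Poisson noise keeps zeros, matches moments, and is reproducible", {
  ax <- temporal_axis(4, 1)
  m <- structure(list(data = matrix(c(0, 100, 400, 0), 2, 2), axis = ax,
                      bank_id = "x", irf_id = "x", noisy = FALSE),
                 class = "measurement_set")
  n1 <- add_poisson_noise(m, 1)
  expect_identical(n1$data, add_poisson_noise(m, 1)$data)
  expect_true(all(n1$data[m$data == 0] == 0))
  big <- m; big$data <- matrix(400, 100, 100)
  draws <- add_poisson_noise(big, 2)$data
  expect_gt(var(as.vector(draws)) / mean(draws), 0.9)
  expect_lt(var(as.vector(draws)) / mean(draws), 1.1)
  lam100 <- m; lam100$data <- matrix(100, 100, 100)
  expect_lt(abs(mean(add_poisson_noise(lam100, 3)$data) - 100), 1)
  bad <- m; bad$data[1] <- -1
  expect_error(add_poisson_noise(bad, 1), "nonnegative")
})

test_that("the full simulated sample has the documented shape and conserves photons", {
  s <- fx_scene()
  sm <- simulate_sample(s, fx_bank512(), fx_irf(), fx_axis(), rng_seed = 3,
                        noisy = FALSE)
  expect_equal(dim(sm$measurements$data), c(256L, 512L))
  expect_equal(sum(sm$measurements$data[, 1]), sum(s$intensity),
               tolerance = 1e-9)
  n1 <- simulate_sample(s, fx_bank512(), fx_irf(), fx_axis(), rng_seed = 5)
  n2 <- simulate_sample(s, fx_bank512(), fx_irf(), fx_axis(), rng_seed = 5)
  expect_identical(n1$measurements$data, n2$measurements$data)
})

test_that("complete-bank inversion reproduces the cube to machine precision", {
  s <- fx_scene()
  tp <- simulate_tpsf_cube(s, fx_irf(), fx_axis())
  m <- project_measurements(tp, fx_bank1024())
  inv <- invert_complete_bank(m, fx_bank1024())
  expect_lt(max(abs(inv$cube - tp$cube)) / max(tp$cube), 1e-6)
  expect_error(invert_complete_bank(m, fx_bank512()), "k == order")
})

test_that("relative Monte-Carlo noise shrinks as intensity grows across levels", {
  ax <- fx_axis(); irf <- fx_irf(); bank <- fx_bank512()
  relerr <- vapply(c("1", "2", "3"), function(lev) {
    s <- make_scene(list(make_glyph(5)), level = lev, rng_seed = 8)
    tp <- simulate_tpsf_cube(s, irf, ax)
    m <- project_measurements(tp, bank)
    errs <- vapply(1:5, function(k) {
      n <- add_poisson_noise(m, k)
      sum(abs(n$data - m$data)) / sum(m$data)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(relerr[1] > relerr[2] && relerr[2] > relerr[3])
})

test_that("gate binning preserves counts and rescales the axis", {
  s <- fx_scene()
  sm <- simulate_sample(s, fx_bank512(), fx_irf(), fx_axis(), rng_seed = 3)
  mb <- bin_gates(sm$measurements, 4)
  expect_equal(dim(mb$data), c(64L, 512L))
  expect_equal(colSums(mb$data), colSums(sm$measurements$data))
  expect_equal(mb$axis$gate_width, 0.16)
})
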