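test_that("MAE matches hand calculations", {
  a <- matrix(0, 2, 2)
  expect_identical(mae(a, a), 0)
  expect_identical(mae(a + 2, a), 2)
  expect_identical(mae(matrix(c(0, 0, 0, 4), 2, 2), a), 1)
  expect_error(mae(a, matrix(0, 3, 3)), "2 x 2")
})

test_that("SSIM is 1 on identical images, symmetric, and bounded", {
  set.seed(2)
  for (i in 1:20) {
    a <- matrix(runif(64, 0, 10), 8, 8)
    b <- matrix(runif(64, 0, 10), 8, 8)
    s_ab <- ssim(a, b, data_range = 10)
    expect_equal(s_ab, ssim(b, a, data_range = 10), tolerance = 1e-12)
    expect_gte(s_ab, -1); expect_lte(s_ab, 1)
  }
  a <- matrix(runif(64), 8, 8)
  expect_equal(ssim(a, a, 1), 1, tolerance = 1e-12)
})

test_that("SSIM of two constant images equals the closed-form luminance term", {
  L <- 10; c1 <- 2; c2 <- 2 + L / 2
  C1 <- (0.01 * L)^2
  expected <- (2 * c1 * c2 + C1) / (c1^2 + c2^2 + C1)
  got <- ssim(matrix(c1, 16, 16), matrix(c2, 16, 16), data_range = L)
  expect_equal(got, expected, tolerance = 1e-9)
  expect_lt(got, 1)
})

test_that("region statistics use the population standard deviation", {
  img <- matrix(0, 2, 2); img[1, 1] <- 0.4; img[2, 1] <- 0.6
  msk <- matrix(FALSE, 2, 2); msk[, 1] <- TRUE
  st <- region_stats(img, msk)
  expect_equal(unname(st), c(0.5, 0.1), tolerance = 1e-12)
  img[2, 2] <- 99  # outside the mask: no effect
  expect_equal(unname(region_stats(img, msk)), c(0.5, 0.1), tolerance = 1e-12)
  cst <- matrix(0.5, 3, 3)
  expect_equal(unname(region_stats(cst, cst > 0)), c(0.5, 0))
  expect_error(region_stats(img, msk & FALSE), "empty")
})

test_that("evaluation reports perfect scores for perfect reconstructions", {
  scenes <- make_dataset(4, "test", rng_seed = 17)
  res <- lapply(scenes, function(s)
    flics:::new_recon_result(s$intensity, s$lifetime, "tvrecon",
                             scene_id = s$scene_id))
  rep <- evaluate_recon(res, scenes)
  expect_equal(nrow(rep$per_sample), 4L)
  expect_true(all(rep$per_sample$intensity_mae == 0))
  expect_true(all(rep$per_sample$lifetime_mae == 0))
  expect_equal(rep$per_sample$intensity_ssim, rep(1, 4), tolerance = 1e-12)
})

test_that("aggregates match direct recomputation and ignore sample order", {
  scenes <- make_dataset(5, "test", rng_seed = 18)
  res <- lapply(scenes, function(s) {
    r <- flics:::new_recon_result(s$intensity + 3, pmax(s$lifetime - 0.05, 0),
                                  "netflics", scene_id = s$scene_id)
    r
  })
  rep1 <- evaluate_recon(res, scenes)
  expect_equal(rep1$aggregate$mean[1], mean(rep1$per_sample$intensity_mae),
               tolerance = 1e-12)
  rep2 <- evaluate_recon(res[5:1], scenes)
  expect_equal(rep1$aggregate$mean, rep2$aggregate$mean, tolerance = 1e-12)
  # id mismatch is an error
  res[[1]]$scene_id <- "nonexistent"
  expect_error(evaluate_recon(res, scenes), "ids")
})

test_that("reports serialize to CSV and JSON", {
  scenes <- make_dataset(3, "test", rng_seed = 19)
  res <- lapply(scenes, function(s)
    flics:::new_recon_result(s$intensity, s$lifetime, "tvrecon",
                             scene_id = s$scene_id))
  rep <- evaluate_recon(res, scenes)
  pref <- tempfile()
  paths <- write_eval_report(rep, pref)
  expect_true(all(file.exists(paths)))
  csv <- utils::read.csv(paths["csv"])
  expect_equal(nrow(csv), 3L)
  js <- jsonlite::read_json(paths["json"])
  expect_equal(js$n, 3L)
  unlink(paths)
})
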