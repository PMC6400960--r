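test_that("glyphs honour the nonzero-fraction contract and determinism", {
  g <- make_glyph(0, c(28, 28))
  expect_true(mean(g > 0) >= 0.05 && mean(g > 0) <= 0.6)
  expect_true(all(g >= 0 & g <= 1))
  expect_identical(g, make_glyph(0, c(28, 28)))
  expect_error(make_glyph(1, c(4, 4)), "too small")
})

test_that("glyph generator is diverse across seeds", {
  hashes <- vapply(1:1000, function(s)
    paste(which(make_glyph(s) > 0.5)[1:12], collapse = ","), character(1))
  expect_gte(length(unique(hashes)), 900)
})

test_that("scene composition respects level ranges and lifetime semantics", {
  s <- make_scene(list(make_glyph(1)), level = "3", rng_seed = 2)
  expect_gte(max(s$intensity), 400)
  expect_lte(max(s$intensity), 1600)
  expect_length(unique(s$lifetime[s$mask]), 1)       # one dye per glyph
  expect_true(all(s$lifetime[s$mask] >= 0.3 & s$lifetime[s$mask] <= 1.5))
  expect_true(all(s$intensity[!s$mask] == 0))
  expect_true(all(s$lifetime[!s$mask] == 0))
  expect_error(make_scene(list(), level = "3"), "at least one glyph")
  expect_error(make_scene(list(make_glyph(1)), level = "9"), "unknown photon level")
})

test_that("two non-overlapping glyphs give exactly two distinct lifetimes", {
  # tiny glyphs placed deterministically at opposite corners
  g <- matrix(0, 6, 6); g[2:5, 2:5] <- 1
  found <- FALSE
  for (seed in 1:50) {
    s <- make_scene(list(g, g), level = "2", rng_seed = seed)
    taus <- unique(s$lifetime[s$mask])
    if (length(taus) == 2) { found <- TRUE; break }
  }
  expect_true(found)
  # overlap rule: weighted average stays inside the component range
  s <- make_scene(list(make_glyph(2), make_glyph(3)), level = "2", rng_seed = 4)
  expect_true(all(s$lifetime[s$mask] >= 0.3 & s$lifetime[s$mask] <= 1.5))
})

test_that("every generated scene satisfies the container invariants", {
  scenes <- make_dataset(40, "test", level = "mix", rng_seed = 5)
  for (s in scenes) {
    rng <- switch(s$level, "1" = c(25, 100), "2" = c(100, 400), "3" = c(400, 1600))
    expect_true(all(s$intensity >= 0))
    expect_gte(max(s$intensity), rng[1])
    expect_lte(max(s$intensity), rng[2])
    expect_true(all((s$intensity == 0) == !s$mask))
    expect_true(all((s$lifetime == 0) == !s$mask))
  }
})

test_that("dataset splits are reproducible and disjoint", {
  a <- make_dataset(5, "train", rng_seed = 9)
  b <- make_dataset(5, "train", rng_seed = 9)
  expect_identical(lapply(a, `[[`, "intensity"), lapply(b, `[[`, "intensity"))
  v <- make_dataset(5, "val", rng_seed = 9)
  ha <- vapply(a, function(s) paste(signif(s$intensity[s$mask][1:5], 10), collapse = ","),
               character(1))
  hv <- vapply(v, function(s) paste(signif(s$intensity[s$mask][1:5], 10), collapse = ","),
               character(1))
  expect_length(intersect(ha, hv), 0)
})

test_that("IDX glyph import reads images and reports malformed files", {
  tf <- tempfile(fileext = ".idx3-ubyte")
  con <- file(tf, "wb")
  writeBin(c(2051L, 2L, 4L, 4L), con, size = 4, endian = "big")
  writeBin(as.raw(c(rep(255, 16), rep(128, 16))), con)
  close(con)
  imgs <- read_idx_images(tf)
  expect_length(imgs, 2)
  expect_equal(imgs[[1]], matrix(1, 4, 4))
  expect_equal(imgs[[2]], matrix(128 / 255, 4, 4))
  bad <- tempfile()
  con <- file(bad, "wb"); writeBin(1234L, con, size = 4, endian = "big"); close(con)
  expect_error(read_idx_images(bad), "offset 0")
  unlink(c(tf, bad))
})
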