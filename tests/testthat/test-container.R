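test_that("datasets round-trip bit-exactly and validate references", {
  scenes <- make_dataset(3, "test", rng_seed = 41)
  ax <- fx_axis()
  meas <- lapply(scenes, function(s)
    simulate_sample(s, fx_bank512(), fx_irf(), ax, rng_seed = 1)$measurements)
  names(meas) <- vapply(scenes, function(s) s$scene_id, character(1))
  tf <- tempfile(fileext = ".dataset")
  write_dataset(tf, scenes, meas)
  back <- read_dataset(tf)
  expect_identical(back$scene_ids,
                   vapply(scenes, function(s) s$scene_id, character(1)))
  expect_identical(back$scenes[[1]]$intensity, scenes[[1]]$intensity)
  expect_identical(back$measurements[[names(meas)[2]]]$data, meas[[2]]$data)
  # overwrite guard
  expect_error(write_dataset(tf, scenes), "exists")
  expect_silent(write_dataset(tf, scenes, overwrite = TRUE))
  unlink(tf)
})

test_that("measurements referencing unknown scenes are rejected at write time", {
  scenes <- make_dataset(2, "test", rng_seed = 42)
  m <- simulate_sample(scenes[[1]], fx_bank512(), fx_irf(), fx_axis(),
                       rng_seed = 1)$measurements
  tf <- tempfile()
  expect_error(write_dataset(tf, scenes, list(ghost = m)), "unknown scene id")
  expect_error(write_dataset(tf, scenes, list(m)), "named list")
})

test_that("foreign or truncated files give clean errors", {
  tf <- tempfile()
  writeLines("not a dataset", tf)
  expect_error(read_dataset(tf), "unreadable|not a flics dataset")
  saveRDS(list(something = 1), tf)
  expect_error(read_dataset(tf), "not a flics dataset")
  saveRDS(list(schema_version = "99.0", scenes = list()), tf)
  expect_error(read_dataset(tf), "schema version 99.0")
  expect_error(read_dataset(tempfile()), "no such file")
  unlink(tf)
})
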