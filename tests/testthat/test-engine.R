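test_that("configuration validation", {
  expect_error(stand_config(dt = 0), "dt")
  expect_error(stand_config(lock_s = 40, duration_s = 30), "lock_s")
  expect_error(stand_config(scale = 1.5), "scale")
  expect_error(reduced_scale_config(stand_config(), 0.0005), "empty")
  cfg <- reduced_scale_config(stand_config(), 0.1)
  expect_equal(cfg$scale, 0.1)
})

test_that("identical configuration and seed give bitwise-identical rasters", {
  cfg <- stand_config(duration_s = 2.5, scale = 0.1, seed = 12)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$afferent_spikes, b$afferent_spikes)
  expect_identical(a$series, b$series)
  c2 <- run_simulation(stand_config(duration_s = 2.5, scale = 0.1, seed = 13))
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("every recorded event time is a multiple of the engine step", {
  cfg <- stand_config(duration_s = 2, scale = 0.1, seed = 5)
  r <- run_simulation(cfg)
  for (ev in list(r$spikes$time_s, r$afferent_spikes$time_s)) {
    frac <- ev / cfg$dt
    expect_lt(max(abs(frac - round(frac))), 1e-6)
  }
})

test_that("the locked warm-up leaves the angle exactly constant", {
  r <- run_simulation(stand_config(duration_s = 2, scale = 0.1, seed = 5,
                                   theta0_deg = 5))
  lock <- r$series$t < 1
  expect_true(all(r$series$theta[lock] == 5 * pi / 180))
})

test_that("turning the controller off makes the pendulum fall", {
  r <- run_simulation(stand_config(duration_s = 6, scale = 0.1, seed = 1,
                                   controller = FALSE))
  expect_equal(r$status, "fell")
})

test_that("mean motor-neuron input load is approximately scale invariant", {
  # synaptic bank conductances are fixed while synapse counts scale, so the
  # per-neuron mean drive should match across scales; compare SO MN firing
  rates <- vapply(c(0.1, 0.3), function(sc) {
    r <- run_simulation(stand_config(duration_s = 2, scale = sc, seed = 6,
                                     feedback = FALSE))
    ids <- .mn_ids_test(r, "SO")
    sp <- r$spikes
    n_sp <- sum(sp$unit_id %in% ids & sp$time_s > 0.5 & sp$time_s <= 1)
    n_sp / length(ids) / 0.5
  }, numeric(1))
  expect_equal(rates[1], rates[2], tolerance = 0.35)
})

test_that("fusimotor grid search returns a completing pair and logs trials", {
  cfg <- stand_config(duration_s = 4, scale = 0.1, seed = 2)
  out <- tune_fusimotor(cfg, static_grid = 32, dynamic_grid = 33.8)
  expect_equal(out$static, 32)
  expect_true(nrow(out$log) >= 1)
  expect_error(tune_fusimotor(stand_config(duration_s = 4, scale = 0.1,
                                           controller = FALSE),
                              static_grid = 32, dynamic_grid = 33.8),
               "empty feasible set")
})

test_that("spike event lists and series round-trip through the text formats", {
  r <- run_simulation(stand_config(duration_s = 2, scale = 0.1, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_events(r$spikes, path)
  back <- read_spike_events(path)
  expect_equal(back$time_s, sort(r$spikes$time_s))
  mf <- population_manifest(r$network)
  expect_equal(nrow(mf$neurons), nrow(r$network$neurons))
  sp <- withr::local_tempfile(fileext = ".csv")
  export_series(r, sp, every = 10)
  expect_true(file.exists(sp))
  header <- readLines(sp, n = 2)
  expect_match(header[1], "Nm")
})
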