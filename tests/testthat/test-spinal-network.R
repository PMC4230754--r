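test_that("network composition matches the motor-nucleus table", {
  net <- build_network("model2", seed = 1, scale = 1)
  nn <- net$neurons
  mg <- nn[!is.na(nn$muscle) & nn$muscle == "MG" & nn$is_mn == 1, ]
  expect_equal(nrow(mg), 600)
  expect_equal(sum(mg$type == "S"), 300)
  expect_equal(sum(mg$type == "FR"), 150)
  expect_equal(sum(mg$type == "FF"), 150)
  # six interneuron pools of 350
  expect_equal(sum(nn$is_mn == 0), 6 * 350)
})

test_that("same seed gives identical connectivity; variants differ only in the
           reciprocal-inhibition projections", {
  a <- build_network("model2", seed = 7, scale = 0.1)
  b <- build_network("model2", seed = 7, scale = 0.1)
  expect_identical(network_edges(a), network_edges(b))

  m1 <- build_network("model1", seed = 7, scale = 0.1)
  e2 <- network_edges(a); e1 <- network_edges(m1)
  only2 <- setdiff(unique(e2$projection), unique(e1$projection))
  expect_setequal(only2, c("Ia_TA_IaIN", "IaIN_TS_MN"))
  shared <- e2[!(e2$projection %in% only2), ]
  shared <- shared[order(shared$projection, shared$source, shared$target), ]
  e1s <- e1[order(e1$projection, e1$source, e1$target), ]
  rownames(shared) <- rownames(e1s) <- NULL
  expect_identical(shared, e1s)
})

test_that("no projection from MG Ia afferents onto SO motor neurons", {
  net <- build_network("model2", seed = 3, scale = 0.2)
  expect_false("Ia_MG_MN_SO" %in% names(net$projections))
  expect_true("Ia_SO_MN_MG" %in% names(net$projections))
})

test_that("connectivity fractions match the table within binomial error", {
  net <- build_network("model2", seed = 5, scale = 1)
  p <- net$projections$Ia_SO_MN
  n_src <- sum(diff(p$ptr) > 0)
  n_tgt <- p$tgt_hi - p$tgt_lo
  frac <- length(p$tgt) / (n_src * n_tgt)
  expect_equal(frac, 0.80, tolerance = 0.02)
  p2 <- net$projections$IbIN_TS_MN
  n_src2 <- sum(diff(p2$ptr) > 0)
  expect_equal(length(p2$tgt) / (n_src2 * (p2$tgt_hi - p2$tgt_lo)), 0.10,
               tolerance = 0.05)
})

test_that("thresholds, velocities and delays follow the printed ranges", {
  net <- build_network("model2", seed = 2, scale = 1)
  nn <- net$neurons
  # interneuron thresholds linear from 10 to 20 mV across each pool
  for (pool in c("IaIN_TS", "gII_TA")) {
    thr <- nn$thr[nn$population == pool]
    expect_equal(thr[1], 10)
    expect_equal(thr[length(thr)], 20)
    expect_true(all(diff(thr) > 0))
    expect_lt(max(abs(thr - seq(10, 20, length.out = length(thr)))), 1e-9)
  }
  # motor axon velocities within type bands; delay = length / velocity
  s_mn <- nn[nn$is_mn == 1 & nn$type == "S", ]
  expect_true(all(s_mn$v_axon >= 44 & s_mn$v_axon <= 51))
  ff <- nn[nn$is_mn == 1 & nn$type == "FF", ]
  expect_true(all(ff$v_axon >= 52 & ff$v_axon <= 53))
  expect_equal(conduction_delay(50), 0.8 / 50)
  # recruitment thresholds ordered S <= FR <= FF within each nucleus (bands)
  for (m in muscle_names()) {
    mm <- nn[nn$is_mn == 1 & !is.na(nn$muscle) & nn$muscle == m, ]
    expect_lt(max(mm$thr[mm$type == "S"]), min(mm$thr[mm$type == "FF"]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(build_network("model3"), "arg")
  comp <- pool_composition(1)
  comp$n_S <- comp$n_FR <- comp$n_FF <- 0L
  expect_error(build_network("model2", composition = comp), "zero-size")
})
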