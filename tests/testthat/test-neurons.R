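test_that("resting neurons are silent and stable", {
  pool <- neuron_pool_params(c("S", "FR", "FF", "IN"), seed = 1)
  out <- step_neurons(pool, 0, dt = 5e-5, duration = 1)
  expect_equal(nrow(out$spikes), 0)
  expect_lt(max(abs(out$V)), 1e-6)
})

test_that("suprathreshold current gives periodic firing with a monotone f-I
           relation and a post-spike afterhyperpolarisation", {
  pool <- neuron_pool_params("S", seed = 1, thr_jitter = 0)
  rates <- vapply(c(12, 16, 20, 25, 30), function(I) {
    nrow(step_neurons(pool, I, duration = 1)$spikes)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  out <- step_neurons(pool, 15, duration = 0.5)
  isi <- diff(out$spikes$time_s[-1])      # drop first (onset) interval
  expect_lt(stats::sd(isi) / mean(isi), 0.05)   # periodic
  # AHP: after a brief suprathreshold pulse, the potential dips below rest
  I <- matrix(0, 8000, 1)
  I[1:100, 1] <- 30                      # 5-ms pulse
  pulse <- step_neurons(pool, I, dt = 5e-5)
  expect_gt(nrow(pulse$spikes), 0)
  expect_lt(min(pulse$V), -1)
})

test_that("spike times match a 10x finer-step reference within 1 ms", {
  pool <- neuron_pool_params(c("S", "FF"), seed = 2, thr_jitter = 0)
  coarse <- step_neurons(pool, c(15, 30), dt = 5e-5, duration = 1)$spikes
  fine <- step_neurons(pool, c(15, 30), dt = 5e-6, duration = 1)$spikes
  for (u in 1:2) {
    tc <- coarse$time_s[coarse$unit_id == u]
    tf <- fine$time_s[fine$unit_id == u]
    n <- min(length(tc), length(tf))
    expect_gt(n, 5)
    expect_lt(max(abs(tc[seq_len(n)] - tf[seq_len(n)])), 1e-3)
  }
})

test_that("a slow ramp recruits S before FR before FF", {
  set.seed(1)
  types <- rep(c("S", "FR", "FF"), times = c(30, 15, 15))
  pool <- neuron_pool_params(types, seed = 3, thr_jitter = 0.02)
  nstep <- 40000                       # 2 s ramp 0 -> 40 nA
  I <- matrix(seq(0, 40, length.out = nstep), nstep, nrow(pool))
  sp <- step_neurons(pool, I, dt = 5e-5)$spikes
  first <- vapply(seq_len(nrow(pool)), function(u) {
    t <- sp$time_s[sp$unit_id == u]
    if (length(t)) min(t) else Inf
  }, numeric(1))
  rank_type <- rep(c(1, 2, 3), times = c(30, 15, 15))
  # count cross-type pair inversions
  inv <- 0; tot <- 0
  for (i in seq_along(first)) for (j in seq_along(first)) {
    if (rank_type[i] < rank_type[j]) {
      tot <- tot + 1
      if (first[i] > first[j]) inv <- inv + 1
    }
  }
  expect_lt(inv / tot, 0.02)
})
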