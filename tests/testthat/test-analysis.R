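test_that("preprocessing trims transients, removes trends and preserves
           sinusoid amplitude through resampling", {
  fs <- 10000
  x <- seq(0, 30, by = 1 / fs)[-1]
  out <- preprocess_series(sin(2 * pi * 0.5 * x), fs, 2000)
  expect_equal(length(out) / 2000, 22.5, tolerance = 0.001)

  trend <- 3 + 0.2 * x
  expect_lt(max(abs(preprocess_series(trend, fs, 2000))), 1e-9)

  s <- preprocess_series(sin(2 * pi * 2 * x), fs, 2000, detrend = FALSE)
  expect_equal(max(s), 1, tolerance = 0.01)
  expect_error(preprocess_series(numeric(100), 100), "too short")
})

test_that("COP metrics reproduce closed forms", {
  fs <- 2000
  t <- seq(0, 60, by = 1 / fs)[-1]
  sine <- sin(2 * pi * 0.4 * t)
  m <- cop_metrics(sine, fs, nseg = 2^15)
  expect_equal(m$rms, 1 / sqrt(2), tolerance = 0.01)
  expect_equal(m$f50, 0.4, tolerance = 2000 / 2^15 + 0.02)  # spectral resolution
  # triangle wave amplitude A, frequency f: mean |slope| = 4 A f
  A <- 2; f <- 0.5
  tri <- A * (2 / pi) * asin(sin(2 * pi * f * t))
  expect_equal(cop_metrics(tri, fs)$mv, 4 * A * f, tolerance = 0.01)
})

test_that("cross-correlation peak finds identity, constructed delays, and is
           antisymmetric under argument swap", {
  set.seed(42)
  fs <- 1000
  x <- as.numeric(stats::filter(rnorm(20000), rep(1, 50), sides = 1))
  x <- x[!is.na(x)]
  self <- xcorr_peak(x, x, fs)
  expect_equal(self$rho, 1, tolerance = 1e-9)
  expect_equal(self$lag_s, 0)

  k <- 200                                  # y = x delayed by 200 ms
  y <- c(rep(0, k), x[seq_len(length(x) - k)])
  pk <- xcorr_peak(x, y, fs)
  expect_equal(pk$lag_s, 0.2, tolerance = 0.002)  # x leads y
  sw <- xcorr_peak(y, x, fs)
  expect_equal(sw$lag_s, -pk$lag_s)
  expect_equal(sw$rho, pk$rho, tolerance = 1e-9)

  z <- rnorm(length(x))
  expect_lt(abs(xcorr_peak(x, z, fs, max_lag_s = 0.5)$rho), 0.15)
  expect_error(xcorr_peak(x, rep(1, length(x)), fs), "zero-variance")
})

test_that("activation ratio measures ISI coverage below 250 ms", {
  expect_equal(activation_ratio(numeric(0), c(0, 10)), 0)
  st <- seq(0, 10, by = 0.1)
  expect_equal(activation_ratio(st, c(0, 10)), 1)
  st2 <- seq(0, 5, by = 0.1)
  expect_equal(activation_ratio(st2, c(0, 10)), 0.5)
  # coverage partition: short-ISI time + long-ISI time + edges = record
  st3 <- c(seq(0, 2, by = 0.1), seq(4, 6, by = 0.1))
  isi <- diff(sort(st3))
  short <- sum(isi[isi < 0.25]); long <- sum(isi[isi >= 0.25])
  edges <- 10 - max(st3) + min(st3)
  expect_equal(short + long + edges, 10)
  expect_equal(activation_ratio(st3, c(0, 10)), short / 10)
})

test_that("inter-recruitment intervals collect only interspike intervals
           longer than 250 ms", {
  tonic <- seq(0, 10, by = 0.1)
  expect_length(inter_recruitment_intervals(tonic)$intervals, 0)
  bursts <- unlist(lapply(seq(0, 9.5, by = 0.5), function(t0) t0 + c(0, 0.02, 0.04)))
  iv <- inter_recruitment_intervals(bursts)
  expect_equal(mean(iv$intervals), 0.46, tolerance = 0.01)
  expect_equal(iv$mode_s, 0.475, tolerance = 0.05)
  mixed <- c(0, 0.1, 0.2, 1.0, 1.1, 2.5)
  expect_equal(sort(inter_recruitment_intervals(mixed)$intervals), c(0.8, 1.4))
})

test_that("recruitment phase plots count events in the correct quadrants and
           conserve totals", {
  fs <- 100; dur <- 20
  t <- seq(0, dur, by = 1 / fs)[-1]
  theta <- sin(2 * pi * 0.25 * t)
  omega <- cos(2 * pi * 0.25 * t)
  torque <- -theta
  empty <- recruitment_phase_plot(
    data.frame(time_s = numeric(0), unit_id = integer(0)),
    theta, omega, torque, fs)
  expect_true(all(empty$windows$n_recruited == 0))

  # recruit units only while theta > 0 (forward lean)
  pos_t <- t[theta > 0.3]
  spikes <- data.frame(time_s = sample(pos_t, 40), unit_id = rep(1:20, 2))
  pp <- recruitment_phase_plot(spikes, theta, omega, torque, fs)
  q <- pp$quad_angle_velocity
  expect_gt(q["q1"] + q["q4"], 0.8)
  expect_equal(sum(pp$windows$n_recruited) >= 20, TRUE)
})

test_that("windowed correlation classifies orthodox and paradoxical windows", {
  fs <- 2000
  com <- as.numeric(scale(cumsum(rnorm(fs * 21.1))))
  w <- windowed_length_correlation(com, com, fs)
  expect_equal(w$n_pos, 7)                  # 21 s -> 7 windows of 3 s
  expect_equal(w$n_neg, 0)
  expect_true(all(abs(w$rho - 1) < 1e-12))
  w2 <- windowed_length_correlation(com, -com, fs)
  expect_equal(w2$n_neg, 7)
  ch <- window_sign_test(c(17, 4), c(10, 11))
  expect_s3_class(ch, "htest")
})

test_that("Jarque-Bera bimodality screen: nominal size under the null and
           full power for a separated mixture at protocol sample size", {
  set.seed(7)
  n <- 2000
  rej <- mean(replicate(200, jarque_bera_test(rnorm(n))$p_value < 0.05))
  expect_lt(rej, 0.12)
  # symmetric two-Gaussian mixture, modes separated by 2 sigma
  nprot <- 135000                          # three 22.5-s runs at 2 kHz
  pow <- mean(replicate(20, {
    x <- rnorm(nprot, mean = sample(c(-1, 1), nprot, replace = TRUE), sd = 1)
    jarque_bera_test(x)$p_value < 0.05
  }))
  expect_gt(pow, 0.9)

  runs <- list(rnorm(5000, 3), rnorm(5000, -2))
  cb <- com_bimodality(runs)
  expect_equal(mean(cb$pooled_mm), 0, tolerance = 1e-9)
  expect_s3_class(cb$histogram, "histogram")
})
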