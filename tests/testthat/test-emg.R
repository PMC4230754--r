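ch <- mu_activation_channels("MG", scale = 0.05)
tmpl <- muap_templates(ch)

test_that("EMG synthesis: silence is zero, one spike is one template,
           overlaps superpose", {
  z <- synthesize_emg(data.frame(time_s = numeric(0), unit_id = integer(0)),
                      tmpl, duration = 0.2)
  expect_equal(max(abs(z)), 0)

  one <- synthesize_emg(data.frame(time_s = 0.05, unit_id = 1), tmpl,
                        duration = 0.2)
  # single template instance: peak equals the analytic waveform maximum
  # A * max(x exp(-x^2)) sampled on the output grid
  expect_equal(max(one), tmpl$amplitude[1] * exp(-0.5) / sqrt(2),
               tolerance = 0.05)
  two <- synthesize_emg(data.frame(time_s = c(0.05, 0.052), unit_id = c(1, 2)),
                        tmpl, duration = 0.2)
  a <- synthesize_emg(data.frame(time_s = 0.05, unit_id = 1), tmpl, duration = 0.2)
  b <- synthesize_emg(data.frame(time_s = 0.052, unit_id = 2), tmpl, duration = 0.2)
  expect_equal(two, a + b, tolerance = 1e-12)
  expect_error(synthesize_emg(data.frame(time_s = 0.1, unit_id = 999), tmpl, 2000, 1),
               "template")
  expect_error(synthesize_emg(data.frame(time_s = 0.1, unit_id = 1), tmpl,
                              fs = 500, duration = 1), "2 kHz")
})

test_that("template amplitudes follow motor-unit size ordering", {
  expect_true(all(diff(tmpl$amplitude) >= 0))
})

test_that("envelope: zero in, zero out; tracks slow amplitude modulation;
           scales linearly; symmetric burst stays symmetric (zero phase)", {
  expect_equal(max(abs(emg_envelope(numeric(8000)))), 0)

  set.seed(1)
  fs <- 2000
  t <- seq(0, 6, by = 1 / fs)[-1]
  mod <- 1 + sin(2 * pi * t / 3)
  x <- mod * rnorm(length(t))
  env <- emg_envelope(x, fs)
  expect_gt(stats::cor(env, mod), 0.8)      # envelope tracks the modulation

  expect_equal(emg_envelope(3 * x, fs), 3 * env, tolerance = 1e-6)

  burst <- exp(-((t - 3)^2) / 0.1) * sin(2 * pi * 100 * t)
  envb <- emg_envelope(burst, fs)
  pk <- which.max(envb)
  expect_equal(t[pk], 3, tolerance = 0.02)
  w <- 600
  expect_equal(envb[(pk - w):(pk - 1)], rev(envb[(pk + 1):(pk + w)]),
               tolerance = 0.02)
})

test_that("envelope undershoot is bounded by 1% of the peak for smooth
           bursts", {
  set.seed(3)
  fs <- 2000
  t <- seq(0, 8, by = 1 / fs)[-1]
  x <- exp(-((t - 4)^2) / 0.5) * rnorm(length(t))
  env <- emg_envelope(x, fs)
  expect_gt(min(env), -0.01 * max(env))
})
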