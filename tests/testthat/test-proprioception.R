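test_that("spindle settles to a fixed point under constant input", {
  sp <- spindle_response(rep(0.98, 60000), 32, 33.8)
  late <- sp[sp$t > 2.5, ]
  expect_lt(diff(range(late$Ia)), 0.01)
  expect_lt(diff(range(late$II)), 0.01)
  expect_gt(late$Ia[1], 0)
})

test_that("ramp stretch: the primary shows a dynamic overshoot, the secondary
           essentially tracks the static component", {
  dt <- 5e-5
  L <- c(rep(0.95, 10000), seq(0.95, 1.0, length.out = 10000), rep(1.0, 20000))
  sp <- spindle_response(L, 32, 33.8, dt = dt)
  plat_Ia <- mean(sp$Ia[sp$t > 1.8])
  plat_II <- mean(sp$II[sp$t > 1.8])
  over_Ia <- max(sp$Ia) / plat_Ia
  over_II <- max(sp$II) / plat_II
  expect_gt(over_Ia, 1.3)
  expect_lt(over_II - 1, 0.5 * (over_Ia - 1))

  # higher dynamic fusimotor drive raises the ramp response of Ia but leaves
  # the II plateau unchanged
  sp_hi <- spindle_response(L, 32, 60, dt = dt)
  expect_gt(max(sp_hi$Ia), max(sp$Ia))
  expect_equal(mean(sp_hi$II[sp_hi$t > 1.8]), plat_II, tolerance = 0.02)
})

test_that("spindle integration agrees with an independent stiff-solver
           reference of the intrafusal equations", {
  skip_if_not_installed("deSolve")
  pars <- spindle_params()
  b2 <- pars$fibres$bag2
  gam <- 32
  L_fun <- function(t) 0.95 + ifelse(t < 0.5, 0, ifelse(t < 1, 0.1 * (t - 0.5), 0.05))
  V_fun <- function(t) ifelse(t >= 0.5 & t < 1, 0.1, 0)
  deriv <- function(t, y, p) {
    f <- y[1]; T <- y[2]; Td <- y[3]
    gp <- gam^b2$p
    fss <- gp / (gp + b2$freq^b2$p)
    df <- (fss - f) / b2$tau
    beta <- b2$beta0 + b2$beta2 * f
    Gam <- b2$Gamma2 * f
    L <- L_fun(t); V <- V_fun(t)
    vpr <- V - Td / b2$K_SR
    C <- ifelse(vpr > 0, b2$C_L, b2$C_S)
    term <- C * beta * sign(vpr) * abs(vpr)^b2$a_pow *
      (L - b2$L0_SR - T / b2$K_SR - b2$R)
    dTd <- b2$K_SR / b2$M *
      (term + b2$K_PR * (L - b2$L0_SR - T / b2$K_SR - b2$L0_PR) + Gam - T)
    list(c(df, dT = Td, dTd))
  }
  gp <- gam^b2$p
  f0 <- gp / (gp + b2$freq^b2$p)
  T0 <- (b2$K_PR * (0.95 - b2$L0_SR - b2$L0_PR) + b2$Gamma2 * f0) /
    (1 + b2$K_PR / b2$K_SR)
  ref <- suppressWarnings(deSolve::lsoda(c(f0, T0, 0), seq(0, 1.5, by = 0.01),
                        deriv, NULL, rtol = 1e-6, atol = 1e-8,
                        maxsteps = 50000))
  # same bag2 primary potential from the engine trace
  dt <- 5e-5
  tt <- seq(0, 1.5 - dt, by = dt)
  sp <- .spindle_trace_cpp(L_fun(tt), rep(gam, length(tt)), rep(0, length(tt)),
                           pars, dt)
  pot_cpp <- sp$Ia  # with gamma_d = 0 the bag1 branch is weak; compare shapes
  pot_ref <- pmax(0, b2$G_pri * (ref[, 3] / b2$K_SR - (b2$LN_SR - b2$L0_SR)))
  # compare the bag2 tension trajectory indirectly: engine II is bag2+chain
  # secondary; use correlation of the reference primary with engine Ia
  idx <- findInterval(ref[, 1], tt)
  ok <- idx > 0
  expect_gt(stats::cor(pot_ref[ok], pot_cpp[idx[ok]]), 0.98)
})

test_that("tendon-organ response: zero at rest, monotone statics, digital
           filter matches the continuous transfer function below 10 Hz", {
  expect_equal(gto_response(rep(0, 100), n_ib = 300)$rate, rep(0, 100))
  F <- seq(0, 50, by = 1)
  expect_true(all(diff(gto_static(F)) > 0))
  expect_error(gto_response(-1), ">= 0")

  # frequency response of the bilinear filter vs the analog prototype,
  # measured from sinusoidal steady state with linearised statics
  fs <- 2000
  z <- c(0.15, 1.5, 16); p <- c(0.2, 2, 37)
  Hc <- function(w) prod(p) / prod(z) *
    prod(complex(real = z, imaginary = w)) / prod(complex(real = p, imaginary = w))
  for (f in c(0.5, 2, 10)) {
    t <- seq(0, 20, by = 1 / fs)
    u <- 10 + sin(2 * pi * f * t)
    y <- .gto_trace_cpp(u, fs, 1e6, 1e6)   # 1e6*log1p(u/1e6) ~ u
    yy <- y[t > 10]; uu <- u[t > 10]
    gain <- (diff(range(yy)) / 2) / (diff(range(uu)) / 2)
    expect_equal(gain, Mod(Hc(2 * pi * f)), tolerance = 0.01)
  }
})

test_that("afferent recruitment follows the linear threshold grid", {
  b <- afferent_bundle("SO", "Ia", scale = 1, seed = 1)
  expect_equal(nrow(b), 400)
  expect_true(all(diff(b$thr) > 0))
  expect_equal(range(b$thr), c(0, 50))
  # 50 Hz recruits the whole bundle
  r50 <- recruit_afferents(50, b)
  expect_true(all(r50 > 0))
  # 0 Hz: only the zero-threshold afferent is eligible
  r0 <- recruit_afferents(0, b)
  expect_true(r0[1] >= 0 && all(r0[-1] == 0))
  # 25 Hz recruits half the bundle (within one afferent)
  expect_equal(sum(recruit_afferents(25, b) > 0), 200, tolerance = 1)
  # monotonicity of the recruited set
  sets <- lapply(c(5, 10, 20, 40), function(r) which(recruit_afferents(r, b) > 0))
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  expect_error(recruit_afferents(-1, b), ">= 0")
})

test_that("gamma spike encoding has renewal moments and passes time-rescaling
           diagnostics", {
  expect_length(encode_spikes(rep(0, 1000)), 0)
  dt <- 2e-4
  st <- encode_spikes(rep(20, 500 / dt), dt = dt, order = 6, seed = 2)
  isi <- diff(st)
  expect_equal(mean(isi), 1 / 20, tolerance = 0.02)
  expect_equal(stats::sd(isi) / mean(isi), 1 / sqrt(6), tolerance = 0.05)
  # time rescaling: with constant rate, rescaled ISIs ~ gamma(k, 1/k);
  # de-quantise spike times (uniform within one step) before the KS test
  set.seed(1)
  n <- length(isi)
  isi_j <- isi + stats::runif(n, -dt / 2, dt / 2)
  ks <- stats::ks.test(isi_j * 20, function(q) stats::pgamma(q, 6, 6))
  expect_gt(ks$p.value, 0.01)
  expect_gt(n, 9000)
})

test_that("kernel-smoothed rate of encoded trains recovers a slowly varying
           intensity within 5 percent", {
  dt <- 1e-3
  t <- seq(0, 20, by = dt)[-1]
  rate <- 30 + 10 * sin(2 * pi * 0.2 * t)
  sts <- lapply(1:60, function(k) encode_spikes(rate, dt, order = 6, seed = k))
  counts <- table(cut(unlist(sts), breaks = seq(0, 20, by = 0.5)))
  est <- as.numeric(counts) / (60 * 0.5)
  ref <- vapply(seq_len(40), function(i) mean(rate[t > (i - 1) * 0.5 & t <= i * 0.5]),
                numeric(1))
  expect_lt(mean(abs(est - ref) / ref), 0.05)
})

test_that("fusimotor drive has the stated mean and variance and is
           reproducible only through its seed", {
  fd <- fusimotor_drive(32, 33.8, duration = 200, dt = 1e-3, seed = 5)
  expect_equal(mean(fd$gamma_s), 32, tolerance = 0.02)
  expect_equal(stats::var(fd$gamma_s), 0.03 * 32, tolerance = 0.15)
  const <- fusimotor_drive(32, 33.8, duration = 1, var_frac = 0)
  expect_true(all(const$gamma_s == 32))
  a <- fusimotor_drive(32, 33.8, 1, seed = 1)
  b <- fusimotor_drive(32, 33.8, 1, seed = 2)
  expect_false(identical(a$gamma_s, b$gamma_s))
  expect_equal(mean(a$gamma_s), mean(b$gamma_s), tolerance = 0.05)
})
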