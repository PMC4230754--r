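so <- mtu_params("SO")

test_that("activation saturation is zero at zero, monotone and bounded", {
  expect_equal(saturate(0, 2), 0)
  u <- seq(0, 10, by = 0.1)
  a <- saturate(u, 1.5)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 0 & a < 1))
  expect_error(saturate(-1, 2), "negative")
})

test_that("saturation shape places the tetanic plateau at the tetanic rate
           (root-finding oracle)", {
  ch <- mu_activation_channels("SO", scale = 0.1)
  i <- 5
  # oracle: solve for the filtered level u where saturation reaches 95%
  f <- function(u) saturate(u, ch$c_sat[i]) - 0.95
  u95 <- stats::uniroot(f, c(1e-6, 1e4))$root
  # the critically damped filter's mean output at rate f is f * tc
  expect_equal(u95, ch$f_tet[i] * ch$tc[i], tolerance = 1e-6)
})

test_that("parallel passive force: small at optimal length, viscosity linear,
           elastic part strictly increasing", {
  expect_lt(abs(parallel_passive_force(1, 0, so)), 0.05)
  base <- parallel_passive_force(1.05, 0, so)
  expect_equal(parallel_passive_force(1.05, 2, so) - base, so$b_pe * 2)
  expect_equal(parallel_passive_force(1.05, -2, so) - base, -so$b_pe * 2)
  L <- seq(0.7, 1.6, by = 0.01)
  expect_true(all(diff(parallel_passive_force(L, 0, so)) > 0))
})

test_that("tendon curve: slack ~ zero, unit force at unit length, smooth at
           the toe-linear transition, linear stiffness beyond", {
  expect_lt(tendon_force(0.90, so), 1e-4)
  expect_equal(tendon_force(1, so), 1, tolerance = 1e-3)
  # continuity of value and slope at L_r
  eps <- 1e-6
  f <- function(x) tendon_force(x, so)
  # value continuity: the two-sided difference is bounded by slope * gap
  expect_lt(abs(f(so$L_r + eps) - f(so$L_r - eps)), so$k_t * 3 * eps)
  slope_lo <- (f(so$L_r) - f(so$L_r - eps)) / eps
  slope_hi <- (f(so$L_r + eps) - f(so$L_r)) / eps
  expect_equal(slope_lo, slope_hi, tolerance = 1e-3)
  # linear region slope equals k_t
  s <- (f(1.05) - f(1.03)) / 0.02
  expect_equal(s, so$k_t, tolerance = 0.01)
})

test_that("pinnation keeps muscle thickness constant and flags impossible
           geometry", {
  g <- fibre_geometry(28.9, 1, so)
  expect_equal(g$alpha, so$alpha0_deg * pi / 180)
  g2 <- fibre_geometry(28.9, 0.8, so)
  expect_gt(g2$alpha, g$alpha)                  # shorter fibre, larger angle
  expect_equal(sin(g2$alpha) * 0.8, sin(so$alpha0_deg * pi / 180))
  expect_error(fibre_geometry(28.9, 0.40, so), "pinnation")
})

test_that("contractile force conventions: zero at rest, unity at optimum,
           eccentric > isometric > concentric", {
  expect_equal(contractile_force(0, 0, 1, 0), 0)
  expect_equal(contractile_force(1, 0, 1, 0), 1)
  expect_equal(contractile_force(0, 1, 1, 0), 1)
  iso <- contractile_force(0.5, 0.5, 1, 0)
  ecc <- contractile_force(0.5, 0.5, 1, 0.5)
  conc <- contractile_force(0.5, 0.5, 1, -0.5)
  expect_gt(ecc, iso)
  expect_gt(iso, conc)
  # force-length peaks at optimal length
  L <- seq(0.6, 1.5, by = 0.05)
  fl <- contractile_force(1, 0, L, 0)
  expect_equal(L[which.max(fl)], 1, tolerance = 0.051)
})

test_that("kinematic polynomials give the printed values at upright and are
           consistent with the moment arms", {
  kin <- mtu_kinematics(0)
  expect_equal(kin$L_MTU_cm[kin$muscle == "SO"], 32.30)
  expect_equal(kin$moment_arm_cm[kin$muscle == "SO"], -4.10)
  expect_equal(kin$moment_arm_cm[kin$muscle == "TA"], 4.30)
  # d(L_MTU)/d(theta) sign-consistent with the moment arm (r = -dL/dtheta)
  for (m in muscle_names()) {
    k <- mtu_kinematics(c(-0.5, 0.5), m)
    dL <- diff(k$L_MTU_cm)
    r0 <- mtu_kinematics(0)$moment_arm_cm[mtu_kinematics(0)$muscle == m]
    expect_equal(sign(dL), -sign(r0))
  }
})

test_that("muscle torque: plantar flexors negative, linear in force", {
  expect_equal(muscle_torque(0, c(SO = 0, MG = 0, LG = 0, TA = 0)), 0)
  t1 <- muscle_torque(0, c(SO = 100))
  expect_lt(t1, 0)
  expect_gt(muscle_torque(0, c(TA = 100)), 0)
  expect_equal(muscle_torque(0, c(SO = 200)), 2 * t1)
  expect_error(muscle_torque(0, c(SO = -5)), ">= 0")
})

test_that("activation from spikes: silence gives zero; tetanic drive of all
           units gives total activation near one; a single S unit
           contributes only to the slow channel", {
  ch <- mu_activation_channels("SO", scale = 0.02)   # 16 S + 1 FR + 1 FF
  none <- activation_from_spikes(
    data.frame(time_s = numeric(0), unit_id = integer(0)), ch, duration = 0.5)
  expect_equal(max(none$a_slow + none$a_fast), 0)

  spikes <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i)
    data.frame(time_s = seq(0.001, 3, by = 1 / (1.3 * ch$f_tet[i])), unit_id = i)))
  act <- activation_from_spikes(spikes, ch, duration = 3)
  tot <- act$a_slow + act$a_fast
  expect_gt(max(tot), 0.93)
  expect_lte(max(tot), 1)

  one <- activation_from_spikes(
    data.frame(time_s = seq(0.001, 3, by = 1 / (1.3 * ch$f_tet[1])), unit_id = 1),
    ch, duration = 3)
  expect_equal(max(one$a_fast), 0)
  expect_equal(max(one$a_slow), ch$A_tet[1] * 0.95 / sum(ch$A_tet),
               tolerance = 0.1)
  expect_error(activation_from_spikes(
    data.frame(time_s = 0.1, unit_id = 999), ch, 1), "unknown unit")
})

test_that("fibre dynamics: equilibrium is stationary, added load stretches the
           fibre, trajectory matches a 10x finer-step reference", {
  L_eq <- fibre_equilibrium("SO", theta_deg = 0)
  r <- mtu_response(32.30, 0, 0, "SO", duration = 0.1)
  expect_lt(max(abs(r$L_f - L_eq)), 1e-3)
  expect_lt(max(abs(r$accel)), 1)

  # step increase in MTU length (more tendon load) stretches the fibre
  Lm <- c(rep(32.30, 1000), rep(32.80, 3000))
  r2 <- mtu_response(Lm, 0, 0, "SO")
  expect_gt(max(r2$V_f[1001:1500]), 0)
  expect_gt(r2$L_f[4000], r2$L_f[1])

  # refinement oracle on the free response after an activation step
  n <- 4000
  r_c <- mtu_response(rep(32.30, n), a_slow = 0.2, a_fast = 0, "SO",
                      dt = 5e-5, L_init = L_eq)
  r_f <- mtu_response(rep(32.30, n * 10), a_slow = 0.2, a_fast = 0, "SO",
                      dt = 5e-6, L_init = L_eq)
  expect_equal(r_c$L_f[n], r_f$L_f[n * 10], tolerance = 1e-5)
})

test_that("passive musculotendon dissipates energy under cyclic stretching", {
  t <- seq(0, 2, by = 5e-5)
  Lm <- 32.30 + 0.3 * sin(2 * pi * 1 * t)
  r <- mtu_response(Lm, 0, 0, "SO")
  # work done by the tendon force over one full cycle > 0 (dissipation)
  cyc <- which(t >= 1 & t < 2)
  dLm <- diff(Lm[cyc]) / 100
  W <- sum(r$F_tendon[cyc][-1] * dLm)
  expect_gt(W, 0)
})
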