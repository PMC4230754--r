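bp <- body_params()

test_that("critical stiffness is m*g*h and the passive default is 65% of it", {
  expect_equal(critical_stiffness(bp), 60 * 9.81 * 0.85)
  expect_equal(critical_stiffness(bp), 500.31, tolerance = 1e-6)
  expect_equal(critical_stiffness(body_params(m = 120)), 2 * critical_stiffness(bp))
  expect_equal(bp$K_pas, 0.65 * critical_stiffness(bp))
  expect_equal(bp$B_pas, 5.81)
})

test_that("upright rest is a stationary (unstable) equilibrium", {
  r <- pendulum_response(0, bp, theta0 = 0, duration = 0.5, K_pas = 0, B_pas = 0)
  expect_lt(max(abs(r$series$theta)), 1e-12)
})

test_that("the uncontrolled linearised pendulum diverges at rate sqrt(mgh/I)", {
  th0 <- 1e-4
  r <- pendulum_response(0, bp, theta0 = th0, duration = 1.5,
                         K_pas = 0, B_pas = 0)
  s <- r$series
  lam_ref <- sqrt(bp$g / bp$h)                # sqrt(mgh / (m h^2))
  # cosh growth: fit on the late exponential phase
  t1 <- 0.8; t2 <- 1.4
  th1 <- s$theta[which.min(abs(s$t - t1))]
  th2 <- s$theta[which.min(abs(s$t - t2))]
  lam_est <- log(th2 / th1) / (t2 - t1)
  expect_equal(lam_est, lam_ref, tolerance = 0.02)
})

test_that("a constant torque balancing gravity is stationary; perturbations
           decay iff net stiffness exceeds m*g*h", {
  th_star <- 0.05
  Tm <- -(bp$m * bp$g * bp$h * sin(th_star))   # spring disabled below
  r <- pendulum_response(Tm, bp, theta0 = th_star, duration = 1,
                         K_pas = 0, B_pas = 0)
  expect_lt(max(abs(r$series$theta - th_star)), 1e-10)
  # stabilising spring above critical stiffness -> perturbation decays
  for (Kfac in c(1.2, 0.8)) {
    K <- Kfac * critical_stiffness(bp)
    rr <- pendulum_response(Tm, bp, theta0 = th_star + 0.01, duration = 4,
                            K_pas = K, B_pas = 30, theta_ref = th_star)
    dev_end <- abs(rr$series$theta[nrow(rr$series)] - th_star)
    if (Kfac > 1) expect_lt(dev_end, 0.004) else expect_gt(dev_end, 0.01)
  }
})

test_that("COP equals COM in static equilibrium and the fall flag fires", {
  ob <- observables(theta = 0.08, omega = 0, T_muscles =
                      -(bp$m * bp$g * bp$h * sin(0.08)) + bp$K_pas * 0.08)
  expect_equal(ob$x_cop, ob$x_com, tolerance = 1e-12)
  expect_equal(observables(0)$x_com, 0)

  r <- pendulum_response(0, bp, theta0 = 0.05, duration = 3)
  expect_equal(r$status, "fell")
  expect_lt(r$fell_at, 3)
})

test_that("the impedance estimator recovers a known linear spring within 2%", {
  est <- estimate_passive_mtu_stiffness(duration = 30, seed = 2,
                                        torque_fun = function(th) 120 * th)
  expect_equal(est$K_Nm_rad, 120, tolerance = 0.02)
  expect_error(estimate_passive_mtu_stiffness(sd_deg = 0), "excitation")
  expect_error(estimate_passive_mtu_stiffness(duration = 2), "too short")
})

test_that("with passive elements only the pendulum falls from any lean", {
  for (th0 in c(0.02, -0.02)) {
    r <- pendulum_response(0, bp, theta0 = th0, duration = 10, theta_ref = 0)
    expect_equal(r$status, "fell")
  }
})
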