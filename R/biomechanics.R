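# Body biomechanics: single-link inverted pendulum about the ankle, passive
# joint impedance, sway observables, passive MTU stiffness estimation.

#' Inverted pendulum response
#'
#' Integrates (RK4) the body as a point-mass inverted pendulum about the
#' ankle under an imposed muscular torque series: angular acceleration is the
#' gravitational toppling torque minus the restoring torque (passive
#' stiffness, viscosity and muscle torque). Forward lean is positive;
#' plantar-flexion (triceps surae) torque is negative and restores the body
#' backwards.
#'
#' @param T_muscles Muscular torque series (Nm) or scalar.
#' @param params \code{\link{body_params}}.
#' @param theta0,omega0 Initial angle (rad) and velocity (rad/s).
#' @param dt Step (s).
#' @param duration Duration (s) when a scalar torque is given.
#' @param fall_deg Fall threshold; the run is flagged "fell" beyond it.
#' @param K_pas,B_pas Optional overrides of the passive stiffness/viscosity.
#' @param theta_ref Reference angle (rad) about which the passive joint
#'   stiffness acts (the posture at which the incremental ankle stiffness was
#'   measured); 0 for a spring centred at the vertical.
#' @return List with a series data.frame (t, theta, omega, T_a, x_com,
#'   x_cop), \code{status} ("completed"/"fell") and \code{fell_at} (s or NA).
#' @export
pendulum_response <- function(T_muscles, params = body_params(), theta0 = 0,
                              omega0 = 0, dt = 5e-5, duration = NULL,
                              fall_deg = 25, K_pas = NULL, B_pas = NULL,
                              theta_ref = 0) {
  if (length(T_muscles) == 1L) {
    stopifnot(!is.null(duration))
    T_muscles <- rep(T_muscles, as.integer(round(duration / dt)))
  }
  Kp <- if (is.null(K_pas)) params$K_pas else K_pas
  Bp <- if (is.null(B_pas)) params$B_pas else B_pas
  out <- .pendulum_trace_cpp(T_muscles, params$m, params$h, params$g, Kp, Bp,
                             theta0, omega0, dt, fall_deg * pi / 180, theta_ref)
  n <- length(out$theta)
  fell <- out$fell_at >= 0
  keep <- if (fell) seq_len(out$fell_at + 1L) else seq_len(n)
  ser <- data.frame(t = (keep - 1) * dt, theta = out$theta[keep],
                    omega = out$omega[keep], T_a = out$T_a[keep])
  ser$x_com <- params$h * sin(ser$theta)
  ser$x_cop <- ser$T_a / (params$m * params$g)
  list(series = ser, status = if (fell) "fell" else "completed",
       fell_at = if (fell) out$fell_at * dt else NA_real_)
}

#' Sway observables from pendulum state
#'
#' Centre-of-mass displacement from the pendulum geometry and
#' centre-of-pressure displacement from the ankle-torque balance (massless
#' feet); in static equilibrium the two coincide.
#'
#' @param theta Angle (rad).
#' @param omega Angular velocity (rad/s).
#' @param T_muscles Muscle torque (Nm).
#' @param params \code{\link{body_params}}.
#' @param theta_ref Passive-stiffness reference angle (rad).
#' @return Data.frame (x_com, x_cop) in metres.
#' @export
observables <- function(theta, omega = 0, T_muscles = 0, params = body_params(),
                        theta_ref = 0) {
  n <- max(length(theta), length(omega), length(T_muscles))
  theta <- rep_len(theta, n); omega <- rep_len(omega, n)
  T_muscles <- rep_len(T_muscles, n)
  T_a <- params$K_pas * (theta - theta_ref) + params$B_pas * omega - T_muscles
  data.frame(x_com = params$h * sin(theta), x_cop = T_a / (params$m * params$g))
}

#' Passive ankle stiffness of the Hill-type MTUs
#'
#' With the neuronal controller off, imposes a Gaussian stochastic ankle
#' angle trajectory, records the passive muscle torque, and estimates the
#' cross-spectral ankle impedance; the passive MTU stiffness is the mean
#' impedance magnitude over 0-1 Hz, expressed as a fraction of the critical
#' stiffness m*g*h.
#'
#' @param duration Record duration (s).
#' @param seed Integer seed for the angle trajectory.
#' @param sd_deg Standard deviation of the imposed angle (degrees).
#' @param tau Correlation time of the angle process (s).
#' @param theta_mean_deg Mean imposed angle (degrees).
#' @param dt Engine step (s).
#' @param params \code{\link{body_params}}.
#' @param torque_fun Optional replacement restoring-torque mechanism: a
#'   function theta_rad -> restoring torque (Nm); used to validate the
#'   estimator against a known linear spring.
#' @return List with \code{fraction} (of critical stiffness),
#'   \code{K_Nm_rad}, and the frequency-resolved impedance estimate.
#' @export
estimate_passive_mtu_stiffness <- function(duration = 60, seed = 1, sd_deg = 1,
                                           tau = 0.05, theta_mean_deg = 0,
                                           dt = 5e-5, params = body_params(),
                                           torque_fun = NULL) {
  if (sd_deg <= 0) stop("imposed angle must have positive variance (no excitation)")
  if (duration < 10) stop("record too short for 0-1 Hz spectral resolution")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 29))
  nstep <- as.integer(round(duration / dt))
  sd_rad <- sd_deg * pi / 180
  th <- numeric(nstep)
  th[1] <- 0
  a <- dt / tau; b <- sqrt(2 * dt / tau) * sd_rad
  innov <- stats::rnorm(nstep - 1)
  for (i in 2:nstep) th[i] <- th[i - 1] - th[i - 1] * a + b * innov[i - 1]
  th <- th + theta_mean_deg * pi / 180
  fs_out <- 200
  dec <- as.integer(round(1 / (fs_out * dt)))
  if (is.null(torque_fun)) {
    run <- .run_passive(th, dt, dec, seed)
    torque <- -run$T_muscles      # restoring torque of the MTUs
    th_rec <- run$theta
  } else {
    idx <- seq(1, nstep, by = dec)
    th_rec <- th[idx]
    torque <- vapply(th_rec, torque_fun, numeric(1))
  }
  # cross-spectral impedance estimate (H1) on the decimated records
  seg <- 2^floor(log2(length(th_rec) / 8))
  sp <- welch_csd(th_rec - mean(th_rec), torque - mean(torque), fs = fs_out,
                  nseg = seg)
  band <- sp$freq > 0 & sp$freq <= 1
  # static (in-phase) component of the impedance; the quadrature part is the
  # viscous contribution
  H <- Re(sp$cross[band]) / sp$pxx[band]
  K <- mean(H)
  list(fraction = K / critical_stiffness(params), K_Nm_rad = K,
       freq = sp$freq[band], impedance = H)
}

# imposed-angle passive engine run (controller off, zero activation)
.run_passive <- function(theta_rad, dt, decim, seed) {
  plant <- .build_plant(theta0_deg = theta_rad[1] * 180 / pi)
  res <- .run_engine_cpp(
    mode = 2L, dt = dt, duration_s = length(theta_rad) * dt, lock_s = 0,
    theta0 = theta_rad[1], fall_rad = 10,
    body = unclass(body_params()), muscles = plant$muscles,
    curves = plant$curves, spindle = spindle_params(), gto = plant$gto,
    neurons_ = NULL, projections = list(),
    descending = list(step = integer(0), axon = integer(0)),
    afferents_ = NULL,
    fusimotor = list(mean_s = 32, mean_d = 33.8, var_frac = 0, tau = 0.1),
    feedback_on = FALSE, controller_on = FALSE,
    fixed_a_ = NULL, imposed_theta_ = theta_rad,
    seed_encode = seed, seed_fusimotor = seed,
    decim = decim, record_spikes = FALSE)
  data.frame(theta = res$theta, T_muscles = res$T_muscles)
}

# plant description shared by all engine calls
.build_plant <- function(theta0_deg = 5, spindle_gains = c(1, 1, 1),
                         spindle_rest = c(0.98, 0.98, 0.98, 0.95)) {
  spindle_rest <- rep_len(spindle_rest, 4)
  muscles <- lapply(seq_along(muscle_names()), function(mi) {
    m <- muscle_names()[mi]
    p <- .mtu_list(m)
    p$L_init <- fibre_equilibrium(m, theta_deg = theta0_deg)
    # spindle mounting: the muscle length at the upright operating point maps
    # onto the intrafusal model rest length (triceps surae shorten actively at
    # stance, the dorsiflexor stays passive, hence the lower TA target)
    p$spindle_offset <- spindle_rest[mi] - p$L_init
    p
  })
  names(muscles) <- muscle_names()
  attr(muscles, "act_norm") <- rep(1, 4)
  cnt <- afferent_counts(1)
  list(muscles = muscles,
       curves = list(slow = .curve_list("slow"), fast = .curve_list("fast")),
       gto = list(g1 = 60, g2 = 4, n_ib = cnt$n_Ib[match(muscle_names(), cnt$muscle)]))
}
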