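# Hill-type musculotendon mechanics: activation dynamics, passive and
# contractile forces, pinnation geometry, kinematic polynomials, joint torque.

.curve_list <- function(fibre) {
  tab <- flfv_params()
  as.list(tab[tab$fibre == fibre, ])
}

.mtu_list <- function(muscle) {
  p <- mtu_params(muscle)
  kp <- kinematics_poly(muscle)
  c(p, list(a = kp$a, b = kp$b))
}

#' Smooth activation saturation
#'
#' Monotone saturating map applied to the filtered motor-unit spike train;
#' models calcium-release saturation. Zero at zero, bounded by 1, with shape
#' parameter \code{c} tuned per motor unit so the plateau is reached at the
#' unit's tetanic rate.
#'
#' @param u Filtered activation signal (>= 0).
#' @param c Shape parameter (> 0).
#' @return Saturated signal in [0, 1).
#' @export
saturate <- function(u, c) {
  if (any(u < 0)) stop("negative activation input")
  e <- exp(-c * u)
  (1 - e) / (1 + e)
}

#' Parallel passive fibre force
#'
#' Exponential-strain elastic law plus linear viscosity, normalised by the
#' muscle's maximum isometric force.
#'
#' @param L_f_norm Fibre length in optimal-length units (> 0).
#' @param V_f_norm Fibre velocity in L0/s (positive = stretch).
#' @param params Musculotendon parameter list/row (see \code{\link{mtu_params}}).
#' @return Normalised passive force.
#' @export
parallel_passive_force <- function(L_f_norm, V_f_norm = 0, params = mtu_params("SO")) {
  stopifnot(all(L_f_norm > 0))
  n <- max(length(L_f_norm), length(V_f_norm))
  .pe_force_cpp(rep_len(L_f_norm, n), rep_len(V_f_norm, n), params)
}

#' Tendon force-length relation
#'
#' Exponential toe region blending into a linear region of stiffness
#' \code{k_t} above the transition length \code{L_r}; continuous in value and
#' slope everywhere, essentially zero for a slack tendon, and equal to 1
#' (i.e. F0) at normalised length 1 by the normalisation convention.
#'
#' @param L_t_norm Tendon length normalised by the length at which tendon
#'   force equals F0.
#' @param params Musculotendon parameter list/row.
#' @return Normalised tendon force (>= 0).
#' @export
tendon_force <- function(L_t_norm, params = mtu_params("SO")) {
  .tendon_force_cpp(L_t_norm, params$c_t, params$k_t, params$L_r)
}

#' Fibre-tendon geometry
#'
#' Pinnation follows the constant-muscle-thickness rule
#' sin(alpha) * L_f = sin(alpha0) * L0; tendon length is the musculotendon
#' length minus the projected fibre length.
#'
#' @param L_MTU_cm Musculotendon length (cm).
#' @param L_f_norm Fibre length (L0 units).
#' @param params Musculotendon parameter list/row.
#' @return List with \code{L_t_norm} and \code{alpha} (rad).
#' @export
fibre_geometry <- function(L_MTU_cm, L_f_norm, params = mtu_params("SO")) {
  stopifnot(all(L_MTU_cm > 0), all(L_f_norm > 0))
  sin_a <- sin(params$alpha0_deg * pi / 180) / L_f_norm
  if (any(sin_a >= 1))
    stop("pinnation geometry impossible (sin(alpha) >= 1)")
  alpha <- asin(sin_a)
  L_t <- (L_MTU_cm - L_f_norm * params$L0_cm * cos(alpha)) / params$Lt1_cm
  list(L_t_norm = L_t, alpha = alpha)
}

#' Contractile-element force
#'
#' Sum of slow (type-I) and fast (type-II) contractile contributions, each
#' activation x force-length x force-velocity. FL peaks at optimal length and
#' FV is continuous at zero velocity; eccentric force exceeds isometric.
#'
#' @param a_slow,a_fast Activations in [0, 1].
#' @param L_f_norm Fibre length (L0 units).
#' @param V_f_norm Fibre velocity (L0/s, positive = stretch).
#' @return Normalised contractile force.
#' @export
contractile_force <- function(a_slow, a_fast, L_f_norm, V_f_norm = 0) {
  stopifnot(all(a_slow >= 0), all(a_slow <= 1), all(a_fast >= 0), all(a_fast <= 1))
  n <- max(length(a_slow), length(a_fast), length(L_f_norm), length(V_f_norm))
  L <- rep_len(L_f_norm, n); V <- rep_len(V_f_norm, n)
  rep_len(a_slow, n) * .flfv_cpp(L, V, .curve_list("slow"), FALSE) +
    rep_len(a_fast, n) * .flfv_cpp(L, V, .curve_list("fast"), FALSE)
}

#' Musculoskeletal kinematics
#'
#' Quartic polynomials (fit to inverse-kinematics data) give each muscle's
#' musculotendon length and ankle moment arm as functions of the ankle angle.
#' The dorsiflexor moment arm has the opposite sign to the plantar flexors.
#'
#' @param theta_deg Ankle angle (degrees; forward lean / dorsiflexion
#'   positive).
#' @param muscle Optional muscle code; default returns all four.
#' @return For one angle: data.frame with columns muscle, L_MTU_cm,
#'   moment_arm_cm. For a vector of angles and one muscle: data.frame of the
#'   series.
#' @export
mtu_kinematics <- function(theta_deg, muscle = NULL) {
  tab <- kinematics_poly()
  musc <- if (is.null(muscle)) tab$muscle else muscle
  ev <- function(cf, x) cf[1] + x * (cf[2] + x * (cf[3] + x * (cf[4] + x * cf[5])))
  if (length(theta_deg) == 1L) {
    out <- do.call(rbind, lapply(musc, function(m) {
      kp <- kinematics_poly(m)
      data.frame(muscle = m, L_MTU_cm = ev(kp$a, theta_deg),
                 moment_arm_cm = ev(kp$b, theta_deg))
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (length(musc) != 1L) stop("vector angles require a single muscle")
  kp <- kinematics_poly(musc)
  data.frame(theta_deg = theta_deg, L_MTU_cm = ev(kp$a, theta_deg),
             moment_arm_cm = ev(kp$b, theta_deg))
}

#' Net muscular ankle torque
#'
#' Twice (both legs) the sum of moment arm times tendon force over the four
#' muscles. Dorsiflexion torque is positive, so triceps surae force produces
#' negative (plantar-flexion) torque.
#'
#' @param theta_deg Ankle angle (degrees).
#' @param F_tendon Named vector of tendon forces (N) for SO, MG, LG, TA
#'   (missing muscles count as zero).
#' @return Torque (Nm).
#' @export
muscle_torque <- function(theta_deg, F_tendon) {
  if (any(F_tendon < 0)) stop("tendon forces must be >= 0")
  kin <- mtu_kinematics(theta_deg)
  f <- numeric(nrow(kin))
  names(f) <- kin$muscle
  f[names(F_tendon)] <- F_tendon
  2 * sum(kin$moment_arm_cm / 100 * f)
}

#' Motor-unit activation channels of a muscle
#'
#' Per-unit critically damped filter time constants, tetanic rates and
#' amplitudes, and tuned saturation shapes, recruitment-ordered (S, FR, FF).
#'
#' @param muscle Muscle code.
#' @param scale Pool scale factor.
#' @return Data.frame, one row per motor unit, with attribute
#'   \code{act_norm} (the sum of tetanic amplitudes used to normalise the
#'   muscle activation).
#' @export
mu_activation_channels <- function(muscle = "SO", scale = 1) {
  comp <- pool_composition(scale)
  comp <- comp[comp$muscle == muscle, ]
  if (nrow(comp) != 1L) stop("unknown muscle: ", muscle)
  types <- rep(c("S", "FR", "FF"), times = c(comp$n_S, comp$n_FR, comp$n_FF))
  out <- .mu_channel_params(types)
  out$unit_id <- seq_len(nrow(out))
  out$mu_type <- types
  attr(out, "act_norm") <- sum(out$A_tet)
  out
}

#' Muscle activation from motor-unit spike trains
#'
#' Each unit's spike train is filtered by a second-order critically damped
#' system and passed through the smooth saturation; S-type outputs sum to the
#' slow-fibre activation and FR/FF outputs to the fast-fibre activation, both
#' normalised by the sum of all tetanic amplitudes of the muscle.
#'
#' @param spikes \code{spike_events} data.frame (time_s, unit_id) for one
#'   motor nucleus, unit ids indexing rows of \code{channels}.
#' @param channels \code{\link{mu_activation_channels}} result.
#' @param duration Record length (s).
#' @param dt Step (s).
#' @return Data.frame (t, a_slow, a_fast).
#' @export
activation_from_spikes <- function(spikes, channels, duration, dt = 5e-4) {
  if (nrow(spikes) && (any(spikes$unit_id < 1) || any(spikes$unit_id > nrow(channels))))
    stop("unknown unit id in spike train")
  nstep <- as.integer(round(duration / dt))
  t <- (seq_len(nstep) - 1) * dt
  a_s <- numeric(nstep); a_f <- numeric(nstep)
  norm <- attr(channels, "act_norm")
  if (is.null(norm)) norm <- sum(channels$A_tet)
  for (i in seq_len(nrow(channels))) {
    st <- spikes$time_s[spikes$unit_id == i]
    if (!length(st)) next
    x1 <- 0; x2 <- 0
    tc <- channels$tc[i]
    e1 <- exp(-dt / tc)
    u <- numeric(nstep)
    imp <- tabulate(pmin(nstep, floor(st / dt) + 1L), nbins = nstep)
    for (k in seq_len(nstep)) {
      x1 <- x1 + imp[k]
      x2 <- e1 * (x2 + (dt / tc) * x1)
      x1 <- e1 * x1
      u[k] <- x2
    }
    a <- channels$A_tet[i] * saturate(u, channels$c_sat[i])
    if (channels$mu_type[i] == "S") a_s <- a_s + a else a_f <- a_f + a
  }
  data.frame(t = t, a_slow = a_s / norm, a_fast = a_f / norm)
}

#' Open-loop musculotendon response
#'
#' Integrates the fibre state (RK4) under an imposed musculotendon length and
#' activation time course; the fibre accelerates according to the force
#' balance along the fibre (tendon force against the pinnation-projected
#' contractile plus passive force) with the fibre mass.
#'
#' @param L_MTU_cm Imposed MTU length series (cm) or scalar.
#' @param a_slow,a_fast Activation series or scalars.
#' @param muscle Muscle code.
#' @param dt Step (s).
#' @param duration Duration (s) if scalars given.
#' @param L_init Initial fibre length (L0); default is the static passive
#'   equilibrium at the initial MTU length.
#' @return Data.frame (t, L_f, V_f, F_tendon, accel).
#' @export
mtu_response <- function(L_MTU_cm, a_slow = 0, a_fast = 0, muscle = "SO",
                         dt = 5e-5, duration = NULL, L_init = NULL) {
  if (length(L_MTU_cm) == 1L) {
    stopifnot(!is.null(duration))
    n <- as.integer(round(duration / dt))
    L_MTU_cm <- rep(L_MTU_cm, n)
  }
  n <- length(L_MTU_cm)
  a_slow <- rep_len(a_slow, n); a_fast <- rep_len(a_fast, n)
  mtu <- .mtu_list(muscle)
  if (is.null(L_init))
    L_init <- .fibre_equilibrium_cpp(L_MTU_cm[1] / 100, a_slow[1], a_fast[1],
                                     mtu, .curve_list("slow"), .curve_list("fast"))
  out <- .mtu_trace_cpp(L_MTU_cm / 100, a_slow, a_fast, mtu,
                        .curve_list("slow"), .curve_list("fast"), L_init, dt)
  data.frame(t = (seq_len(n) - 1) * dt, L_f = out$L_f, V_f = out$V_f,
             F_tendon = out$F_tendon, accel = out$accel)
}

#' Static passive fibre equilibrium
#'
#' Fibre length (L0 units) at which tendon force balances the
#' pinnation-projected fibre force at a given MTU length and activation.
#' @inheritParams mtu_response
#' @param theta_deg Ankle angle used to compute the MTU length when
#'   \code{L_MTU_cm} is missing.
#' @export
fibre_equilibrium <- function(muscle = "SO", theta_deg = 0, L_MTU_cm = NULL,
                              a_slow = 0, a_fast = 0) {
  if (is.null(L_MTU_cm))
    L_MTU_cm <- mtu_kinematics(theta_deg, muscle)$L_MTU_cm[1]
  .fibre_equilibrium_cpp(L_MTU_cm / 100, a_slow, a_fast, .mtu_list(muscle),
                         .curve_list("slow"), .curve_list("fast"))
}
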