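# Simulation protocol orchestration: configuration, closed-loop runs, the
# locked-pendulum basal-drive check, fusimotor tuning and scale reduction.

#' Simulation configuration
#'
#' @param variant "model2" (complete circuit) or "model1" (no reciprocal
#'   inhibition from TA Ia afferents onto the triceps surae).
#' @param duration_s Run duration (s).
#' @param lock_s Warm-up during which the pendulum is clamped at its initial
#'   angle while the neuromuscular system reaches steady state.
#' @param dt Integration step (s); all subsystems share this RK4 clock.
#' @param scale Pool scale factor in (0, 1].
#' @param theta0_deg Initial forward lean (degrees).
#' @param fall_deg Fall threshold (degrees).
#' @param seed Master seed; named sub-streams (network build, descending
#'   drive, afferent encoding, fusimotor noise) are derived from it.
#' @param fusimotor_static,fusimotor_dynamic Mean fusimotor drives.
#' @param fusimotor_var_frac Variance of the fusimotor noise as a fraction of
#'   the mean.
#' @param fusimotor_tau Correlation time of the fusimotor noise (s).
#' @param descending_n,descending_rate,descending_shape Descending drive:
#'   number of axons, per-axon rate (Hz) and gamma shape factor.
#' @param g_descending Descending synaptic bank per motor neuron (nS).
#' @param spindle_gains Length-3 gain multipliers (bag1, bag2, chain).
#' @param gamma_order Gamma order of afferent spike encoding.
#' @param thr_jitter Relative threshold jitter in the pools.
#' @param feedback Logical; proprioceptive feedback enabled.
#' @param controller Logical; spinal controller (neurons) enabled.
#' @param fs_out Output sampling rate for continuous records (Hz).
#' @return Object of class \code{stand_config}.
#' @export
stand_config <- function(variant = c("model2", "model1"), duration_s = 30,
                         lock_s = 1, dt = 5e-5, scale = 1, theta0_deg = 5,
                         fall_deg = 25, seed = 1,
                         fusimotor_static = 32, fusimotor_dynamic = 33.8,
                         fusimotor_var_frac = 0.03, fusimotor_tau = 0.1,
                         descending_n = 400, descending_rate = 50,
                         descending_shape = 25, g_descending = 1230,
                         spindle_gains = c(1, 1, 1), gamma_order = 6,
                         thr_jitter = 0.02, feedback = TRUE, controller = TRUE,
                         fs_out = 2000) {
  variant <- match.arg(variant)
  if (dt <= 0) stop("dt must be positive")
  if (lock_s >= duration_s) stop("lock_s must be shorter than duration_s")
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  cfg <- list(variant = variant, duration_s = duration_s, lock_s = lock_s,
              dt = dt, scale = scale, theta0_deg = theta0_deg,
              fall_deg = fall_deg, seed = as.integer(seed),
              fusimotor_static = fusimotor_static,
              fusimotor_dynamic = fusimotor_dynamic,
              fusimotor_var_frac = fusimotor_var_frac,
              fusimotor_tau = fusimotor_tau,
              descending_n = descending_n, descending_rate = descending_rate,
              descending_shape = descending_shape,
              g_descending = g_descending, spindle_gains = spindle_gains,
              gamma_order = gamma_order, thr_jitter = thr_jitter,
              feedback = feedback, controller = controller, fs_out = fs_out)
  class(cfg) <- "stand_config"
  cfg
}

#' Rescale a configuration's populations
#'
#' Pool and afferent counts shrink with proportions preserved; synaptic bank
#' conductances are unchanged (individual synaptic weights scale up
#' inversely), keeping the mean synaptic drive per neuron approximately
#' scale-invariant.
#'
#' @param config A \code{\link{stand_config}}.
#' @param scale New scale in (0, 1].
#' @return Updated configuration.
#' @export
reduced_scale_config <- function(config, scale) {
  stopifnot(inherits(config, "stand_config"))
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  comp <- pool_composition(scale)   # errors on empty pools
  config$scale <- scale
  config
}

.derived_seeds <- function(seed) {
  list(network = .substream(seed, 1), descending = .substream(seed, 2),
       encode = .substream(seed, 3), fusimotor = .substream(seed, 4))
}

.engine_network_args <- function(net, dt) {
  nn <- net$neurons
  neurons <- list(
    n = nrow(nn), Cs = nn$Cs, Cd = nn$Cd, gls = nn$gls, gld = nn$gld,
    gc = nn$gc, thr = nn$thr, gNa = nn$gNa, gKf = nn$gKf, gKs = nn$gKs,
    tau_q = nn$tau_q, two_comp = as.integer(nn$two_comp),
    is_mn = as.integer(nn$is_mn),
    muscle = as.integer(net$muscle_of), mu_slow = as.integer(nn$mu_slow),
    axon_delay_steps = as.integer(ifelse(is.na(nn$v_axon), 1L,
        pmax(1, round(conduction_delay(ifelse(is.na(nn$v_axon), 50, nn$v_axon)) / dt)))),
    tc = nn$tc, c_sat = nn$c_sat, A_tet = nn$A_tet,
    emg_amp = nn$emg_amp, emg_lambda_ms = nn$emg_lambda_ms)
  projections <- lapply(net$projections, function(p) {
    list(ptr = p$ptr, tgt = p$tgt, delay_steps = as.integer(p$delay_steps),
         tgt_lo = as.integer(p$tgt_lo), tgt_hi = as.integer(p$tgt_hi),
         ghat = p$ghat, inhib = p$inhib, to_dend = p$to_dend,
         alpha = p$alpha, beta = p$beta,
         Tdur_steps = max(1L, as.integer(round(p$Tdur_ms / (dt * 1000)))),
         src_kind = as.integer(p$src_kind))
  })
  af <- net$afferents
  afferents <- list(
    n = nrow(af), muscle = as.integer(af$m_idx),
    type = as.integer(match(af$type, c("Ia", "II", "Ib")) - 1L),
    delay_steps = as.integer(pmax(1, round(af$delay_s / dt))),
    thr = af$thr, r0 = af$r0, order = af$order)
  list(neurons = neurons, projections = unname(projections), afferents = afferents)
}

.engine_plant_args <- function(config, net) {
  plant <- .build_plant(theta0_deg = config$theta0_deg,
                        spindle_gains = config$spindle_gains)
  attr(plant$muscles, "act_norm") <- net$act_norm
  # Ib force sharing uses the scaled afferent counts actually simulated
  cnt <- net$afferent_counts
  plant$gto$n_ib <- cnt$n_Ib[match(muscle_names(), cnt$muscle)]
  plant
}

.descending_events <- function(config, seeds) {
  dr <- generate_descending_drive(config$descending_n, config$descending_rate,
                                  config$descending_shape, config$duration_s,
                                  seeds$descending)
  list(step = as.integer(floor(dr$time_s / config$dt)),
       axon = as.integer(dr$unit_id - 1L),
       events = dr)
}

#' Run a closed-loop simulation
#'
#' One second of clamped-pendulum warm-up followed by free closed-loop
#' dynamics of the complete neuromusculoskeletal model, all subsystems
#' advanced on the common RK4 clock. Deterministic given the configuration
#' seed. A fall sets the result status rather than raising an error.
#'
#' @param config A \code{\link{stand_config}}.
#' @return Object of class \code{stand_result}: \code{series} (pendulum and
#'   torque records at \code{fs_out}), \code{muscles} (per-muscle records
#'   including fibre state, tendon force, activations, receptor rates and
#'   EMG), \code{spikes} and \code{afferent_spikes} event lists,
#'   \code{descending} drive events, \code{network}, \code{status}
#'   ("completed" or "fell"), \code{fell_at}, \code{fs}, and the
#'   configuration echo.
#' @export
run_simulation <- function(config = stand_config()) {
  stopifnot(inherits(config, "stand_config"))
  seeds <- .derived_seeds(config$seed)
  net <- build_network(config$variant, seed = seeds$network,
                       scale = config$scale, thr_jitter = config$thr_jitter,
                       g_descending = config$g_descending,
                       n_descending = config$descending_n,
                       gamma_order = config$gamma_order)
  args <- .engine_network_args(net, config$dt)
  plant <- .engine_plant_args(config, net)
  desc <- if (config$controller) .descending_events(config, seeds)
          else list(step = integer(0), axon = integer(0), events = NULL)
  decim <- max(1L, as.integer(round(1 / (config$fs_out * config$dt))))
  res <- .run_engine_cpp(
    mode = 0L, dt = config$dt, duration_s = config$duration_s,
    lock_s = config$lock_s, theta0 = config$theta0_deg * pi / 180,
    fall_rad = config$fall_deg * pi / 180,
    body = c(unclass(body_params()),
             list(theta_ref = config$theta0_deg * pi / 180)),
    muscles = plant$muscles,
    curves = plant$curves, spindle = spindle_params(config$spindle_gains),
    gto = plant$gto,
    neurons_ = if (config$controller) args$neurons else NULL,
    projections = if (config$controller) args$projections else list(),
    descending = desc[c("step", "axon")],
    afferents_ = if (config$controller && config$feedback) args$afferents else NULL,
    fusimotor = list(mean_s = config$fusimotor_static,
                     mean_d = config$fusimotor_dynamic,
                     var_frac = config$fusimotor_var_frac,
                     tau = config$fusimotor_tau),
    feedback_on = config$feedback, controller_on = config$controller,
    fixed_a_ = NULL, imposed_theta_ = NULL,
    seed_encode = seeds$encode, seed_fusimotor = seeds$fusimotor,
    decim = decim, record_spikes = TRUE)
  .assemble_result(res, config, net, desc$events)
}

.assemble_result <- function(res, config, net, descending) {
  keep <- res$t <= if (!is.null(res$fell_at)) res$fell_at else Inf
  series <- data.frame(t = res$t, theta = res$theta, omega = res$omega,
                       T_muscles = res$T_muscles, T_a = res$T_a,
                       x_com = res$x_com, x_cop = res$x_cop)[keep, ]
  musc <- lapply(seq_along(muscle_names()), function(k) {
    data.frame(t = res$t, L_f = res$L_f[, k], V_f = res$V_f[, k],
               F_tendon = res$F_tendon[, k], a_slow = res$a_slow[, k],
               a_fast = res$a_fast[, k], Ia = res$Ia[, k], II = res$II[, k],
               Ib = res$Ib[, k], emg = res$emg[, k])[keep, ]
  })
  names(musc) <- muscle_names()
  spikes <- data.frame(time_s = res$spike_t, unit_id = res$spike_id)
  class(spikes) <- c("spike_events", "data.frame")
  aff <- data.frame(time_s = res$aff_t, unit_id = res$aff_id)
  class(aff) <- c("spike_events", "data.frame")
  out <- list(series = series, muscles = musc, spikes = spikes,
              afferent_spikes = aff, descending = descending, network = net,
              status = res$status, fell_at = res$fell_at,
              fs = config$fs_out, config = config)
  class(out) <- "stand_result"
  out
}

#' @export
print.stand_result <- function(x, ...) {
  cat("Quiet-stance simulation (", x$config$variant, "), ",
      x$config$duration_s, " s at scale ", x$config$scale, "\n", sep = "")
  cat("  status:", x$status,
      if (x$status == "fell") sprintf("(at %.2f s)", x$fell_at) else "", "\n")
  if (nrow(x$series)) {
    cat(sprintf("  mean lean %.2f deg, mean torque %.1f Nm\n",
                mean(x$series$theta) * 180 / pi, mean(x$series$T_muscles)))
  }
  cat("  spikes:", nrow(x$spikes), "neuronal,", nrow(x$afferent_spikes),
      "afferent\n")
  invisible(x)
}

#' Maximum isometric ankle torque of the model
#'
#' Locked-pendulum run with the triceps surae fully active (slow and fast
#' contractile elements at their tetanic shares) and the dorsiflexor
#' passive; returns the settled torque magnitude.
#'
#' @param theta_deg Locked ankle angle (degrees).
#' @param settle_s Settling time (s).
#' @param dt Step (s).
#' @return Torque magnitude (Nm).
#' @export
max_torque <- function(theta_deg = 5, settle_s = 1.5, dt = 5e-5) {
  plant <- .build_plant(theta0_deg = theta_deg)
  comp <- pool_composition(1)
  fixed <- matrix(0, 4, 2)
  for (k in 1:3) {
    ch <- mu_activation_channels(muscle_names()[k])
    fr_slow <- sum(ch$A_tet[ch$mu_type == "S"]) / sum(ch$A_tet)
    fixed[k, ] <- c(fr_slow, 1 - fr_slow)
  }
  res <- .run_engine_cpp(
    mode = 3L, dt = dt, duration_s = settle_s, lock_s = settle_s,
    theta0 = theta_deg * pi / 180, fall_rad = 10,
    body = unclass(body_params()), muscles = plant$muscles,
    curves = plant$curves, spindle = spindle_params(), gto = plant$gto,
    neurons_ = NULL, projections = list(),
    descending = list(step = integer(0), axon = integer(0)),
    afferents_ = NULL,
    fusimotor = list(mean_s = 32, mean_d = 33.8, var_frac = 0, tau = 0.1),
    feedback_on = FALSE, controller_on = FALSE,
    fixed_a_ = fixed, imposed_theta_ = NULL,
    seed_encode = 1L, seed_fusimotor = 1L,
    decim = 100L, record_spikes = FALSE)
  n <- length(res$T_muscles)
  mean(abs(res$T_muscles[res$t > settle_s - 0.2]))
}

#' Basal drive check
#'
#' Locked pendulum, proprioceptive feedback disabled, descending gamma drive
#' on: returns the mean muscle torque (active increment over the passive
#' baseline) divided by the maximum active torque, over the window after the
#' warm-up second.
#'
#' @param config A \code{\link{stand_config}} (duration, scale and
#'   descending parameters are honoured; feedback is forced off).
#' @param warmup_s Discarded initial window (s).
#' @return List with \code{fraction}, \code{basal_Nm}, \code{passive_Nm} and
#'   \code{max_Nm}.
#' @export
basal_drive_check <- function(config = stand_config(duration_s = 5, scale = 0.2),
                              warmup_s = 1) {
  stopifnot(inherits(config, "stand_config"))
  config$feedback <- FALSE
  seeds <- .derived_seeds(config$seed)
  net <- build_network(config$variant, seed = seeds$network,
                       scale = config$scale, thr_jitter = config$thr_jitter,
                       g_descending = config$g_descending,
                       n_descending = config$descending_n,
                       gamma_order = config$gamma_order)
  args <- .engine_network_args(net, config$dt)
  plant <- .engine_plant_args(config, net)
  desc <- .descending_events(config, seeds)
  res <- .run_engine_cpp(
    mode = 1L, dt = config$dt, duration_s = config$duration_s,
    lock_s = config$duration_s, theta0 = config$theta0_deg * pi / 180,
    fall_rad = 10,
    body = c(unclass(body_params()),
             list(theta_ref = config$theta0_deg * pi / 180)),
    muscles = plant$muscles,
    curves = plant$curves, spindle = spindle_params(config$spindle_gains),
    gto = plant$gto,
    neurons_ = if (config$controller) args$neurons else NULL,
    projections = if (config$controller) args$projections else list(),
    descending = desc[c("step", "axon")],
    afferents_ = NULL,
    fusimotor = list(mean_s = config$fusimotor_static,
                     mean_d = config$fusimotor_dynamic,
                     var_frac = 0, tau = config$fusimotor_tau),
    feedback_on = FALSE, controller_on = config$controller,
    fixed_a_ = NULL, imposed_theta_ = NULL,
    seed_encode = seeds$encode, seed_fusimotor = seeds$fusimotor,
    decim = 10L, record_spikes = FALSE)
  win <- res$t >= warmup_s
  basal <- mean(abs(res$T_muscles[win]))
  passive <- abs(res$T_muscles[1])
  mx <- max_torque(config$theta0_deg)
  list(fraction = (basal - passive) / (mx - passive),
       basal_Nm = basal, passive_Nm = passive, max_Nm = mx)
}

#' Grid search for stabilising fusimotor drives
#'
#' Runs short trial simulations over a grid of (static, dynamic) mean
#' fusimotor drives and returns the first pair whose trial completes without
#' falling; all trials are logged.
#'
#' @param config Base configuration (trial duration taken from it).
#' @param static_grid,dynamic_grid Candidate mean drives.
#' @return List with the selected \code{static}/\code{dynamic} pair and the
#'   trial \code{log} data.frame.
#' @export
tune_fusimotor <- function(config = stand_config(duration_s = 8, scale = 0.2),
                           static_grid = c(28, 30, 32, 34),
                           dynamic_grid = c(30, 32, 34, 36)) {
  log <- data.frame()
  for (s in static_grid) for (d in dynamic_grid) {
    cfg <- config
    cfg$fusimotor_static <- s; cfg$fusimotor_dynamic <- d
    r <- run_simulation(cfg)
    log <- rbind(log, data.frame(static = s, dynamic = d, status = r$status,
                                 fell_at = ifelse(is.null(r$fell_at), NA, r$fell_at)))
    if (r$status == "completed")
      return(list(static = s, dynamic = d, log = log))
  }
  stop("empty feasible set: no grid point stabilised the pendulum")
}
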