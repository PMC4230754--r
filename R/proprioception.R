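# Proprioceptors: muscle spindle (bag1/bag2/chain), Golgi tendon organ,
# afferent recruitment law, stochastic spike encoding, fusimotor drive.

#' Spindle model parameters
#'
#' Mechanical constants of the three intrafusal fibres plus the configurable
#' afferent-potential gain multipliers.
#' @param gains Length-3 multipliers for the bag1, bag2 and chain
#'   afferent-potential gains.
#' @return List consumed by \code{\link{spindle_response}} and the engine.
#' @export
spindle_params <- function(gains = c(1, 1, 1)) {
  tab <- spindle_param_table()
  fib <- lapply(c("bag1", "bag2", "chain"), function(f) {
    v <- as.list(tab[[f]])
    names(v) <- tab$param
    v
  })
  names(fib) <- c("bag1", "bag2", "chain")
  list(fibres = fib, gains = gains, S_occl = fib$bag1$S_occl)
}

#' Muscle spindle response
#'
#' Advances the bag1, bag2 and chain intrafusal fibre dynamics under an
#' imposed normalised fibre-length trajectory and fusimotor drives. The
#' primary (Ia) rate combines all three intrafusal outputs (bag1 carrying the
#' dynamic, fusimotor-gamma-dynamic-sensitive component) with partial
#' occlusion; the secondary (II) rate combines bag2 and chain only and tracks
#' the static stretch component.
#'
#' @param L_f_norm Fibre length series (L0 units, > 0).
#' @param gamma_s,gamma_d Static/dynamic fusimotor drives (scalar or series,
#'   >= 0).
#' @param dt Step (s).
#' @param params \code{\link{spindle_params}} result.
#' @return Data.frame (t, Ia, II) of rates in Hz.
#' @export
spindle_response <- function(L_f_norm, gamma_s = 32, gamma_d = 33.8,
                             dt = 5e-5, params = spindle_params()) {
  stopifnot(all(L_f_norm > 0), all(gamma_s >= 0), all(gamma_d >= 0))
  n <- length(L_f_norm)
  out <- .spindle_trace_cpp(L_f_norm, rep_len(gamma_s, n), rep_len(gamma_d, n),
                            params, dt)
  data.frame(t = (seq_len(n) - 1) * dt, Ia = out$Ia, II = out$II)
}

#' Golgi tendon organ response
#'
#' Per-afferent static saturating nonlinearity (gain 60 Hz, force constant
#' 4 N, applied to the tendon force shared across the muscle's Ib
#' population) followed by the tendon-organ transfer-function dynamics,
#' discretised by the bilinear transform at the engine rate.
#'
#' @param F_tendon Tendon force series (N, >= 0).
#' @param n_ib Number of Ib afferents of the muscle.
#' @param dt Step (s).
#' @param g1 Static gain (Hz).
#' @param g2 Force constant (N).
#' @return Data.frame (t, rate, pooled) with the per-afferent rate and the
#'   pooled (sum over afferents) rate, in Hz.
#' @export
gto_response <- function(F_tendon, n_ib = 300, dt = 5e-5, g1 = 60, g2 = 4) {
  if (any(F_tendon < 0)) stop("tendon force must be >= 0")
  r <- .gto_trace_cpp(F_tendon / n_ib, 1 / dt, g1, g2)
  data.frame(t = (seq_along(r) - 1) * dt, rate = r, pooled = n_ib * r)
}

#' Static tendon-organ nonlinearity
#' @param F_share Force per afferent (N).
#' @inheritParams gto_response
#' @return Rate in Hz.
#' @export
gto_static <- function(F_share, g1 = 60, g2 = 4) {
  ifelse(F_share <= 0, 0, g1 * log1p(F_share / g2))
}

#' Afferent bundle description
#'
#' Recruitment thresholds increase linearly from 0 to 50 Hz across the
#' bundle, initial rates are Gaussian (mean 5 Hz, sd 2.5 Hz, clipped at 0),
#' and conduction velocities vary linearly within the tabulated range for
#' the afferent type.
#'
#' @param muscle Muscle code.
#' @param type "Ia", "II" or "Ib".
#' @param scale Scale factor for the bundle size.
#' @param seed Seed for the initial-rate draw.
#' @param gamma_order Gamma order of the spike encoder.
#' @return Data.frame, one row per afferent.
#' @export
afferent_bundle <- function(muscle = "SO", type = c("Ia", "II", "Ib"),
                            scale = 1, seed = 1, gamma_order = 6) {
  type <- match.arg(type)
  cnt <- afferent_counts(scale)
  n <- cnt[cnt$muscle == muscle, paste0("n_", type)]
  if (!length(n)) stop("unknown muscle: ", muscle)
  vr <- sensory_params()[[paste0("v_", type)]]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 19))
  v <- .lin_across(vr[1], vr[2], n)
  data.frame(unit_id = seq_len(n), muscle = muscle, type = type,
             thr = if (n == 1L) 0 else 50 * (seq_len(n) - 1) / (n - 1),
             r0 = pmax(0, stats::rnorm(n, 5, 2.5)),
             velocity = v, delay_s = conduction_delay(v),
             order = gamma_order)
}

#' Afferent recruitment law
#'
#' Afferent i is recruited when the receptor output reaches its threshold;
#' at recruitment it fires at its initial rate and thereafter modulates
#' one-to-one with the receptor output above threshold. When the receptor
#' output reaches 50 Hz the whole bundle is recruited.
#'
#' @param receptor_rate Receptor model output (Hz, >= 0); scalar or vector.
#' @param bundle \code{\link{afferent_bundle}} result.
#' @return For scalar input, a numeric vector of per-afferent mean rates; for
#'   vector input, a matrix (time x afferent).
#' @export
recruit_afferents <- function(receptor_rate, bundle) {
  if (any(receptor_rate < 0)) stop("receptor rate must be >= 0")
  f <- function(r) ifelse(r >= bundle$thr, bundle$r0 + r - bundle$thr, 0)
  if (length(receptor_rate) == 1L) f(receptor_rate)
  else t(vapply(receptor_rate, f, numeric(nrow(bundle))))
}

#' Encode a rate series as a gamma point process
#'
#' Non-homogeneous gamma point process by time rescaling: rescaling the spike
#' train by its cumulative intensity yields unit-mean gamma renewal
#' statistics of the given order.
#'
#' @param rate Intensity series (Hz, >= 0).
#' @param dt Step (s).
#' @param order Gamma order (>= 1); order 1 is a Poisson process.
#' @param seed Integer seed.
#' @return Vector of spike times (s).
#' @export
encode_spikes <- function(rate, dt = 5e-5, order = 6, seed = 1) {
  if (any(rate < 0)) stop("rates must be >= 0")
  stopifnot(order >= 1)
  .encode_gamma_cpp(rate, dt, order, as.integer(seed))
}

#' Stochastic fusimotor drive
#'
#' Gaussian (Ornstein-Uhlenbeck) processes with the stated mean and a
#' stationary variance equal to \code{var_frac} of the mean, clipped at zero.
#'
#' @param mean_static,mean_dynamic Mean drives (> 0).
#' @param duration Duration (s).
#' @param dt Step (s).
#' @param seed Integer seed.
#' @param var_frac Variance as a fraction of the mean (default 3 percent).
#' @param tau Correlation time of the process (s).
#' @return Data.frame (t, gamma_s, gamma_d).
#' @export
fusimotor_drive <- function(mean_static = 32, mean_dynamic = 33.8,
                            duration = 1, dt = 5e-5, seed = 1,
                            var_frac = 0.03, tau = 0.1) {
  stopifnot(mean_static > 0, mean_dynamic > 0, duration > 0)
  n <- as.integer(round(duration / dt))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 23))
  ou <- function(mu) {
    sd_st <- sqrt(var_frac * mu)
    if (sd_st == 0) return(rep(mu, n))
    x <- numeric(n)
    x[1] <- stats::rnorm(1, mu, sd_st)
    a <- dt / tau; b <- sqrt(2 * dt / tau) * sd_st
    innov <- stats::rnorm(n - 1)
    for (i in 2:n) x[i] <- x[i - 1] + (mu - x[i - 1]) * a + b * innov[i - 1]
    pmax(x, 0)
  }
  data.frame(t = (seq_len(n) - 1) * dt, gamma_s = ou(mean_static),
             gamma_d = ou(mean_dynamic))
}
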