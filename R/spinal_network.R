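# Spinal network construction: motor-neuron and interneuron pools, afferent
# bundles, Bernoulli connectivity at the tabulated fractions, and the
# descending drive.

.substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% 2147483629) + 1L
}

.SYN_KINETICS <- list(
  exc = list(alpha = 1.1, beta = 0.19, Tdur_ms = 1.0),   # 1/ms at T = 1 mM
  inh = list(alpha = 4.0, beta = 0.18, Tdur_ms = 1.0)
)

#' Axonal conduction delay
#'
#' @param velocity Conduction velocity (m/s).
#' @param length Conduction path length (m); the spinal-cord-to-muscle
#'   distance, 0.80 m, is used for both motor and sensory axons.
#' @return Delay in seconds.
#' @export
conduction_delay <- function(velocity, length = 0.80) {
  stopifnot(all(velocity > 0))
  length / velocity
}

.lin_across <- function(lo, hi, n) if (n == 1L) (lo + hi) / 2 else lo + (hi - lo) * (seq_len(n) - 1) / (n - 1)

# Electrical parameters for a set of neurons of one type, varying linearly
# across the pool with a small multiplicative jitter of the threshold.
.neuron_type_params <- function(type, n, thr_jitter = 0.02) {
  tab <- neuron_param_table()
  row <- tab[tab$type == type, ]
  rin <- .lin_across(row$rin_mohm_lo, row$rin_mohm_hi, n)
  tau <- .lin_across(row$tau_ms_lo, row$tau_ms_hi, n)
  thr <- .lin_across(row$thr_mv_lo, row$thr_mv_hi, n)
  thr <- thr * (1 + thr_jitter * stats::runif(n, -1, 1))
  tau_q <- .lin_across(row$ahp_tau_ms_lo, row$ahp_tau_ms_hi, n)
  G <- 1 / rin                                   # uS
  if (type == "IN") {
    out <- data.frame(
      Cs = tau * G, Cd = 1, gls = G, gld = 0, gc = 0,
      thr = thr, gNa = 15 * G, gKf = 6 * G, gKs = row$ahp_gfac * G,
      tau_q = tau_q, two_comp = 0L, v_axon = NA_real_)
  } else {
    gls <- 0.4 * G; gld <- 0.9 * G; gc <- 1.8 * G
    out <- data.frame(
      Cs = tau * gls, Cd = tau * gld, gls = gls, gld = gld, gc = gc,
      thr = thr, gNa = 15 * G, gKf = 6 * G, gKs = row$ahp_gfac * G,
      tau_q = tau_q, two_comp = 1L,
      v_axon = .lin_across(row$v_axon_lo, row$v_axon_hi, n))
  }
  out$type <- type
  out
}

# Motor-unit activation-channel parameters across a muscle's pool: contraction
# time and tetanic rate linear within the type band, tetanic amplitude growing
# exponentially (100-fold) across the recruitment-ordered pool.
.mu_channel_params <- function(types, amp_range = 100) {
  tab <- mu_activation_table()
  n <- length(types)
  tc <- ftet <- lam <- numeric(n)
  for (ty in unique(types)) {
    idx <- which(types == ty)
    row <- tab[tab$type == ty, ]
    tc[idx] <- .lin_across(row$tc_s_lo, row$tc_s_hi, length(idx))
    ftet[idx] <- .lin_across(row$ftet_hz_lo, row$ftet_hz_hi, length(idx))
    lam[idx] <- .lin_across(row$emg_lambda_ms_lo, row$emg_lambda_ms_hi, length(idx))
  }
  A_tet <- if (n == 1L) 1 else exp(log(amp_range) * (seq_len(n) - 1) / (n - 1))
  # saturation shape: plateau (95% of tetanic amplitude) reached at the
  # tetanic rate, where the critically damped filter's mean output is f*tc
  c_sat <- log(39) / (ftet * tc)
  data.frame(tc = tc, f_tet = ftet, A_tet = A_tet, c_sat = c_sat,
             emg_amp = A_tet^0.7, emg_lambda_ms = lam)
}

# Bernoulli adjacency: returns 0-based CSR over sources
.draw_csr <- function(n_src, tgt_ids0, frac) {
  tgt <- vector("list", n_src)
  nt <- length(tgt_ids0)
  for (s in seq_len(n_src)) {
    keep <- stats::runif(nt) < frac
    tgt[[s]] <- tgt_ids0[keep]
  }
  counts <- lengths(tgt)
  list(ptr = as.integer(c(0L, cumsum(counts))), tgt = as.integer(unlist(tgt)),
       n_edges = sum(counts))
}

#' Build the spinal network
#'
#' Instantiates the motor nuclei (S/FR/FF motor neurons per muscle), six
#' interneuron pools (group-II excitatory, Ib inhibitory and reciprocal
#' Ia inhibitory pools for each of the triceps surae and tibialis anterior
#' sides), the afferent bundles, and all synaptic projections with Bernoulli
#' connectivity at the tabulated fractions. \code{variant = "model1"} omits
#' the reciprocal-inhibition projections from TA Ia afferents (via the Ia
#' inhibitory interneurons) onto the triceps surae motor neurons; everything
#' else is identical between variants.
#'
#' @param variant "model1" (no reciprocal inhibition onto TS) or "model2"
#'   (complete circuit).
#' @param seed Integer seed; per-unit randomised parameters and connectivity
#'   draws are reproducible from it.
#' @param scale Pool scale factor in (0, 1]; counts are rounded preserving
#'   type proportions and synaptic bank conductances are preserved (so the
#'   mean drive per neuron is scale-invariant).
#' @param composition Motor-nucleus composition data.frame (defaults to the
#'   tabulated one at \code{scale}).
#' @param afferents Afferent count data.frame at \code{scale}.
#' @param n_in Interneurons per pool at full scale.
#' @param thr_jitter Relative width of the uniform threshold jitter.
#' @param g_descending Saturated descending synaptic bank per motor neuron (nS).
#' @param descending_frac Descending connectivity fraction.
#' @param n_descending Number of descending axons.
#' @param gamma_order Gamma order of afferent spike encoding.
#' @return An object of class \code{spinal_network}.
#' @export
build_network <- function(variant = c("model2", "model1"), seed = 1, scale = 1,
                          composition = pool_composition(scale),
                          afferents = afferent_counts(scale),
                          n_in = 350, thr_jitter = 0.02,
                          g_descending = 1230, descending_frac = 0.30,
                          n_descending = 400, gamma_order = 6) {
  variant <- match.arg(variant)
  stopifnot(scale > 0, scale <= 1)
  if (any(rowSums(composition[, c("n_S", "n_FR", "n_FF")]) <= 0))
    stop("zero-size motor nucleus in composition")
  muscles <- muscle_names()
  sens <- sensory_params()
  n_in_s <- max(1L, as.integer(round(n_in * scale)))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 11))

  ## ---- neurons --------------------------------------------------------
  nrn <- list(); pop_label <- character(0)
  muscle_of <- integer(0); is_mn <- integer(0); mu_slow <- integer(0)
  for (mi in seq_along(muscles)) {
    comp <- composition[composition$muscle == muscles[mi], ]
    types <- rep(c("S", "FR", "FF"), times = c(comp$n_S, comp$n_FR, comp$n_FF))
    for (ty in c("S", "FR", "FF")) {
      n_ty <- sum(types == ty)
      if (n_ty == 0L) next
      nrn[[length(nrn) + 1L]] <- .neuron_type_params(ty, n_ty, thr_jitter)
      pop_label <- c(pop_label, rep(paste0("MN_", muscles[mi]), n_ty))
      muscle_of <- c(muscle_of, rep(mi - 1L, n_ty))
      is_mn <- c(is_mn, rep(1L, n_ty))
      mu_slow <- c(mu_slow, rep(as.integer(ty == "S"), n_ty))
    }
  }
  in_pools <- c("gII_TS", "Ib_TS", "IaIN_TS", "gII_TA", "Ib_TA", "IaIN_TA")
  for (pl in in_pools) {
    nrn[[length(nrn) + 1L]] <- .neuron_type_params("IN", n_in_s, thr_jitter = 0)
    pop_label <- c(pop_label, rep(pl, n_in_s))
    muscle_of <- c(muscle_of, rep(-1L, n_in_s))
    is_mn <- c(is_mn, rep(0L, n_in_s))
    mu_slow <- c(mu_slow, rep(0L, n_in_s))
  }
  nrn <- do.call(rbind, nrn)
  n_neurons <- nrow(nrn)
  nrn$id <- seq_len(n_neurons)
  nrn$population <- pop_label
  nrn$muscle <- ifelse(muscle_of >= 0, muscles[muscle_of + 1L], NA)
  nrn$is_mn <- is_mn
  nrn$mu_slow <- mu_slow

  # motor-unit channels per muscle (recruitment-ordered within the nucleus)
  mu <- data.frame(tc = rep(1, n_neurons), f_tet = 0, A_tet = 0, c_sat = 0,
                   emg_amp = 0, emg_lambda_ms = 1)
  for (mi in seq_along(muscles)) {
    idx <- which(muscle_of == mi - 1L)
    if (!length(idx)) next
    mu[idx, ] <- .mu_channel_params(nrn$type[idx])
  }
  act_norm <- vapply(seq_along(muscles) - 1L,
                     function(m) sum(mu$A_tet[muscle_of == m]), numeric(1))

  ## ---- afferent bundles ----------------------------------------------
  set.seed(.substream(seed, 12))
  vr <- list(Ia = sens$v_Ia, II = sens$v_II, Ib = sens$v_Ib)
  aff <- list()
  for (mi in seq_along(muscles)) {
    cnts <- afferents[afferents$muscle == muscles[mi], ]
    for (ty in c("Ia", "II", "Ib")) {
      n_a <- cnts[[paste0("n_", ty)]]
      v <- .lin_across(vr[[ty]][1], vr[[ty]][2], n_a)
      aff[[length(aff) + 1L]] <- data.frame(
        muscle = muscles[mi], m_idx = mi - 1L, type = ty,
        thr = if (n_a == 1L) 0 else 50 * (seq_len(n_a) - 1) / (n_a - 1),
        r0 = pmax(0, stats::rnorm(n_a, 5, 2.5)),
        velocity = v, delay_s = conduction_delay(v),
        order = gamma_order)
    }
  }
  aff <- do.call(rbind, aff)
  aff$id <- seq_len(nrow(aff))

  ## ---- projections ----------------------------------------------------
  set.seed(.substream(seed, 13))
  idx_mn <- function(m) which(muscle_of == (m - 1L)) - 1L          # 0-based
  idx_pool <- function(pl) which(pop_label == pl) - 1L
  aff_idx <- function(m, ty) which(aff$m_idx == (m - 1L) & aff$type == ty) - 1L
  kin <- .SYN_KINETICS
  projections <- list()
  add_proj <- function(name, src_kind, src_ids0, n_src_global, tgt_ids0, frac,
                       bank_nS, n_bank, inhib, delay_by_src) {
    csr_local <- .draw_csr(length(src_ids0), sort(tgt_ids0), frac)
    # remap local CSR rows onto global source numbering
    ptr <- integer(n_src_global + 1L)
    counts <- integer(n_src_global)
    counts[src_ids0 + 1L] <- diff(csr_local$ptr)
    ptr <- as.integer(c(0L, cumsum(counts)))
    tgt <- integer(csr_local$n_edges)
    pos <- ptr[src_ids0 + 1L]
    for (s in seq_along(src_ids0)) {
      a <- csr_local$ptr[s] + 1L; b <- csr_local$ptr[s + 1L]
      if (b >= a) tgt[(pos[s] + 1L):(pos[s] + (b - a + 1L))] <- csr_local$tgt[a:b]
    }
    delays <- integer(n_src_global)
    delays[src_ids0 + 1L] <- delay_by_src
    kk <- if (inhib) kin$inh else kin$exc
    to_dend <- all(nrn$two_comp[sort(tgt_ids0) + 1L] == 1L)
    projections[[name]] <<- list(
      name = name, ptr = ptr, tgt = tgt, delay_steps = delays,
      tgt_lo = min(tgt_ids0), tgt_hi = max(tgt_ids0) + 1L,
      ghat = (bank_nS / max(1, n_bank)) / 1000,      # uS per synapse
      g_bank_nS = bank_nS, conn = frac,
      inhib = inhib, to_dend = to_dend,
      alpha = kk$alpha, beta = kk$beta, Tdur_ms = kk$Tdur_ms,
      src_kind = src_kind)
  }
  dsteps <- function(delay_s, dt = 5e-5) pmax(1L, as.integer(round(delay_s / dt)))
  syn_delay <- rep(1e-3, 1)   # local (interneuronal) synaptic latency, s

  ts_mn0 <- sort(unlist(lapply(1:3, idx_mn)))
  ta_mn0 <- idx_mn(4L)
  n_aff_glob <- nrow(aff)

  # descending -> TS MNs
  add_proj("desc_TS", 0L, seq_len(n_descending) - 1L, n_descending, ts_mn0,
           descending_frac, g_descending, descending_frac * n_descending,
           inhib = FALSE, delay_by_src = rep(1L, n_descending))
  # homonymous Ia -> MN
  for (mi in seq_along(muscles)) {
    src <- aff_idx(mi, "Ia")
    add_proj(paste0("Ia_", muscles[mi], "_MN"), 1L, src, n_aff_glob, idx_mn(mi),
             sens$conn_Ia_MN_hom, sens$g_Ia_MN, sens$conn_Ia_MN_hom * length(src),
             FALSE, dsteps(aff$delay_s[src + 1L]))
  }
  # heteronymous Ia within the triceps surae (no MG -> SO projection)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3), c(3, 2), c(3, 1))) {
    src <- aff_idx(pair[1], "Ia")
    n_hom <- length(src)
    add_proj(paste0("Ia_", muscles[pair[1]], "_MN_", muscles[pair[2]]), 1L,
             src, n_aff_glob, idx_mn(pair[2]), sens$conn_Ia_MN_syn,
             sens$g_Ia_MN * sens$conn_Ia_MN_syn / sens$conn_Ia_MN_hom,
             sens$conn_Ia_MN_syn * n_hom, FALSE, dsteps(aff$delay_s[src + 1L]))
  }
  # Ia -> reciprocal Ia interneurons of the antagonist side
  src_ts_ia <- sort(unlist(lapply(1:3, function(m) aff_idx(m, "Ia"))))
  src_ta_ia <- aff_idx(4L, "Ia")
  add_proj("Ia_TS_IaIN", 1L, src_ts_ia, n_aff_glob, idx_pool("IaIN_TA"),
           sens$conn_Ia_IN, sens$g_Ia_IN, sens$conn_Ia_IN * length(src_ts_ia),
           FALSE, dsteps(aff$delay_s[src_ts_ia + 1L]))
  add_proj("Ia_TA_IaIN", 1L, src_ta_ia, n_aff_glob, idx_pool("IaIN_TS"),
           sens$conn_Ia_IN, sens$g_Ia_IN, sens$conn_Ia_IN * length(src_ta_ia),
           FALSE, dsteps(aff$delay_s[src_ta_ia + 1L]))
  # II -> group II excitatory INs; Ib -> Ib inhibitory INs (same side)
  src_ts_ii <- sort(unlist(lapply(1:3, function(m) aff_idx(m, "II"))))
  src_ta_ii <- aff_idx(4L, "II")
  src_ts_ib <- sort(unlist(lapply(1:3, function(m) aff_idx(m, "Ib"))))
  src_ta_ib <- aff_idx(4L, "Ib")
  add_proj("II_TS_gII", 1L, src_ts_ii, n_aff_glob, idx_pool("gII_TS"),
           sens$conn_II_IN, sens$g_II_IN, sens$conn_II_IN * length(src_ts_ii),
           FALSE, dsteps(aff$delay_s[src_ts_ii + 1L]))
  add_proj("II_TA_gII", 1L, src_ta_ii, n_aff_glob, idx_pool("gII_TA"),
           sens$conn_II_IN, sens$g_II_IN, sens$conn_II_IN * length(src_ta_ii),
           FALSE, dsteps(aff$delay_s[src_ta_ii + 1L]))
  add_proj("Ib_TS_IbIN", 1L, src_ts_ib, n_aff_glob, idx_pool("Ib_TS"),
           sens$conn_Ib_IN, sens$g_Ib_IN, sens$conn_Ib_IN * length(src_ts_ib),
           FALSE, dsteps(aff$delay_s[src_ts_ib + 1L]))
  add_proj("Ib_TA_IbIN", 1L, src_ta_ib, n_aff_glob, idx_pool("Ib_TA"),
           sens$conn_Ib_IN, sens$g_Ib_IN, sens$conn_Ib_IN * length(src_ta_ib),
           FALSE, dsteps(aff$delay_s[src_ta_ib + 1L]))
  # interneurons -> motor neurons
  in_mn <- function(name, pool, tgt0, frac, inhib) {
    src <- idx_pool(pool)
    add_proj(name, 2L, src, n_neurons, tgt0, frac, sens$g_IN_MN,
             frac * length(src), inhib, rep(dsteps(syn_delay), length(src)))
  }
  in_mn("IaIN_TS_MN", "IaIN_TS", ts_mn0, sens$conn_IaIN_MN, TRUE)
  in_mn("IaIN_TA_MN", "IaIN_TA", ta_mn0, sens$conn_IaIN_MN, TRUE)
  in_mn("IbIN_TS_MN", "Ib_TS", ts_mn0, sens$conn_IbIN_MN, TRUE)
  in_mn("IbIN_TA_MN", "Ib_TA", ta_mn0, sens$conn_IbIN_MN, TRUE)
  in_mn("gII_TS_MN", "gII_TS", ts_mn0, sens$conn_gIIIN_MN, FALSE)
  in_mn("gII_TA_MN", "gII_TA", ta_mn0, sens$conn_gIIIN_MN, FALSE)

  if (variant == "model1") {
    # the reciprocal-inhibition pathway (TA Ia -> Ia INs -> TS MNs) is drawn
    # identically and then removed, so both variants share all other edges
    projections$Ia_TA_IaIN <- NULL
    projections$IaIN_TS_MN <- NULL
  }

  structure(list(
    variant = variant, seed = seed, scale = scale,
    neurons = cbind(nrn, mu),
    muscle_of = muscle_of,
    afferents = aff,
    projections = projections,
    n_descending = n_descending,
    act_norm = act_norm,
    composition = composition,
    afferent_counts = afferents
  ), class = "spinal_network")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.spinal_network <- function(x, ...) {
  cat("Spinal network (", x$variant, ", scale ", x$scale, ")\n", sep = "")
  cat("  neurons:  ", nrow(x$neurons), " (",
      sum(x$neurons$is_mn == 1), " MNs, ", sum(x$neurons$is_mn == 0), " INs)\n", sep = "")
  cat("  afferents:", nrow(x$afferents), "\n")
  cat("  projections:", length(x$projections), "with",
      sum(vapply(x$projections, function(p) length(p$tgt), numeric(1))), "edges\n")
  invisible(x)
}

#' Export the network as an edge list
#'
#' @param net A \code{\link{build_network}} result.
#' @param dt Engine step used to convert per-source delays back to seconds.
#' @return Data.frame with columns source, target, projection, g_max_nS,
#'   delay_s, sign. Sources are labelled by kind ("D" descending axon,
#'   "A" afferent, "N" neuron) and 1-based index.
#' @export
network_edges <- function(net, dt = 5e-5) {
  stopifnot(inherits(net, "spinal_network"))
  out <- lapply(net$projections, function(p) {
    ne <- length(p$tgt)
    if (!ne) return(NULL)
    src_rep <- rep(seq_len(length(p$ptr) - 1L), diff(p$ptr))
    kind <- c("D", "A", "N")[p$src_kind + 1L]
    data.frame(source = paste0(kind, src_rep),
               target = paste0("N", p$tgt + 1L),
               projection = p$name,
               g_max_nS = p$ghat * 1000,
               delay_s = p$delay_steps[src_rep] * dt,
               sign = if (p$inhib) -1 else 1)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Generate the stochastic descending drive
#'
#' Independent homogeneous gamma renewal point processes, one per descending
#' axon. With shape 25 and rate 50 Hz the interspike-interval coefficient of
#' variation is 20 percent.
#'
#' @param n_axons Number of axons.
#' @param rate Mean firing rate per axon (Hz), > 0.
#' @param shape Gamma shape (order) >= 1.
#' @param duration Duration (s), > 0.
#' @param seed Integer seed.
#' @return Data.frame (class \code{spike_events}) with columns \code{time_s}
#'   and \code{unit_id} (axon index), time-sorted.
#' @export
generate_descending_drive <- function(n_axons = 400, rate = 50, shape = 25,
                                      duration = 30, seed = 1) {
  if (rate <= 0) stop("rate must be > 0")
  if (shape < 1) stop("shape must be >= 1")
  if (duration <= 0) stop("duration must be positive")
  stopifnot(n_axons >= 1)
  ev <- lapply(seq_len(n_axons), function(a) {
    t <- .gamma_train_cpp(rate, shape, duration, .substream(seed, 100 + a))
    if (length(t)) data.frame(time_s = t, unit_id = a) else NULL
  })
  out <- do.call(rbind, ev)
  out <- out[order(out$time_s), ]
  rownames(out) <- NULL
  class(out) <- c("spike_events", "data.frame")
  out
}

#' Step a pool of neurons under injected somatic current
#'
#' Open-loop integration of two-compartment motor neurons or point
#' interneurons, without synapses; used for rheobase, f-I and refinement
#' checks. Spikes are detected as upward threshold crossings and stamped at
#' the end of the step.
#'
#' @param pool A parameter data.frame as produced by
#'   \code{\link{neuron_pool_params}} (or the \code{neurons} element of a
#'   network restricted to some rows).
#' @param I_nA Injected somatic current: a scalar, a vector (one value per
#'   neuron), or a matrix (steps x neurons).
#' @param dt Time step (s).
#' @param duration Duration (s) when \code{I_nA} is not a matrix.
#' @return List with membrane matrix \code{V} (steps x neurons) and a
#'   \code{spikes} data.frame (time_s, unit_id).
#' @export
step_neurons <- function(pool, I_nA, dt = 5e-5, duration = 1) {
  stopifnot(is.data.frame(pool))
  n <- nrow(pool)
  if (!is.matrix(I_nA)) {
    nstep <- as.integer(round(duration / dt))
    I_nA <- matrix(rep(I_nA, length.out = n), nstep, n, byrow = TRUE)
  }
  pars <- list(n = n, Cs = pool$Cs, Cd = pool$Cd, gls = pool$gls,
               gld = pool$gld, gc = pool$gc, thr = pool$thr, gNa = pool$gNa,
               gKf = pool$gKf, gKs = pool$gKs, tau_q = pool$tau_q,
               two_comp = as.integer(pool$two_comp))
  out <- .neuron_trace_cpp(pars, I_nA, dt)
  list(V = out$V,
       spikes = data.frame(time_s = out$spike_t, unit_id = out$spike_id))
}

#' Neuron parameters for a stand-alone pool
#'
#' @param types Character vector of neuron types ("S", "FR", "FF", "IN"),
#'   one entry per neuron; consecutive entries of one type span that type's
#'   parameter band linearly.
#' @param seed Seed for the threshold jitter.
#' @param thr_jitter Relative jitter width.
#' @return Parameter data.frame accepted by \code{\link{step_neurons}}.
#' @export
neuron_pool_params <- function(types, seed = 1, thr_jitter = 0.02) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 17))
  out <- lapply(unique(types), function(ty)
    .neuron_type_params(ty, sum(types == ty), thr_jitter))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Conductance of a saturating synapse bank driven by a spike train
#'
#' All synapses of one class on one target share two-state kinetics; each
#' presynaptic spike opens a fixed-duration transmitter pulse on every
#' connected synapse and the bank saturates at the class's maximum
#' conductance.
#'
#' @param spike_times Presynaptic spike times (s), all >= 0.
#' @param n_syn Number of synapses in the bank.
#' @param g_max_nS Saturated bank conductance (nS).
#' @param kinetics "exc" or "inh".
#' @param dt Step (s).
#' @param duration Trace duration (s).
#' @return Conductance time series in nS.
#' @export
synaptic_conductance <- function(spike_times, n_syn = 1, g_max_nS = 600,
                                 kinetics = c("exc", "inh"),
                                 dt = 5e-5, duration = 0.2) {
  kinetics <- match.arg(kinetics)
  if (any(spike_times < 0)) stop("presynaptic event earlier than current time")
  kk <- .SYN_KINETICS[[kinetics]]
  g <- .synapse_trace_cpp(spike_times, as.integer(n_syn), g_max_nS / n_syn,
                          kk$alpha, kk$beta, kk$Tdur_ms, dt, duration)
  g
}
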