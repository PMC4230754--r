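# Parameter tables: printed musculoskeletal/afferent constants plus the
# versioned neuron/curve/spindle parameter sets used by the simulator.

.param_env <- new.env(parent = emptyenv())

.read_param_csv <- function(name) {
  key <- paste0("csv_", name)
  if (!is.null(.param_env[[key]])) return(.param_env[[key]])
  path <- system.file("extdata", paste0(name, ".csv"), package = "nmstand")
  if (!nzchar(path)) stop("parameter file not found: ", name)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .param_env[[key]] <- x
  x
}

#' Muscles represented in the model
#'
#' The plantar flexors of the triceps surae group (soleus SO, medial and
#' lateral gastrocnemius MG/LG) and the dorsiflexor tibialis anterior (TA).
#' @return Character vector of muscle codes in canonical order.
#' @export
muscle_names <- function() c("SO", "MG", "LG", "TA")

#' Triceps surae muscle codes
#' @return Character vector \code{c("SO","MG","LG")}.
#' @export
ts_muscles <- function() c("SO", "MG", "LG")

#' Musculotendon parameters
#'
#' Hill-model constants per muscle: maximum isometric force \code{F0_N},
#' optimal fibre length \code{L0_cm}, fibre mass \code{mass_kg}, parallel
#' elastic shape \code{k_pe} and strain \code{strain}, viscosity \code{b_pe}
#' (F0 per L0/s), initial pinnation \code{alpha0_deg}, tendon normalising
#' length \code{Lt1_cm} (length at which tendon force equals F0), tendon toe
#' curvature \code{c_t}, linear stiffness \code{k_t} (F0 per normalised
#' length) and toe-linear transition \code{L_r}.
#'
#' @param muscle Optional muscle code ("SO", "MG", "LG", "TA").
#' @return A data.frame (all muscles) or a one-row list for one muscle.
#' @export
mtu_params <- function(muscle = NULL) {
  tab <- .read_param_csv("mtu_params")
  if (is.null(muscle)) return(tab)
  row <- tab[tab$muscle == muscle, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown muscle: ", muscle)
  as.list(row)
}

#' Ankle kinematics polynomials
#'
#' Quartic polynomial coefficients relating musculotendon length (cm) and
#' moment arm (cm) to the ankle angle in degrees (dorsiflexion/forward lean
#' positive). Gastrocnemii coefficients are for a fully extended knee.
#'
#' @param muscle Optional muscle code.
#' @return Data.frame of coefficients, or a list with \code{a} (length) and
#'   \code{b} (moment arm) coefficient vectors for one muscle.
#' @export
kinematics_poly <- function(muscle = NULL) {
  tab <- .read_param_csv("kinematics_poly")
  if (is.null(muscle)) return(tab)
  row <- tab[tab$muscle == muscle, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown muscle: ", muscle)
  list(a = as.numeric(row[paste0("a", 0:4)]), b = as.numeric(row[paste0("b", 0:4)]))
}

#' Motor-nucleus composition
#'
#' Number of S, FR and FF motor neurons per motor nucleus at full scale.
#' @param scale Pool scale factor in (0, 1]; counts are rounded, preserving
#'   the type proportions.
#' @return Data.frame with columns muscle, n_S, n_FR, n_FF.
#' @export
pool_composition <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0, scale <= 1)
  tab <- .read_param_csv("pool_composition")
  if (scale != 1) {
    for (cl in c("n_S", "n_FR", "n_FF")) tab[[cl]] <- as.integer(round(tab[[cl]] * scale))
    if (any(rowSums(tab[, c("n_S", "n_FR", "n_FF")]) == 0L))
      stop("scale produces an empty motor nucleus")
  }
  tab
}

#' Afferent fibre counts
#'
#' Number of Ia, II and Ib afferents per muscle at full scale.
#' @inheritParams pool_composition
#' @return Data.frame with columns muscle, n_Ia, n_II, n_Ib.
#' @export
afferent_counts <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0, scale <= 1)
  tab <- .read_param_csv("afferent_counts")
  if (scale != 1) {
    for (cl in c("n_Ia", "n_II", "n_Ib")) tab[[cl]] <- pmax(1L, as.integer(round(tab[[cl]] * scale)))
  }
  tab
}

#' Sensory feedback constants
#'
#' Afferent conduction velocity ranges, afferent/interneuron connectivity
#' fractions and maximum (bank) synaptic conductances.
#' @return Named list of values; ranges are length-2 numeric vectors.
#' @export
sensory_params <- function() {
  tab <- .read_param_csv("sensory_params")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    lo <- tab$value_lo[i]; hi <- tab$value_hi[i]
    if (lo == hi) lo else c(lo, hi)
  })
  names(out) <- tab$parameter
  out
}

#' Neuron electrical parameter table
#'
#' Per-type ranges (varying linearly across each pool) for input resistance,
#' membrane time constant, voltage threshold (depolarisation from rest),
#' afterhyperpolarisation decay time and motor axon conduction velocity.
#' Membrane potentials are expressed relative to rest (0 mV).
#' @return Data.frame, one row per neuron type (S, FR, FF, IN).
#' @export
neuron_param_table <- function() .read_param_csv("neuron_params")

#' Force-length / force-velocity curve constants
#'
#' Constants of the contractile-element force-length and force-velocity
#' relations for slow (type-I) and fast (type-II) muscle fibres.
#' @return Data.frame with one row per fibre type.
#' @export
flfv_params <- function() .read_param_csv("flfv_params")

#' Muscle spindle intrafusal fibre constants
#'
#' Mechanical and fusimotor constants of the bag1, bag2 and chain intrafusal
#' fibres. The three afferent-potential gains (\code{G_pri}) are scaled at run
#' time by the configurable spindle gain multipliers.
#' @return Data.frame with one column per intrafusal fibre.
#' @export
spindle_param_table <- function() .read_param_csv("spindle_params")

#' Motor-unit activation parameter ranges
#'
#' Per-type ranges for the contraction time of the critically damped
#' activation filter, the tetanic firing rate at which the saturated
#' activation plateaus, and the EMG waveform time scale.
#' @return Data.frame, one row per motor-unit type.
#' @export
mu_activation_table <- function() .read_param_csv("mu_activation")

#' Body (inverted pendulum) parameters
#'
#' @param m Body mass excluding the feet (kg).
#' @param h Height of the centre of mass above the ankle (m).
#' @param g Gravitational acceleration (m/s^2).
#' @param K_frac Added passive ankle stiffness as a fraction of the critical
#'   stiffness m*g*h.
#' @param B_pas Passive ankle viscosity (Nm s/rad).
#' @return An object of class \code{body_params}.
#' @export
body_params <- function(m = 60, h = 0.85, g = 9.81, K_frac = 0.65, B_pas = 5.81) {
  stopifnot(m > 0, h > 0, g > 0, K_frac >= 0, B_pas >= 0)
  out <- list(m = m, h = h, g = g, I = m * h^2,
              K_frac = K_frac, K_pas = K_frac * m * g * h, B_pas = B_pas)
  class(out) <- "body_params"
  out
}

#' Critical (load) stiffness of the inverted pendulum
#'
#' The gravitational load stiffness m*g*h that total ankle stiffness must
#' exceed for passive stability.
#' @param params A \code{\link{body_params}} object.
#' @return Stiffness in Nm/rad.
#' @export
critical_stiffness <- function(params = body_params()) params$m * params$g * params$h

#' Serialise a parameter table to a config file and read it back
#'
#' Plain-text (CSV) round-trip used to persist parameter sets alongside
#' simulation outputs. Values are written with full precision.
#' @param tab A data.frame.
#' @param path File path.
#' @return \code{write_config} returns \code{path} invisibly;
#'   \code{read_config} returns the data.frame.
#' @export
write_config <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  x
}
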