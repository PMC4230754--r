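# Spike-event, manifest and time-series I/O (plain-text formats).

#' Write / read spike event lists
#'
#' Two-column CSV (time_s, unit_id), time-sorted.
#' @param events \code{spike_events} data.frame.
#' @param path File path.
#' @return \code{read_spike_events} returns a \code{spike_events}
#'   data.frame; \code{write_spike_events} returns \code{path} invisibly.
#' @export
write_spike_events <- function(events, path) {
  ev <- events[order(events$time_s), c("time_s", "unit_id")]
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  ev <- utils::read.csv(path)
  if (!all(c("time_s", "unit_id") %in% names(ev)))
    stop("not a spike event file (need time_s, unit_id)")
  class(ev) <- c("spike_events", "data.frame")
  ev
}

#' Population manifest of a network
#'
#' One row per unit mapping unit ids to population, muscle and type, for the
#' neuronal and afferent event lists.
#' @param net \code{\link{build_network}} result.
#' @return List of two data.frames: \code{neurons}, \code{afferents}.
#' @export
population_manifest <- function(net) {
  stopifnot(inherits(net, "spinal_network"))
  nn <- net$neurons
  af <- net$afferents
  list(
    neurons = data.frame(unit_id = nn$id, population = nn$population,
                         muscle = nn$muscle, type = nn$type),
    afferents = data.frame(unit_id = af$id, muscle = af$muscle,
                           afferent_type = af$type, velocity = af$velocity,
                           threshold = af$thr))
}

#' Export simulation time series
#'
#' Columnar CSV of the pendulum and per-muscle records at a configurable
#' decimation; units are documented in a comment header.
#' @param result \code{\link{run_simulation}} result.
#' @param path File path.
#' @param every Keep every \code{every}-th sample.
#' @return \code{path}, invisibly.
#' @export
export_series <- function(result, path, every = 1L) {
  ser <- result$series[seq(1, nrow(result$series), by = every), ]
  for (m in names(result$muscles)) {
    mm <- result$muscles[[m]][seq(1, nrow(result$muscles[[m]]), by = every), ]
    ser[[paste0("L_f_", m)]] <- mm$L_f
    ser[[paste0("F_tendon_", m)]] <- mm$F_tendon
    ser[[paste0("emg_", m)]] <- mm$emg
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# t: s; theta: rad; omega: rad/s; T_muscles, T_a: Nm",
               "# x_com, x_cop: m; L_f: L0 units; F_tendon: N; emg: a.u."), con)
  utils::write.csv(ser, con, row.names = FALSE)
  invisible(path)
}
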