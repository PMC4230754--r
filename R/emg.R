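# Phenomenological surface EMG: Hermite-Rodriguez motor-unit action
# potentials superposed at conducted spike times, and the envelope
# processing used in the sway analyses.

#' Motor-unit action potential templates
#'
#' First-order Hermite-Rodriguez waveforms, amplitude ordered by motor-unit
#' size (tetanic amplitude) and time scale by type.
#'
#' @param channels \code{\link{mu_activation_channels}} result (provides
#'   amplitudes and time scales).
#' @return Data.frame with one row per unit: amplitude and lambda_ms.
#' @export
muap_templates <- function(channels) {
  data.frame(unit_id = seq_len(nrow(channels)),
             amplitude = channels$emg_amp,
             lambda_ms = channels$emg_lambda_ms)
}

.hr1 <- function(x) x * exp(-x^2)

#' Synthesise a surface EMG from spike trains
#'
#' Linear superposition of per-unit action-potential templates at the spike
#' times, plus optional additive Gaussian measurement noise.
#'
#' @param spikes \code{spike_events} data.frame (time_s, unit_id).
#' @param templates \code{\link{muap_templates}} result.
#' @param fs Sampling rate (Hz, >= 2000).
#' @param duration Record duration (s).
#' @param noise_sd Measurement noise standard deviation (same units as the
#'   template amplitudes; default none).
#' @param seed Seed for the noise.
#' @return Numeric EMG series of length \code{duration * fs}.
#' @export
synthesize_emg <- function(spikes, templates, fs = 2000, duration = 1,
                           noise_sd = 0, seed = 1) {
  if (fs < 2000) stop("fs must be >= 2 kHz")
  if (nrow(spikes) && (any(spikes$unit_id < 1) || any(spikes$unit_id > nrow(templates))))
    stop("spike unit id without a template")
  n <- as.integer(round(duration * fs))
  emg <- numeric(n)
  for (k in seq_len(nrow(spikes))) {
    u <- spikes$unit_id[k]
    lam <- templates$lambda_ms[u] / 1000
    A <- templates$amplitude[u]
    i0 <- floor(spikes$time_s[k] * fs) + 1L
    ns <- ceiling(3 * lam * fs)
    idx <- i0:min(n, i0 + ns)
    idx <- idx[idx >= 1L]
    if (!length(idx)) next
    x <- ((idx - i0) / fs) / lam
    emg[idx] <- emg[idx] + A * .hr1(x)
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(.substream(seed, 37))
    emg <- emg + stats::rnorm(n, 0, noise_sd)
  }
  emg
}

#' EMG envelope
#'
#' Downsample to 2 kHz, full-wave rectify, and low-pass filter at 2 Hz with
#' a zero-phase fourth-order Butterworth filter.
#'
#' @param emg EMG series.
#' @param fs Sampling rate of \code{emg} (Hz).
#' @param fc Low-pass cutoff (Hz).
#' @param fs_out Rate after downsampling (Hz).
#' @return Envelope series at \code{fs_out}.
#' @export
emg_envelope <- function(emg, fs = 2000, fc = 2, fs_out = 2000) {
  if (fs > fs_out) {
    if (fs %% fs_out != 0) stop("fs must be a multiple of fs_out")
    emg <- emg[seq(1, length(emg), by = fs %/% fs_out)]
  }
  if (length(emg) < 4 * fs_out / fc) stop("record too short for the envelope filter")
  bf <- signal::butter(4, fc / (fs_out / 2), type = "low")
  as.numeric(signal::filtfilt(bf, abs(emg)))
}
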