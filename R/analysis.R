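# Posturography and motor-unit analysis battery.

#' Preprocess a sway time series
#'
#' Trims the first 5 s and last 2.5 s (transients and filter edges), removes
#' a linear trend and resamples to the analysis rate.
#'
#' @param x Numeric series.
#' @param fs Input sampling rate (Hz).
#' @param fs_out Output rate (Hz, default 2000).
#' @param head_s,tail_s Seconds removed from the head and tail.
#' @param detrend Remove a linear trend (default TRUE).
#' @return Numeric series at \code{fs_out}.
#' @export
preprocess_series <- function(x, fs, fs_out = 2000, head_s = 5, tail_s = 2.5,
                              detrend = TRUE) {
  n <- length(x)
  if (n / fs <= head_s + tail_s) stop("record too short")
  keep <- seq.int(floor(head_s * fs) + 1L, n - floor(tail_s * fs))
  x <- x[keep]
  if (detrend) {
    t <- seq_along(x)
    x <- stats::residuals(stats::lm.fit(cbind(1, t), x))
  }
  if (fs_out != fs) {
    if (fs %% fs_out == 0) {
      x <- x[seq(1, length(x), by = fs %/% fs_out)]
    } else {
      t_in <- (seq_along(x) - 1) / fs
      t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
      x <- stats::approx(t_in, x, xout = t_out)$y
    }
  }
  as.numeric(x)
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with 50 percent overlap.
#'
#' @param x Numeric series (mean removed internally).
#' @param fs Sampling rate (Hz).
#' @param nseg Segment length in samples (default: a quarter of the record).
#' @return Data.frame (freq, pxx) with one-sided density.
#' @export
welch_psd <- function(x, fs, nseg = NULL) {
  w <- .welch_engine(x, NULL, fs, nseg)
  data.frame(freq = w$freq, pxx = w$pxx)
}

#' Welch cross-spectral density
#'
#' @param x,y Equal-length numeric series.
#' @inheritParams welch_psd
#' @return List with \code{freq}, \code{pxx} (PSD of x) and complex
#'   \code{cross} (cross-spectrum of x and y).
#' @export
welch_csd <- function(x, y, fs, nseg = NULL) .welch_engine(x, y, fs, nseg)

.welch_engine <- function(x, y, fs, nseg = NULL) {
  n <- length(x)
  if (!is.null(y) && length(y) != n) stop("series lengths differ")
  if (is.null(nseg)) nseg <- max(8L, 2L^floor(log2(n / 4)))
  nseg <- min(nseg, n)
  step <- max(1L, nseg %/% 2L)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  U <- sum(win^2)
  starts <- seq(1L, n - nseg + 1L, by = step)
  nf <- nseg %/% 2L + 1L
  pxx <- numeric(nf); cxy <- complex(nf)
  for (s in starts) {
    seg_x <- x[s:(s + nseg - 1L)]; seg_x <- (seg_x - mean(seg_x)) * win
    X <- stats::fft(seg_x)[seq_len(nf)]
    pxx <- pxx + Mod(X)^2
    if (!is.null(y)) {
      seg_y <- y[s:(s + nseg - 1L)]; seg_y <- (seg_y - mean(seg_y)) * win
      Y <- stats::fft(seg_y)[seq_len(nf)]
      cxy <- cxy + Conj(X) * Y
    }
  }
  k <- length(starts)
  scale <- 1 / (k * U * fs)
  pxx <- pxx * scale * c(1, rep(2, nf - 2L), 1)
  out <- list(freq = (seq_len(nf) - 1) * fs / nseg, pxx = pxx)
  if (!is.null(y)) out$cross <- cxy * scale * c(1, rep(2, nf - 2L), 1)
  out
}

#' Centre-of-pressure metrics
#'
#' RMS of the (detrended) displacement, mean velocity (mean absolute first
#' difference over time) and the 50 percent power frequency F50 (frequency
#' below which half of the Welch spectral power lies, linearly interpolated
#' on the cumulative spectrum).
#'
#' @param cop Preprocessed COP series (consistent units, e.g. mm).
#' @param fs Sampling rate (Hz).
#' @param nseg Welch segment length.
#' @return List with \code{rms}, \code{mv} (units/s) and \code{f50} (Hz).
#' @export
cop_metrics <- function(cop, fs = 2000, nseg = NULL) {
  rms <- sqrt(mean(cop^2))
  mv <- mean(abs(diff(cop))) * fs
  sp <- welch_psd(cop, fs, nseg)
  pw <- sp$pxx; pw[1] <- 0                  # exclude DC
  cum <- cumsum(pw)
  tot <- cum[length(cum)]
  i <- which(cum >= tot / 2)[1]
  f50 <- if (i <= 1) sp$freq[1] else {
    p0 <- cum[i - 1]; p1 <- cum[i]
    sp$freq[i - 1] + (sp$freq[i] - sp$freq[i - 1]) * (tot / 2 - p0) / (p1 - p0)
  }
  list(rms = rms, mv = mv, f50 = f50)
}

#' Cross-correlation peak
#'
#' Normalised cross-correlation between two equal-length series; returns the
#' global peak and its signed lag. A positive lag means \code{x} leads
#' \code{y} (the peak occurs with y delayed relative to x).
#'
#' @param x,y Numeric series.
#' @param fs Sampling rate (Hz).
#' @param max_lag_s Maximum lag searched (s).
#' @return List with \code{rho} and \code{lag_s}.
#' @export
xcorr_peak <- function(x, y, fs = 2000, max_lag_s = 2) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  n <- length(x)
  stopifnot(length(y) == n)
  L <- min(n - 1L, as.integer(round(max_lag_s * fs)))
  x <- x - mean(x); y <- y - mean(y)
  nf <- stats::nextn(2L * n)
  X <- stats::fft(c(x, numeric(nf - n)))
  Y <- stats::fft(c(y, numeric(nf - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nf
  # cc[1 + k] = sum x[t] y[t + k]; negative k wraps at the end
  lags <- c(0:L, -(L:1))
  vals <- cc[c(seq_len(L + 1L), nf - (L:1) + 1L)]
  sx <- sqrt(sum(x^2) / n); sy <- sqrt(sum(y^2) / n)
  rho <- vals / (n * sx * sy) * n / (n - abs(lags))
  i <- which.max(abs(rho))
  # lag k means y shifted k samples later matches x[t] y[t+k]: x leads by k
  list(rho = rho[i], lag_s = lags[i] / fs)
}

#' Motor-unit activation ratio
#'
#' Fraction of the record during which a motor unit's interspike intervals
#' are shorter than 250 ms; 0 for an inactive unit, 1 for continuous
#' activity, low values for intermittent units.
#'
#' @param spike_times Spike times (s) of one unit.
#' @param span Length-2 record span (s).
#' @param isi_max ISI threshold (s).
#' @return Ratio in [0, 1].
#' @export
activation_ratio <- function(spike_times, span, isi_max = 0.25) {
  st <- sort(spike_times[spike_times >= span[1] & spike_times <= span[2]])
  if (length(st) < 2L) return(0)
  isi <- diff(st)
  sum(isi[isi < isi_max]) / (span[2] - span[1])
}

#' Inter-recruitment intervals of an intermittently recruited unit
#'
#' Interspike intervals longer than 250 ms (discharge rate below 4 Hz) are
#' taken as intervals between successive recruitments.
#'
#' @param spike_times Sorted spike times (s).
#' @param isi_min Threshold (s).
#' @param mode_bin Bin width (s) used for the modal interval.
#' @return List with \code{intervals} (s), \code{mean_s} and \code{mode_s}
#'   (NA when no interval qualifies).
#' @export
inter_recruitment_intervals <- function(spike_times, isi_min = 0.25,
                                        mode_bin = 0.05) {
  st <- sort(spike_times)
  iv <- diff(st)
  iv <- iv[iv > isi_min]
  if (!length(iv)) return(list(intervals = numeric(0), mean_s = NA_real_,
                               mode_s = NA_real_))
  bins <- floor(iv / mode_bin)
  md <- as.integer(names(which.max(table(bins))))
  list(intervals = iv, mean_s = mean(iv), mode_s = (md + 0.5) * mode_bin)
}

#' Recruitment phase plot
#'
#' Bins joint angle, angular velocity, torque and spike trains into 100-ms
#' windows; counts the motor units recruited (first spike after a silence
#' longer than the recruitment threshold) in each window, positioned at the
#' window's mean-subtracted (angle, velocity) and (angle, torque)
#' coordinates, and reports quadrant occupancy fractions.
#'
#' @param spikes \code{spike_events} data.frame (time_s, unit_id).
#' @param theta,omega,torque Aligned series.
#' @param fs Sampling rate of the series (Hz).
#' @param win_s Window (s).
#' @param silence_s Minimum preceding silence defining a recruitment event.
#' @return List with the per-window data.frame (\code{windows}) and quadrant
#'   fractions for the angle-velocity and angle-torque planes.
#' @export
recruitment_phase_plot <- function(spikes, theta, omega, torque, fs = 2000,
                                   win_s = 0.1, silence_s = 0.25) {
  n <- length(theta)
  dur <- n / fs
  nwin <- floor(dur / win_s)
  counts <- integer(nwin)
  if (nrow(spikes)) {
    for (u in unique(spikes$unit_id)) {
      st <- sort(spikes$time_s[spikes$unit_id == u])
      rec <- st[c(TRUE, diff(st) > silence_s)]
      w <- floor(rec / win_s) + 1L
      w <- w[w >= 1L & w <= nwin]
      counts[unique(w)] <- counts[unique(w)] + 1L
    }
  }
  wmean <- function(x) {
    idx <- pmin(n, floor((seq_len(nwin) - 0.5) * win_s * fs) + 1L)
    x[idx]
  }
  th <- wmean(theta) - mean(theta)
  om <- wmean(omega) - mean(omega)
  tq <- wmean(torque) - mean(torque)
  wins <- data.frame(window = seq_len(nwin), theta = th, omega = om,
                     torque = tq, n_recruited = counts)
  qfrac <- function(a, b) {
    tot <- sum(counts)
    if (tot == 0) return(rep(0, 4))
    c(q1 = sum(counts[a > 0 & b > 0]), q2 = sum(counts[a <= 0 & b > 0]),
      q3 = sum(counts[a <= 0 & b <= 0]), q4 = sum(counts[a > 0 & b <= 0])) / tot
  }
  list(windows = wins,
       quad_angle_velocity = qfrac(th, om),
       quad_angle_torque = qfrac(th, tq))
}

#' Windowed fibre-length / sway correlation
#'
#' Pearson correlation between COM displacement and muscle fibre length in
#' non-overlapping 3-s windows; windows with positive coefficients reflect
#' "orthodox" behaviour, negative ones the "paradoxical" shortening of a
#' plantar flexor during forward sway.
#'
#' @param com COM series.
#' @param fibre_length Aligned fibre-length series.
#' @param fs Sampling rate (Hz).
#' @param win_s Window (s).
#' @return List with per-window \code{rho}, counts \code{n_pos}/\code{n_neg}
#'   and the number of skipped zero-variance windows.
#' @export
windowed_length_correlation <- function(com, fibre_length, fs = 2000, win_s = 3) {
  n <- min(length(com), length(fibre_length))
  nwin <- floor(n / (win_s * fs))
  rho <- rep(NA_real_, nwin)
  skipped <- 0L
  for (w in seq_len(nwin)) {
    idx <- ((w - 1L) * win_s * fs + 1L):(w * win_s * fs)
    a <- com[idx]; b <- fibre_length[idx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) { skipped <- skipped + 1L; next }
    rho[w] <- stats::cor(a, b)
  }
  ok <- !is.na(rho)
  list(rho = rho, n_pos = sum(rho[ok] > 0), n_neg = sum(rho[ok] <= 0),
       skipped = skipped)
}

#' Compare window-sign counts between two runs
#'
#' Chi-square test on the 2x2 table of positive/negative window counts.
#' @param counts1,counts2 Length-2 vectors c(n_pos, n_neg).
#' @return \code{htest} object.
#' @export
window_sign_test <- function(counts1, counts2) {
  stats::chisq.test(rbind(counts1, counts2), correct = FALSE)
}

#' Jarque-Bera normality test
#'
#' Moment-based goodness-of-fit statistic n/6 (S^2 + (K-3)^2/4) with an
#' asymptotic chi-square(2) null distribution.
#'
#' @param x Numeric sample.
#' @return List with \code{statistic}, \code{p_value}, \code{skewness},
#'   \code{kurtosis}.
#' @export
jarque_bera_test <- function(x) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- mean(z^2); m3 <- mean(z^3); m4 <- mean(z^4)
  S <- m3 / m2^1.5; K <- m4 / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K)
}

#' Pooled COM histogram and bimodality test
#'
#' Mean-subtracts each run's COM record, pools the samples, histograms them
#' in 1-mm bins and applies the Jarque-Bera test of the unimodal-Gaussian
#' null.
#'
#' @param com_runs List of COM series (m).
#' @param bin_mm Bin width (mm).
#' @return List with the histogram, the pooled samples (mm) and the test.
#' @export
com_bimodality <- function(com_runs, bin_mm = 1) {
  stopifnot(length(com_runs) >= 2L)
  pooled <- unlist(lapply(com_runs, function(x) (x - mean(x)) * 1000))
  rng <- range(pooled)
  breaks <- seq(floor(rng[1]), ceiling(rng[2]) + bin_mm, by = bin_mm)
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  list(histogram = h, pooled_mm = pooled, test = jarque_bera_test(pooled))
}

#' Full sway-metric battery for a simulation result
#'
#' Preprocesses the sway records and computes the COP metrics, COM-COP and
#' COP-EMG cross-correlations, per-unit activation ratios and intermittency
#' intervals of the requested motor nuclei.
#'
#' @param result A \code{\link{run_simulation}} result.
#' @param muscles Muscles for the EMG correlation and motor-unit metrics.
#' @param n_units Units sampled per muscle for activation ratios.
#' @param seed Seed for unit sampling.
#' @return List of metric components.
#' @export
sway_metrics <- function(result, muscles = c("SO", "MG", "LG"), n_units = 30,
                         seed = 1) {
  fs <- result$fs
  span <- c(5, max(result$series$t) - 2.5)
  cop <- preprocess_series(result$series$x_cop * 1000, fs, fs)
  com <- preprocess_series(result$series$x_com * 1000, fs, fs)
  cm <- cop_metrics(cop, fs)
  cc <- xcorr_peak(com, cop, fs)
  emg_cc <- lapply(muscles, function(m) {
    env <- emg_envelope(result$muscles[[m]]$emg, fs)
    env <- preprocess_series(env, fs, fs)
    if (stats::sd(env) == 0) return(list(rho = NA_real_, lag_s = NA_real_))
    xcorr_peak(env, cop, fs)     # positive lag: EMG leads COP
  })
  names(emg_cc) <- muscles
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.substream(seed, 31))
  mu <- lapply(muscles, function(m) {
    ids <- .mn_ids(result, m)
    sp <- result$spikes
    active <- intersect(ids, unique(sp$unit_id[sp$time_s >= span[1] & sp$time_s <= span[2]]))
    pick <- if (length(active) > n_units) sort(sample(active, n_units)) else active
    ar <- vapply(pick, function(u)
      activation_ratio(sp$time_s[sp$unit_id == u], span), numeric(1))
    iv <- unlist(lapply(pick, function(u) {
      st <- sp$time_s[sp$unit_id == u]
      inter_recruitment_intervals(st[st >= span[1] & st <= span[2]])$intervals
    }))
    list(units = pick, activation_ratio = ar, intervals = iv)
  })
  names(mu) <- muscles
  list(cop = cm, com_cop = cc, cop_emg = emg_cc, motor_units = mu)
}

.mn_ids <- function(result, muscle) {
  nn <- result$network$neurons
  nn$id[nn$is_mn == 1L & !is.na(nn$muscle) & nn$muscle == muscle]
}
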