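# Synthetic composite LFP: 1/f background, movement-locked asymmetric theta,
# stillness-locked delta, injected ripple bursts, optional line noise.

# 1/f^alpha (power) background noise via spectral shaping, scaled to target SD
colored_noise <- function(n, fs, alpha = 2, sd_target = 30) {
  m <- stats::nextn(n, c(2L, 3L, 5L))            # keep the FFT fast
  w <- stats::rnorm(m)
  X <- stats::fft(w)
  f <- seq(0, fs, length.out = m + 1L)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]            # mirror for negative freqs
  shape <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(stats::fft(X * shape, inverse = TRUE) / m)[seq_len(n)]
  x * sd_target / stats::sd(x)
}

# theta waveform from a cycle schedule: cos(phase) with phase 0 at peaks,
# pi at troughs, linear within each half cycle; zero outside the schedule
theta_waveform <- function(t, schedule) {
  if (nrow(schedule) == 0L) return(numeric(length(t)))
  base <- 2 * pi * (seq_len(nrow(schedule)) - 1L)
  knot_t <- as.numeric(rbind(schedule$t_peak, schedule$t_trough,
                             schedule$t_next_peak))
  knot_p <- as.numeric(rbind(base, base + pi, base + 2 * pi))
  # contiguous cycles duplicate the shared peak knot (equal phase): drop dupes
  keep <- !duplicated(knot_t)
  ph <- stats::approx(knot_t[keep], knot_p[keep], xout = t, rule = 2)$y
  w <- cos(ph)
  w[!in_intervals(t, data.frame(t_start = schedule$t_peak,
                                t_end = schedule$t_next_peak))] <- 0
  w
}

#' Generate a multichannel synthetic LFP
#'
#' Composes, per channel: a 1/f aperiodic background; movement-locked theta
#' whose ascending and descending half-cycle durations follow the supplied
#' cycle schedule; stillness-locked 1-4 Hz activity (LIA); and 150-250 Hz
#' ripple bursts injected into the given windows, strongest on one designated
#' channel.  Ripple amplitude is calibrated so the burst envelope peaks at
#' `ripple_amp_sd` standard deviations of the background ripple-band
#' envelope.
#'
#' @param movement Intervals data.frame of movement epochs.
#' @param duration Session duration in seconds.
#' @param theta A [generate_theta_schedule()] cycle schedule.
#' @param swr_windows Data.frame (`t_start`, `t_end`) of ripple injection
#'   windows (in stillness), or NULL.
#' @param fs Sampling rate in Hz (must be >= 600 to represent the ripple
#'   band).
#' @param n_channels Number of channels (default 4).
#' @param ripple_channel Index of the designated high-ripple channel
#'   (default 2).
#' @param theta_amp,delta_amp,noise_amp Component amplitudes in microvolts.
#' @param ripple_freq Ripple carrier frequency in Hz (default 180).
#' @param ripple_amp_sd Ripple envelope peak in background-envelope SDs
#'   (default 6).
#' @param line_amp 60 Hz line-noise amplitude in microvolts (default 5).
#' @param seed Integer seed.
#' @return An [lfp_signal()].
#' @export
generate_lfp <- function(movement, duration, theta, swr_windows = NULL,
                         fs = 1250, n_channels = 4L, ripple_channel = 2L,
                         theta_amp = 150, delta_amp = 120, noise_amp = 30,
                         ripple_freq = 180, ripple_amp_sd = 6, line_amp = 5,
                         seed = 1L) {
  if (fs < 600) {
    stop("sampling rate must be >= 600 Hz to represent the 150-250 Hz band")
  }
  n <- floor(duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  still <- !in_intervals(t, movement)

  with_seed(seed, {
    theta_w <- theta_waveform(t, theta)
    # stillness-locked delta: random 1-4 Hz tones under the stillness mask
    n_tones <- 6L
    fr <- stats::runif(n_tones, 1, 4)
    ph <- stats::runif(n_tones, 0, 2 * pi)
    am <- stats::runif(n_tones, 0.5, 1)
    delta_w <- numeric(n)
    for (j in seq_len(n_tones)) {
      delta_w <- delta_w + am[j] * sin(2 * pi * fr[j] * t + ph[j])
    }
    delta_w <- delta_w / stats::sd(delta_w)
    still_mask <- gaussian_smooth(as.numeric(still), 0.05 * fs)
    move_mask <- gaussian_smooth(as.numeric(!still), 0.05 * fs)

    samples <- matrix(0, nrow = n, ncol = n_channels)
    for (ch in seq_len(n_channels)) {
      gain <- stats::runif(1, 0.85, 1.15)
      x <- colored_noise(n, fs, alpha = 2, sd_target = noise_amp) +
        theta_amp * gain * theta_w * move_mask +
        delta_amp * gain * delta_w * still_mask
      if (line_amp > 0) x <- x + line_amp * sin(2 * pi * 60 * t)
      samples[, ch] <- x
    }

    if (!is.null(swr_windows) && nrow(swr_windows) > 0L) {
      # calibrate against the background ripple-band envelope of the
      # designated channel
      bp <- butter_bandpass(samples[, ripple_channel], fs, c(150, 250))
      env_sd <- stats::sd(Mod(analytic_signal(bp)))
      env_mean <- mean(Mod(analytic_signal(bp)))
      target <- env_mean + ripple_amp_sd * env_sd
      for (i in seq_len(nrow(swr_windows))) {
        i0 <- max(1L, floor(swr_windows$t_start[i] * fs) + 1L)
        i1 <- min(n, ceiling(swr_windows$t_end[i] * fs) + 1L)
        if (i1 <= i0) next
        seg <- i0:i1
        u <- (seg - i0) / (i1 - i0)
        env <- 0.5 - 0.5 * cos(2 * pi * u)        # raised cosine
        burst <- target * env * sin(2 * pi * ripple_freq * t[seg])
        for (ch in seq_len(n_channels)) {
          w <- if (ch == ripple_channel) 1 else 0.25
          samples[seg, ch] <- samples[seg, ch] + w * burst
        }
      }
    }
    lfp_signal(samples, fs)
  })
}

# zero-phase Butterworth bandpass (order chosen for stability at low
# normalized frequencies)
butter_bandpass <- function(x, fs, band, order = 3L) {
  ny <- fs / 2
  if (band[2] >= ny) stop("band upper edge must be below Nyquist")
  bf <- signal::butter(order, band / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# zero-phase Butterworth lowpass
butter_lowpass <- function(x, fs, cutoff, order = 3L) {
  ny <- fs / 2
  bf <- signal::butter(order, cutoff / ny, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}
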