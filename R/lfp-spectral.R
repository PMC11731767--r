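# Spectral analysis: spectrograms, Welch PSDs, band powers, robust aperiodic
# fits and cross-frequency correlation.

#' Standard frequency band definitions
#'
#' Delta 1-4 Hz, theta 6-10 Hz, beta 15-20 Hz, gamma 30-80 Hz; the ripple
#' band is 150-250 Hz for identifying individual events and a broader
#' 120-250 Hz for PSD analyses.  All overridable.
#'
#' @param delta,theta,beta,gamma,swr_event,swr_psd Numeric length-2 ranges in
#'   Hz.
#' @return A named list of class `band_definitions`.
#' @export
band_definitions <- function(delta = c(1, 4), theta = c(6, 10),
                             beta = c(15, 20), gamma = c(30, 80),
                             swr_event = c(150, 250), swr_psd = c(120, 250)) {
  structure(list(delta = delta, theta = theta, beta = beta, gamma = gamma,
                 swr_event = swr_event, swr_psd = swr_psd),
            class = "band_definitions")
}

#' Compute a spectrogram by windowed periodograms
#'
#' The signal is cut into consecutive non-overlapping bins of `bin_length`
#' seconds; each bin is Hann-windowed and its one-sided power spectral
#' density computed, scaled so that integrating the PSD over frequency
#' recovers the bin variance.
#'
#' @param lfp An [lfp_signal()] (or numeric vector with `fs` supplied).
#' @param bin_length Bin length in seconds (default 1).
#' @param channel Channel to analyze (default 1).
#' @param fs Sampling rate, required when `lfp` is a bare vector.
#' @return An object of class `spectrogram`: list with `freq`, `time` (bin
#'   centers), `power` (freq x time matrix, uV^2/Hz), `bin_length`, `fs`.
#' @export
compute_spectrogram <- function(lfp, bin_length = 1, channel = 1L,
                                fs = NULL) {
  if (inherits(lfp, "lfp_signal")) {
    x <- lfp_channel(lfp, channel)
    fs <- lfp$fs
    t0 <- lfp$t0
  } else {
    if (is.null(fs)) stop("fs must be supplied for a bare numeric signal")
    x <- as.numeric(lfp)
    t0 <- 0
  }
  L <- floor(bin_length * fs)
  if (L < 4L) stop("bin_length too short for the sampling rate")
  n_bins <- floor(length(x) / L)
  if (n_bins < 1L) stop("bin longer than the segment")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1L) / (L - 1L))  # Hann
  scale <- 2 / (fs * sum(w^2))
  n_f <- floor(L / 2) + 1L
  power <- matrix(0, nrow = n_f, ncol = n_bins)
  for (b in seq_len(n_bins)) {
    seg <- x[((b - 1L) * L + 1L):(b * L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg)[seq_len(n_f)])^2 * scale
    sp[1L] <- sp[1L] / 2
    if (L %% 2L == 0L) sp[n_f] <- sp[n_f] / 2
    power[, b] <- sp
  }
  structure(list(freq = seq(0, by = fs / L, length.out = n_f),
                 time = t0 + (seq_len(n_bins) - 0.5) * L / fs,
                 power = power, bin_length = bin_length, fs = fs),
            class = "spectrogram")
}

#' Welch power spectral density
#'
#' Averages the windowed periodograms of a spectrogram (optionally a subset
#' of its time bins).  Given an [lfp_signal()], the spectrogram is computed
#' first.
#'
#' @param x An [lfp_signal()] or a `spectrogram`.
#' @param bins Optional integer indices or logical mask selecting spectrogram
#'   time bins.
#' @param ... Passed to [compute_spectrogram()] when `x` is a signal.
#' @return A data.frame of class `psd` with columns `freq` and `power`.
#' @export
compute_psd <- function(x, bins = NULL, ...) {
  spec <- if (inherits(x, "spectrogram")) x else compute_spectrogram(x, ...)
  p <- spec$power
  if (!is.null(bins)) p <- p[, bins, drop = FALSE]
  if (ncol(p) == 0L) stop("no spectrogram bins selected")
  structure(data.frame(freq = spec$freq, power = rowMeans(p)),
            class = c("psd", "data.frame"))
}

#' Mean power within a frequency band
#'
#' @param psd A `psd` data.frame from [compute_psd()].
#' @param band Numeric length-2 range in Hz (inclusive).
#' @return Mean power across the band's frequencies.
#' @export
band_power <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("band outside PSD support")
  mean(psd$power[sel])
}

#' Remove the aperiodic (1/f) component from a PSD by robust regression
#'
#' Fits a robust linear regression to the log-log PSD within `fit_band` and
#' returns the residual power (observed minus fitted), which isolates
#' oscillatory power such as the ripple band from the broadband background.
#'
#' @param psd A `psd` data.frame.
#' @param fit_band Frequency range (Hz) of the fit (default 80-400).
#' @return A `psd` data.frame restricted to `fit_band` whose `power` column
#'   is the residual; attributes `slope` and `intercept` carry the log-log
#'   fit.
#' @export
fit_aperiodic_residual <- function(psd, fit_band = c(80, 400)) {
  sel <- psd$freq >= fit_band[1] & psd$freq <= fit_band[2] &
    psd$freq > 0 & psd$power > 0
  if (sum(sel) < 10L) stop("fewer than 10 PSD points in the fit band")
  lf <- log10(psd$freq[sel])
  lp <- log10(psd$power[sel])
  fit <- MASS::rlm(lp ~ lf, maxit = 100)
  fitted_power <- 10^stats::fitted(fit)
  out <- data.frame(freq = psd$freq[sel],
                    power = psd$power[sel] - fitted_power)
  attr(out, "slope") <- unname(stats::coef(fit)[2L])
  attr(out, "intercept") <- unname(stats::coef(fit)[1L])
  class(out) <- c("psd", "data.frame")
  out
}

#' Cross-frequency power correlation
#'
#' Correlates log power across spectrogram time bins for every pair of
#' frequencies.  A block of high correlation spanning 150-250 Hz is the
#' signature of sharp-wave ripples.
#'
#' @param spec A `spectrogram`.
#' @param log_power Correlate log10 power (default TRUE; variance
#'   stabilizing).
#' @return A symmetric frequency-by-frequency correlation matrix with unit
#'   diagonal; rows with constant power are `NA` off the diagonal.
#' @export
crossfreq_correlation <- function(spec, log_power = TRUE) {
  if (ncol(spec$power) < 30L) stop("need at least 30 time bins")
  p <- t(spec$power)
  if (log_power) p <- log10(p + .Machine$double.eps)
  sds <- apply(p, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(p))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- 1
  dimnames(cc) <- list(spec$freq, spec$freq)
  cc
}

#' @export
plot.psd <- function(x, log = "xy", ...) {
  sel <- x$freq > 0 & x$power > 0
  graphics::plot(x$freq[sel], x$power[sel], type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "power (uV^2/Hz)", ...)
  invisible(x)
}
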