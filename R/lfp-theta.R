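# Theta/LIA state classification and cycle-by-cycle theta segmentation.

#' Classify hippocampal LFP state (theta vs LIA) per time bin
#'
#' Computes the log ratio of theta to delta band power per spectrogram bin,
#' z-normalizes it over the session, and labels a bin `theta` when the
#' normalized ratio is at or above `threshold` (default 0.5); otherwise the
#' bin is large-amplitude irregular activity (`lia`).
#'
#' @param x An [lfp_signal()] or a `spectrogram`.
#' @param bands A [band_definitions()].
#' @param threshold Normalized log-ratio threshold (default 0.5).
#' @param bin_length Spectrogram bin length in seconds when `x` is a signal.
#' @param channel Channel used when `x` is a signal.
#' @return A data.frame of class `state_series` with `time`, `ratio`
#'   (normalized log theta/delta) and `state` (`"theta"`/`"lia"`); the bin
#'   length is carried as attribute `bin_length`.
#' @export
classify_state <- function(x, bands = band_definitions(), threshold = 0.5,
                           bin_length = 1, channel = 1L) {
  spec <- if (inherits(x, "spectrogram")) x else
    compute_spectrogram(x, bin_length = bin_length, channel = channel)
  th_sel <- spec$freq >= bands$theta[1] & spec$freq <= bands$theta[2]
  de_sel <- spec$freq >= bands$delta[1] & spec$freq <= bands$delta[2]
  if (!any(th_sel) || !any(de_sel)) {
    stop("spectrogram resolution too coarse for the theta/delta bands")
  }
  th <- colMeans(spec$power[th_sel, , drop = FALSE])
  de <- colMeans(spec$power[de_sel, , drop = FALSE])
  r <- log(pmax(th, .Machine$double.xmin) / pmax(de, .Machine$double.xmin))
  sdr <- stats::sd(r)
  z <- if (is.finite(sdr) && sdr > 0) (r - mean(r)) / sdr else r * 0
  out <- data.frame(time = spec$time, ratio = z,
                    state = ifelse(z >= threshold, "theta", "lia"))
  attr(out, "bin_length") <- spec$bin_length
  class(out) <- c("state_series", "data.frame")
  out
}

# intervals (t_start, t_end) of bins labeled theta
state_epochs <- function(state, label = "theta") {
  bl <- attr(state, "bin_length")
  runs <- logical_runs(state$state == label)
  if (nrow(runs) == 0L) return(empty_intervals())
  data.frame(t_start = state$time[runs[, "first"]] - bl / 2,
             t_end = state$time[runs[, "last"]] + bl / 2)
}

# local extremum of y nearest the candidate index, searched within
# [lo, hi]; ties broken to the earliest sample
refine_extremum <- function(y, lo, hi, maximum = TRUE) {
  seg <- y[lo:hi]
  i <- if (maximum) which.max(seg) else which.min(seg)
  lo + i - 1L
}

#' Segment theta cycles and measure half-cycle asymmetry
#'
#' Candidate peaks and troughs are the extrema between zero crossings of the
#' narrow-band (6-10 Hz) filtered LFP; each is then refined to the extremum
#' of the broad-band (6-40 Hz) signal, which better preserves the saw-tooth
#' shape of hippocampal theta, within the same zero-crossing bracket.
#' The descending half-cycle runs peak to trough and the ascending half
#' trough to next peak (pyramidal-layer convention).  Cycles are restricted
#' to theta-state epochs when a state series is supplied.  The per-cycle
#' asymmetry index is `log2(ascending duration / descending duration)`,
#' typically summarized by its median.
#'
#' @param lfp An [lfp_signal()].
#' @param state Optional `state_series` from [classify_state()]; only cycles
#'   inside theta epochs are kept.
#' @param channel Channel to segment.
#' @param narrow,broad Narrow and broad filter bands in Hz.
#' @return A data.frame of class `theta_cycles` with `t_peak`, `t_trough`,
#'   `t_next_peak`, `dur_desc`, `dur_asc`, `asymmetry`.
#' @export
segment_theta_cycles <- function(lfp, state = NULL, channel = 1L,
                                 narrow = c(6, 10), broad = c(6, 40)) {
  lfp <- maybe_decimate(lfp)
  x <- lfp_channel(lfp, channel)
  fs <- lfp$fs
  t <- lfp_times(lfp)
  xn <- butter_bandpass(x, fs, narrow)
  # gentle rolloff for the broad band: its role is preserving the saw-tooth
  # waveform shape (steep filters symmetrize the asymmetric cycle)
  xb <- butter_bandpass(x, fs, broad, order = 1L)
  xn <- xn - mean(xn)
  sgn <- sign(xn)
  sgn[sgn == 0] <- 1
  zc <- which(diff(sgn) != 0)                    # last index before crossing
  peaks <- integer(0); troughs <- integer(0)
  for (k in seq_len(length(zc) - 1L)) {
    lo <- zc[k] + 1L; hi <- zc[k + 1L]
    if (hi <= lo) next
    if (xn[lo] > 0) peaks <- c(peaks, refine_extremum(xb, lo, hi, TRUE))
    else troughs <- c(troughs, refine_extremum(xb, lo, hi, FALSE))
  }
  cycles <- list()
  for (p in seq_len(length(peaks) - 1L)) {
    tr <- troughs[troughs > peaks[p] & troughs < peaks[p + 1L]]
    if (length(tr) != 1L) next
    cycles[[length(cycles) + 1L]] <- c(peaks[p], tr, peaks[p + 1L])
  }
  if (length(cycles) == 0L) {
    out <- data.frame(t_peak = numeric(0), t_trough = numeric(0),
                      t_next_peak = numeric(0), dur_desc = numeric(0),
                      dur_asc = numeric(0), asymmetry = numeric(0))
    class(out) <- c("theta_cycles", "data.frame")
    return(out)
  }
  m <- do.call(rbind, cycles)
  out <- data.frame(t_peak = t[m[, 1L]], t_trough = t[m[, 2L]],
                    t_next_peak = t[m[, 3L]])
  out$dur_desc <- out$t_trough - out$t_peak
  out$dur_asc <- out$t_next_peak - out$t_trough
  out <- out[out$dur_desc > 0 & out$dur_asc > 0, , drop = FALSE]
  if (!is.null(state)) {
    ep <- state_epochs(state, "theta")
    keep <- in_intervals(out$t_peak, ep) & in_intervals(out$t_next_peak, ep)
    out <- out[keep, , drop = FALSE]
  }
  out$asymmetry <- log2(out$dur_asc / out$dur_desc)
  rownames(out) <- NULL
  class(out) <- c("theta_cycles", "data.frame")
  out
}
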