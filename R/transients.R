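# Transient events: sharp-wave ripple and high-synchrony event detection.

#' Sharp-wave ripple detector configuration
#'
#' Defaults: 150-250 Hz band, envelope threshold 4 SD above its session mean,
#' minimum duration 20 ms, merge gaps of 5 ms (end to start) and 20 ms
#' (start to start).
#'
#' @param band Ripple band in Hz.
#' @param z_threshold Envelope threshold in SDs above the session mean.
#' @param min_duration Minimum event duration in seconds (events must last
#'   longer than this).
#' @param merge_gap_end_start,merge_gap_start_start Merge gaps in seconds.
#' @return A list of class `swr_detector_config`.
#' @export
swr_detector_config <- function(band = c(150, 250), z_threshold = 4,
                                min_duration = 0.020,
                                merge_gap_end_start = 0.005,
                                merge_gap_start_start = 0.020) {
  if (z_threshold <= 0 || min_duration <= 0) {
    stop("thresholds must be positive")
  }
  structure(list(band = band, z_threshold = z_threshold,
                 min_duration = min_duration,
                 merge_gap_end_start = merge_gap_end_start,
                 merge_gap_start_start = merge_gap_start_start),
            class = "swr_detector_config")
}

#' High-synchrony event detector configuration
#'
#' Defaults: 1 ms population count bins, Gaussian kernel SD 7 ms, threshold
#' 3 SD above the session mean, durations strictly between 20 and 750 ms.
#'
#' @param bin_width Count bin width in seconds.
#' @param kernel_sd Gaussian smoothing SD in seconds.
#' @param z_threshold Threshold in SDs above the session mean.
#' @param min_duration,max_duration Exclusive duration bounds in seconds.
#' @return A list of class `hse_detector_config`.
#' @export
hse_detector_config <- function(bin_width = 0.001, kernel_sd = 0.007,
                                z_threshold = 3, min_duration = 0.020,
                                max_duration = 0.750) {
  if (min_duration >= max_duration) stop("min_duration must be < max_duration")
  structure(list(bin_width = bin_width, kernel_sd = kernel_sd,
                 z_threshold = z_threshold, min_duration = min_duration,
                 max_duration = max_duration),
            class = "hse_detector_config")
}

# iterative merge to fixpoint under both gap rules; events sorted by start
merge_events <- function(ev, gap_end_start, gap_start_start) {
  if (nrow(ev) <= 1L) return(ev)
  repeat {
    ev <- ev[order(ev$t_start), , drop = FALSE]
    merged <- FALSE
    keep <- rep(TRUE, nrow(ev))
    i <- 1L
    while (i < nrow(ev)) {
      j <- i + 1L
      if (!keep[j]) { i <- j; next }
      gap_es <- ev$t_start[j] - ev$t_end[i]
      gap_ss <- ev$t_start[j] - ev$t_start[i]
      if (gap_es < gap_end_start || gap_ss < gap_start_start) {
        ev$t_end[i] <- max(ev$t_end[i], ev$t_end[j])
        ev$peak_z[i] <- max(ev$peak_z[i], ev$peak_z[j])
        keep[j] <- FALSE
        ev <- ev[keep, , drop = FALSE]
        keep <- rep(TRUE, nrow(ev))
        merged <- TRUE
      } else {
        i <- j
      }
    }
    if (!merged) break
  }
  ev
}

#' Select the best ripple channel per shank
#'
#' For each channel, computes the Welch PSD, removes the aperiodic component
#' by the robust log-log fit over 80-400 Hz, and integrates the residual
#' power over the 120-250 Hz band; the channel with the largest residual
#' ripple power wins (ties go to the lowest channel index).
#'
#' @param lfp An [lfp_signal()].
#' @param shanks Optional integer/character vector assigning each channel to
#'   a shank; one winner is returned per shank.
#' @param fit_band Aperiodic fit range in Hz.
#' @param power_band Ripple power integration range in Hz.
#' @return Named integer vector of selected channel indices (one per shank).
#' @export
select_swr_channel <- function(lfp, shanks = NULL, fit_band = c(80, 400),
                               power_band = c(120, 250)) {
  n_ch <- ncol(lfp$samples)
  if (is.null(shanks)) shanks <- rep(1L, n_ch)
  if (length(shanks) != n_ch) stop("shanks must label every channel")
  score <- vapply(seq_len(n_ch), function(ch) {
    x <- lfp$samples[, ch]
    if (stats::sd(x) == 0) return(NA_real_)
    psd <- compute_psd(lfp, channel = ch, bin_length = 1)
    res <- fit_aperiodic_residual(psd, fit_band)
    sel <- res$freq >= power_band[1] & res$freq <= power_band[2]
    sum(res$power[sel])
  }, numeric(1))
  if (all(is.na(score))) stop("all channels are flat; cannot select")
  out <- vapply(split(seq_len(n_ch), shanks), function(idx) {
    s <- score[idx]
    if (all(is.na(s))) return(NA_integer_)
    idx[which.max(replace(s, is.na(s), -Inf))]   # which.max -> lowest index tie-break
  }, integer(1))
  out
}

#' Detect sharp-wave ripples
#'
#' Band-pass filters one LFP channel to the ripple band, takes the analytic
#' (Hilbert) envelope, z-normalizes it over the whole session, finds
#' supra-threshold intervals, merges candidates separated by less than 5 ms
#' (end to start) or whose starts are less than 20 ms apart, and keeps events
#' lasting longer than 20 ms.
#'
#' @param lfp An [lfp_signal()].
#' @param channel Channel to detect on; `NULL` selects the best ripple
#'   channel with [select_swr_channel()].
#' @param cfg A [swr_detector_config()].
#' @return A data.frame of class `transient_events` (attribute
#'   `kind = "swr"`) with `t_start`, `t_end`, `duration`, `peak_z`,
#'   `channel`.
#' @export
detect_swrs <- function(lfp, channel = NULL, cfg = swr_detector_config()) {
  if (lfp$fs < 2 * cfg$band[2]) {
    stop("sampling rate cannot represent the ripple band")
  }
  if (is.null(channel)) channel <- unname(select_swr_channel(lfp)[1L])
  x <- lfp_channel(lfp, channel)
  xf <- butter_bandpass(x, lfp$fs, cfg$band)
  env <- Mod(analytic_signal(xf))
  sde <- stats::sd(env)
  if (!is.finite(sde) || sde == 0) stop("envelope has zero variance")
  z <- (env - mean(env)) / sde
  t <- lfp_times(lfp)
  runs <- logical_runs(z > cfg$z_threshold)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), peak_z = numeric(0),
                      channel = integer(0))
  if (nrow(runs) == 0L) {
    return(structure(empty, class = c("transient_events", "data.frame"),
                     kind = "swr"))
  }
  ev <- data.frame(t_start = t[runs[, "first"]], t_end = t[runs[, "last"]],
                   peak_z = vapply(seq_len(nrow(runs)), function(i) {
                     max(z[runs[i, "first"]:runs[i, "last"]])
                   }, numeric(1)))
  ev <- merge_events(ev, cfg$merge_gap_end_start, cfg$merge_gap_start_start)
  ev$duration <- ev$t_end - ev$t_start
  ev <- ev[ev$duration > cfg$min_duration, , drop = FALSE]
  ev$channel <- rep(channel, nrow(ev))
  rownames(ev) <- NULL
  structure(ev[, c("t_start", "t_end", "duration", "peak_z", "channel")],
            class = c("transient_events", "data.frame"), kind = "swr")
}

#' Detect high-synchrony events from population spiking
#'
#' Sums spikes of the supplied (putative pyramidal) cells in 1 ms bins,
#' smooths with a 7 ms SD Gaussian kernel, z-normalizes over the session,
#' and keeps supra-threshold intervals lasting more than 20 ms and less than
#' 750 ms.  Event starts/ends are the first/last supra-threshold samples.
#'
#' @param spikes Data.frame with `cell_id`, `t`, restricted to putative
#'   pyramidal cells.
#' @param cfg A [hse_detector_config()].
#' @param t_range Session time span (length-2); defaults to the spike range.
#' @return A data.frame of class `transient_events` (attribute
#'   `kind = "hse"`) with `t_start`, `t_end`, `duration`, `peak_z`,
#'   `n_spikes`.
#' @export
detect_hses <- function(spikes, cfg = hse_detector_config(), t_range = NULL) {
  if (nrow(spikes) == 0L) stop("empty spike ensemble")
  if (is.null(t_range)) t_range <- c(0, max(spikes$t))
  edges <- seq(t_range[1], t_range[2] + cfg$bin_width, by = cfg$bin_width)
  counts <- tabulate(findInterval(spikes$t, edges,
                                  rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  sm <- gaussian_smooth(counts, cfg$kernel_sd / cfg$bin_width)
  sds <- stats::sd(sm)
  if (!is.finite(sds) || sds == 0) stop("population rate has zero variance")
  z <- (sm - mean(sm)) / sds
  runs <- logical_runs(z > cfg$z_threshold)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), peak_z = numeric(0),
                      n_spikes = integer(0))
  if (nrow(runs) == 0L) {
    return(structure(empty, class = c("transient_events", "data.frame"),
                     kind = "hse"))
  }
  centers <- edges[-length(edges)] + cfg$bin_width / 2
  ev <- data.frame(t_start = centers[runs[, "first"]] - cfg$bin_width / 2,
                   t_end = centers[runs[, "last"]] + cfg$bin_width / 2)
  ev$duration <- ev$t_end - ev$t_start
  ev$peak_z <- vapply(seq_len(nrow(runs)), function(i) {
    max(z[runs[i, "first"]:runs[i, "last"]])
  }, numeric(1))
  ev <- ev[ev$duration > cfg$min_duration & ev$duration < cfg$max_duration, ,
           drop = FALSE]
  ev$n_spikes <- vapply(seq_len(nrow(ev)), function(i) {
    sum(spikes$t >= ev$t_start[i] & spikes$t <= ev$t_end[i])
  }, integer(1))
  rownames(ev) <- NULL
  structure(ev, class = c("transient_events", "data.frame"), kind = "hse")
}

#' Summarize temporal overlap between SWRs and HSEs
#'
#' An event of one kind "overlaps" when any event of the other kind
#' intersects it in time.  Counts and percentages are reported from each
#' reference set.
#'
#' @param swrs,hses `transient_events` tables.
#' @return A list of class `overlap_summary` with counts and percentages.
#' @export
overlap_summary <- function(swrs, hses) {
  swr_hit <- intervals_overlap_any(swrs, hses)
  hse_hit <- intervals_overlap_any(hses, swrs)
  structure(list(
    n_swr = nrow(swrs), n_hse = nrow(hses),
    swr_overlapping = sum(swr_hit), hse_overlapping = sum(hse_hit),
    pct_swr = if (nrow(swrs) > 0L) 100 * mean(swr_hit) else NA_real_,
    pct_hse = if (nrow(hses) > 0L) 100 * mean(hse_hit) else NA_real_),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("SWRs: %d, of which %d (%.1f%%) overlap an HSE\n",
              x$n_swr, x$swr_overlapping, x$pct_swr))
  cat(sprintf("HSEs: %d, of which %d (%.1f%%) overlap an SWR\n",
              x$n_hse, x$hse_overlapping, x$pct_hse))
  invisible(x)
}
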