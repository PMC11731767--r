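# Multichannel LFP container.

#' Construct a multichannel LFP signal
#'
#' @param samples Numeric matrix (samples x channels) in microvolts, or a
#'   numeric vector for a single channel.
#' @param fs Sampling rate in Hz.
#' @param channel_ids Channel labels (default `ch1..chK`).
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, fs, channel_ids = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric matrix (samples x channels)")
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_ids) != ncol(samples)) {
    stop("channel_ids length must match the channel count")
  }
  colnames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs, channel_ids = channel_ids,
                 t0 = t0),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("LFP signal: %d channels, %.1f s at %g Hz (t0 = %g s)\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs, x$t0))
  invisible(x)
}

# sample times
lfp_times <- function(lfp) {
  lfp$t0 + (seq_len(nrow(lfp$samples)) - 1L) / lfp$fs
}

# one channel as a numeric vector; accepts an index or a channel id
lfp_channel <- function(lfp, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, lfp$channel_ids)
  if (is.na(channel) || channel < 1L || channel > ncol(lfp$samples)) {
    stop("unknown channel")
  }
  lfp$samples[, channel]
}

# anti-aliased decimation to at most target_fs (no-op when already below)
maybe_decimate <- function(lfp, target_fs = 2000) {
  if (lfp$fs <= target_fs) return(lfp)
  q <- ceiling(lfp$fs / target_fs)
  dec <- apply(lfp$samples, 2L, function(col) signal::decimate(col, q))
  lfp_signal(dec, lfp$fs / q, lfp$channel_ids, lfp$t0)
}
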