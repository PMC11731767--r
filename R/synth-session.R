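# Full synthetic session assembly: trajectory + spikes + LFP + ground truth.

# content location for scripted bursts: replay over-represents the reward
# site and (session-invariantly) the guarded end, with the rest uniform
draw_content <- function(n, geom, weights = c(feeder = 0.3, robot = 0.25,
                                              uniform = 0.45)) {
  z <- geom$zones
  kind <- sample(names(weights), n, replace = TRUE, prob = weights)
  x <- numeric(n)
  fz <- z[z$zone == "feeder", ]
  rz <- z[z$zone == "robot", ]
  x[kind == "feeder"] <- stats::runif(sum(kind == "feeder"), fz$start,
                                      fz$end)
  x[kind == "robot"] <- pmin(pmax(
    stats::rnorm(sum(kind == "robot"), (rz$start + rz$end) / 2, 3),
    rz$start + 1), rz$end - 1)
  # the unstructured component spans the nest-through-track region that
  # carries pre-attack assemblies (replay content expresses an assembly)
  x[kind == "uniform"] <- stats::runif(sum(kind == "uniform"), 0,
                                       rz$start)
  x
}

# draw non-overlapping event windows inside stillness intervals
draw_still_windows <- function(still, rate, dur_range, geom, seed) {
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(still))) {
      t0 <- still$t_start[i]; t1 <- still$t_end[i]
      len <- t1 - t0
      if (len < 1) next
      n_w <- stats::rpois(1, rate * len)
      if (n_w == 0L) next
      durs <- stats::runif(n_w, dur_range[1], dur_range[2])
      starts <- sort(stats::runif(n_w, t0 + 0.2, t1 - 0.2 - dur_range[2]))
      ends <- starts + durs
      keep <- logical(n_w)                       # enforce 0.2 s separation
      last_end <- -Inf
      for (j in seq_len(n_w)) {
        if (starts[j] > last_end + 0.2) {
          keep[j] <- TRUE
          last_end <- ends[j]
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        t_start = starts[keep], t_end = ends[keep],
        x_content = draw_content(sum(keep), geom))
    }
    if (length(out) == 0L) {
      return(data.frame(t_start = numeric(0), t_end = numeric(0),
                        x_content = numeric(0)))
    }
    do.call(rbind, out)
  })
}

#' Generate a complete synthetic session
#'
#' Composes the trajectory, place-field, theta-schedule, spike and LFP
#' generators under one master seed, returning the session bundle together
#' with full ground truth (scripted behavioral events, attack log, injected
#' ripple/high-synchrony windows, generative fields, the theta cycle
#' schedule and movement epochs).  Two calls with equal configuration and
#' seed produce identical sessions.
#'
#' @param cfg A [task_config()]; `cfg$seed` is the master seed.
#' @param geom An [arena_geometry()].
#' @param n_cells Number of place cells (default 50).
#' @param n_interneurons Number of fast-spiking cells added so the
#'   pyramidal-cell filter has something to reject (default 3).
#' @param remap_fraction Fraction of cells gaining post-attack robot-zone
#'   fields (default 0.3).
#' @param rates A [behavior_rates()].
#' @param theta_freq,theta_asym Theta base frequency (Hz) and
#'   ascending:descending duration ratio.
#' @param lookahead_cm Ascending-phase look-ahead offset (cm).
#' @param hse_rate Scripted high-synchrony events per second of stillness
#'   (default 0.25).
#' @param hse_duration Range (s) of scripted event durations.
#' @param with_lfp Generate the multichannel LFP (default TRUE; skipping it
#'   makes spike-only studies much faster).
#' @param fs LFP sampling rate in Hz.
#' @param ripple_amp_sd Injected ripple amplitude in background-envelope SDs.
#' @param ... Further arguments passed to [generate_lfp()].
#' @return An object of class `synthetic_session`: a list with `config`,
#'   `geometry`, `trajectory`, `spikes`, `cells` (waveform metrics), `lfp`
#'   (or NULL) and `ground_truth`.
#' @export
generate_session <- function(cfg, geom = arena_geometry(), n_cells = 50L,
                             n_interneurons = 3L, remap_fraction = 0.3,
                             rates = behavior_rates(), theta_freq = 8,
                             theta_asym = 1, lookahead_cm = 8,
                             hse_rate = 0.25, hse_duration = c(0.04, 0.09),
                             with_lfp = TRUE, fs = 1250, ripple_amp_sd = 6,
                             ...) {
  stopifnot(inherits(cfg, "task_config"))
  seed <- cfg$seed
  tr <- generate_trajectory(cfg, geom, rates,
                            seed = derive_seed(seed, "trajectory"))
  gt <- tr$ground_truth
  attack_time <- if (nrow(gt$attacks) > 0L) min(gt$attacks$t) else Inf

  fields <- generate_place_fields(n_cells, geom, remap_fraction,
                                  seed = derive_seed(seed, "fields"))
  theta <- generate_theta_schedule(gt$movement, freq = theta_freq,
                                   asym_ratio = theta_asym,
                                   seed = derive_seed(seed, "theta"))
  # stillness = session minus movement
  dur <- cfg$session_duration
  still <- local({
    m <- gt$movement
    if (nrow(m) == 0L) return(data.frame(t_start = 0, t_end = dur))
    data.frame(t_start = c(0, m$t_end), t_end = c(m$t_start, dur))
  })
  still <- still[still$t_end - still$t_start > 0, , drop = FALSE]
  hse_windows <- draw_still_windows(still, hse_rate, hse_duration, geom,
                                    derive_seed(seed, "hse_windows"))
  # ripples coincide with the population bursts but last at least ~80 ms so
  # the supra-threshold envelope core clears the 20 ms duration criterion
  swr_windows <- hse_windows[, c("t_start", "t_end")]
  if (nrow(swr_windows) > 0L) {
    pad <- pmax(0, 0.08 - (swr_windows$t_end - swr_windows$t_start)) / 2
    swr_windows$t_start <- swr_windows$t_start - pad
    swr_windows$t_end <- swr_windows$t_end + pad
  }

  spikes <- generate_spike_trains(tr$trajectory, fields, theta, hse_windows,
                                  attack_time = attack_time,
                                  lookahead_cm = lookahead_cm,
                                  seed = derive_seed(seed, "spikes"))
  # fast-spiking cells: high rate, narrow waveform (rejected by the
  # pyramidal filter)
  if (n_interneurons > 0L) {
    int_spk <- with_seed(derive_seed(seed, "interneurons"), {
      do.call(rbind, lapply(seq_len(n_interneurons), function(j) {
        n_s <- stats::rpois(1, 25 * dur)
        data.frame(cell_id = as.integer(n_cells + j),
                   t = sort(stats::runif(n_s, 0, dur)))
      }))
    })
    spikes <- rbind(spikes, int_spk)
    spikes <- spikes[order(spikes$t), ]
    rownames(spikes) <- NULL
    class(spikes) <- c("spike_ensemble", "data.frame")
  }
  counts <- table(factor(spikes$cell_id,
                         levels = seq_len(n_cells + n_interneurons)))
  cells <- with_seed(derive_seed(seed, "waveforms"), data.frame(
    cell_id = seq_len(n_cells + n_interneurons),
    mean_rate_hz = as.numeric(counts) / dur,
    peak_valley_ratio = c(stats::runif(n_cells, 0.55, 1.1),
                          stats::runif(n_interneurons, 0.1, 0.35))))

  lfp <- NULL
  if (with_lfp) {
    lfp <- generate_lfp(gt$movement, dur, theta, swr_windows, fs = fs,
                        ripple_amp_sd = ripple_amp_sd,
                        seed = derive_seed(seed, "lfp"), ...)
  }

  gt$fields <- fields
  gt$theta <- theta
  gt$hse_windows <- hse_windows
  gt$swr_windows <- swr_windows
  gt$attack_time <- attack_time
  gt$stillness <- still
  structure(list(config = cfg, geometry = geom, trajectory = tr$trajectory,
                 spikes = spikes, cells = cells, lfp = lfp,
                 ground_truth = gt, n_laps = tr$n_laps),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "Synthetic %s session: %.0f s, %d laps, %d cells, %d spikes\n",
    x$config$session_type, x$config$session_duration, x$n_laps,
    nrow(x$cells), nrow(x$spikes)))
  cat(sprintf(
    "  scripted: %d hesitations, %d aborts, %d pauses, %d attacks, %d bursts\n",
    nrow(gt$hesitations), nrow(gt$mtas), nrow(gt$pauses), nrow(gt$attacks),
    nrow(gt$hse_windows)))
  if (!is.null(x$lfp)) print(x$lfp)
  invisible(x)
}
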