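# One-step Bayesian decoding of spatial posteriors from ensemble spike
# counts, and its applications to high-synchrony events and theta half-cycles.

#' Decoder configuration
#'
#' @param min_cells Minimum ensemble size; decoding refuses smaller ensembles
#'   (default 10).
#' @param rate_floor Small rate (spikes/s) substituted for zero expected
#'   rates in defined bins, preventing one silent cell from zeroing the
#'   posterior (default 0.01).
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(min_cells = 10L, rate_floor = 0.01) {
  if (min_cells < 1L) stop("min_cells must be >= 1")
  structure(list(min_cells = as.integer(min_cells),
                 rate_floor = rate_floor),
            class = "decoder_config")
}

#' Decode a spatial posterior from one window of spike counts
#'
#' Computes the one-step Bayesian posterior over the tuning grid under
#' Poisson-independent firing and a uniform spatial prior:
#' `P(x | n) = prod_i A_i(x)^(n_i) * (1/X) / exp(tau * sum_i A_i(x))`,
#' normalized to sum to 1 over the defined bins.  Evaluation is in log
#' space.  Bins with undefined tuning (zero occupancy) receive zero posterior
#' mass and are excluded from the normalization.
#'
#' @param counts Integer vector of spikes per cell within the window, in the
#'   order of `curves$cells` (or named by cell id).
#' @param curves A [build_tuning_curves()] fit supplying the expected rates
#'   `A_i(x)`.
#' @param tau Window duration in seconds.
#' @param config A [decoder_config()].
#' @return An object of class `posterior`: probability mass over the full
#'   grid (`prob`), the position marginal over the 64 positional bins
#'   (`marginal`), the grid, `n_cells` and `tau`.
#' @export
decode_posterior <- function(counts, curves, tau,
                             config = decoder_config()) {
  a <- curves$rates
  if (!is.null(names(counts))) {
    counts <- counts[match(curves$cells, as.integer(names(counts)))]
  }
  if (length(counts) != nrow(a)) {
    stop("counts length must match the number of cells in the curves")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (tau <= 0) stop("tau must be positive")
  n_cells <- length(counts)
  if (n_cells < config$min_cells) {
    stop(sprintf("ensemble of %d cells is below the minimum of %d",
                 n_cells, config$min_cells))
  }
  defined <- curves$occupancy > 0
  if (!any(defined)) stop("all tuning bins are undefined")
  a_def <- pmax(a[, defined, drop = FALSE], config$rate_floor)
  logp <- colSums(counts * log(a_def)) - tau * colSums(a_def) -
    log(ncol(a))
  logp <- logp - logsumexp(logp)
  prob <- numeric(ncol(a))
  prob[defined] <- exp(logp)
  g <- curves$grid
  marg <- rowSums(matrix(prob, nrow = g$n_pos))
  structure(list(prob = prob, marginal = marg, grid = g,
                 n_cells = n_cells, tau = tau,
                 n_spikes = sum(counts)),
            class = "posterior")
}

#' @rdname decode_posterior
#' @param object A `tuning_curves` fit.
#' @param ... Passed on to [decode_posterior()].
#' @export
predict.tuning_curves <- function(object, counts, tau, ...) {
  decode_posterior(counts, object, tau, ...)
}

#' @export
print.posterior <- function(x, ...) {
  cat(sprintf(
    "Posterior over %d bins (%d cells, %d spikes, tau = %.3f s); MAP bin %d\n",
    length(x$prob), x$n_cells, x$n_spikes, x$tau, which.max(x$marginal)))
  invisible(x)
}

#' Posterior mass within an arena zone
#'
#' Sums the position-marginal posterior over the positional bins whose
#' centers fall inside the named zone.
#'
#' @param posterior A [decode_posterior()] result.
#' @param geom An [arena_geometry()].
#' @param zone Zone name (e.g. `"robot"`, `"feeder"`).
#' @return Probability mass in `[0, 1]`.
#' @export
zone_mass <- function(posterior, geom, zone) {
  z <- geom$zones
  if (!zone %in% z$zone) stop("unknown zone: ", zone)
  lo <- z$start[z$zone == zone]; hi <- z$end[z$zone == zone]
  centers <- posterior$grid$centers
  sum(posterior$marginal[centers >= lo & centers < hi])
}

# spike counts per cell within [t0, t1), using per-cell sorted spike times
window_counts <- function(spike_times_by_cell, t0, t1) {
  vapply(spike_times_by_cell, function(st) {
    if (length(st) == 0L) return(0L)
    as.integer(findInterval(t1, st) - findInterval(t0, st))
  }, integer(1))
}

split_spike_times <- function(spikes, cells) {
  lapply(cells, function(cid) sort(spikes$t[spikes$cell_id == cid]))
}

#' Cross-decode high-synchrony events against pre/post tuning curves
#'
#' Each in-nest event is decoded with `tau` equal to its duration under both
#' the pre-attack and post-attack tuning-curve sets; the posterior mass over
#' the robot and feeder zones is recorded.  Events are partitioned into
#' pre/post by the first-attack (or yoked) split time, giving the 2 x 2
#' design of event epoch by tuning epoch.
#'
#' @param hses A `transient_events` table of high-synchrony events (already
#'   restricted to the epochs of interest, e.g. in-nest LIA).
#' @param spikes Spike table for the decoded ensemble.
#' @param curves_pre,curves_post `tuning_curves` fits for the two epochs.
#' @param split_time First-attack (or yoked-lap) time in seconds.
#' @param geom An [arena_geometry()].
#' @param config A [decoder_config()].
#' @return An object of class `cross_decoding`: per-event table and the 2 x 2
#'   summary of mean zone masses.
#' @export
decode_hse_events <- function(hses, spikes, curves_pre, curves_post,
                              split_time, geom = arena_geometry(),
                              config = decoder_config()) {
  if (!identical(curves_pre$cells, curves_post$cells)) {
    stop("curve epochs must share one cell set")
  }
  cells <- curves_pre$cells
  by_cell <- split_spike_times(spikes, cells)
  rows <- list()
  for (i in seq_len(nrow(hses))) {
    t0 <- hses$t_start[i]; t1 <- hses$t_end[i]
    n <- window_counts(by_cell, t0, t1)
    tau <- t1 - t0
    for (ce in c("pre", "post")) {
      cu <- if (ce == "pre") curves_pre else curves_post
      post <- decode_posterior(n, cu, tau, config)
      rows[[length(rows) + 1L]] <- data.frame(
        event = i, t_start = t0, t_end = t1,
        event_epoch = if (t1 <= split_time) "pre" else "post",
        curve_epoch = ce,
        robot_mass = zone_mass(post, geom, "robot"),
        feeder_mass = zone_mass(post, geom, "feeder"),
        n_cells = post$n_cells, n_spikes = post$n_spikes, tau = tau)
    }
  }
  per_event <- if (length(rows) == 0L) {
    data.frame(event = integer(0), t_start = numeric(0), t_end = numeric(0),
               event_epoch = character(0), curve_epoch = character(0),
               robot_mass = numeric(0), feeder_mass = numeric(0),
               n_cells = integer(0), n_spikes = integer(0), tau = numeric(0))
  } else do.call(rbind, rows)
  combos <- expand.grid(event_epoch = c("pre", "post"),
                        curve_epoch = c("pre", "post"),
                        stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    sel <- per_event$event_epoch == combos$event_epoch[k] &
      per_event$curve_epoch == combos$curve_epoch[k]
    data.frame(event_epoch = combos$event_epoch[k],
               curve_epoch = combos$curve_epoch[k],
               n_events = sum(sel),
               robot_mass = if (any(sel)) mean(per_event$robot_mass[sel])
                 else NA_real_,
               feeder_mass = if (any(sel)) mean(per_event$feeder_mass[sel])
                 else NA_real_)
  }))
  structure(list(per_event = per_event, summary = summary,
                 split_time = split_time),
            class = "cross_decoding")
}

#' @export
print.cross_decoding <- function(x, ...) {
  cat("Cross-decoding of high-synchrony events",
      sprintf("(split at %.1f s)\n", x$split_time))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Decode ascending and descending theta half-cycles
#'
#' Accumulates ensemble spike counts separately over the descending
#' (peak-to-trough) and ascending (trough-to-peak) half of every theta cycle,
#' decodes each half with `tau` equal to the half-cycle duration, and
#' expresses the posterior both in track coordinates and re-centered on the
#' animal's position at the half-cycle midpoint, signed so positive offsets
#' point along the current journey direction.  Halves with zero ensemble
#' spikes decode to the closed-form zero-spike posterior and are flagged.
#' The difference map is descending minus ascending, averaged across cycles.
#'
#' @param cycles A `theta_cycles` table.
#' @param spikes Spike table for the decoded ensemble (putative pyramidal
#'   cells).
#' @param curves A `tuning_curves` fit.
#' @param traj Trajectory data.frame.
#' @param config A [decoder_config()].
#' @param stationary_speed Speed bound (cm/s) used to sign the offsets.
#' @return An object of class `theta_decoding`: per-half-cycle table
#'   (decoded MAP bin, true bin, signed offset, flags) and the
#'   descending-minus-ascending difference map over signed positional
#'   offsets.
#' @export
decode_theta_cycles <- function(cycles, spikes, curves, traj,
                                config = decoder_config(),
                                stationary_speed = 5) {
  cells <- curves$cells
  by_cell <- split_spike_times(spikes, cells)
  g <- curves$grid
  vd <- track_direction(traj, stationary_speed)
  n_cyc <- nrow(cycles)
  halves <- data.frame(
    cycle = rep(seq_len(n_cyc), each = 2L),
    phase = rep(c("descending", "ascending"), n_cyc),
    t0 = as.numeric(rbind(cycles$t_peak, cycles$t_trough)),
    t1 = as.numeric(rbind(cycles$t_trough, cycles$t_next_peak)))
  n_off <- 2L * g$n_pos - 1L
  offsets <- seq(-(g$n_pos - 1L), g$n_pos - 1L)
  acc <- matrix(0, nrow = 2L, ncol = n_off,
                dimnames = list(c("descending", "ascending"), offsets))
  acc_n <- c(descending = 0L, ascending = 0L)
  n_h <- nrow(halves)
  t_mid <- (halves$t0 + halves$t1) / 2
  x_now <- stats::approx(traj$t, traj$x, xout = t_mid, rule = 2)$y
  true_bin <- pos_bin_of(x_now, g)
  si <- pmin(pmax(findInterval(t_mid, traj$t), 1L), nrow(traj))
  dir_sign <- ifelse(vd$v[si] >= 0, 1L, -1L)
  n_spk <- integer(n_h); map_bin <- integer(n_h); com_bin <- numeric(n_h)
  for (i in seq_len(n_h)) {
    n <- window_counts(by_cell, halves$t0[i], halves$t1[i])
    post <- decode_posterior(n, curves, halves$t1[i] - halves$t0[i], config)
    n_spk[i] <- post$n_spikes
    map_bin[i] <- which.max(post$marginal)
    com_bin[i] <- sum(post$marginal * seq_len(g$n_pos)) /
      sum(post$marginal)
    rel <- (seq_len(g$n_pos) - true_bin[i]) * dir_sign[i]
    sh <- numeric(n_off)
    sh[match(rel, offsets)] <- post$marginal
    ph <- halves$phase[i]
    acc[ph, ] <- acc[ph, ] + sh
    acc_n[ph] <- acc_n[ph] + 1L
  }
  per_half <- data.frame(
    cycle = halves$cycle, phase = halves$phase, t0 = halves$t0,
    t1 = halves$t1, tau = halves$t1 - halves$t0, n_spikes = n_spk,
    true_bin = true_bin, map_bin = map_bin, com_bin = com_bin,
    dir_sign = dir_sign,
    err_bins = abs(map_bin - true_bin),
    signed_offset = (map_bin - true_bin) * dir_sign,
    signed_com = (com_bin - true_bin) * dir_sign,
    zero_spikes = n_spk == 0L)
  mean_maps <- sweep(acc, 1L, pmax(acc_n, 1L), "/")
  structure(list(per_half = per_half,
                 offsets = offsets,
                 diff_map = mean_maps["descending", ] -
                   mean_maps["ascending", ],
                 mean_maps = mean_maps),
            class = "theta_decoding")
}

#' @export
print.theta_decoding <- function(x, ...) {
  d <- x$per_half[!x$per_half$zero_spikes, ]
  for (ph in c("descending", "ascending")) {
    s <- d[d$phase == ph, ]
    cat(sprintf(
      "%s halves: %d decoded, median |error| %.1f bins, median signed offset %.1f bins\n",
      ph, nrow(s), stats::median(s$err_bins),
      stats::median(s$signed_offset)))
  }
  invisible(x)
}

#' Select position/direction/epoch-matched control cycles
#'
#' For each target theta cycle, draws up to `cap` control cycles (without
#' replacement, seeded) that share the target's positional bin, direction
#' and pre/post epoch, excluding cycles that fall within `margin` seconds of
#' any event window.
#'
#' @param targets Integer indices (rows of `annotations`) of the target
#'   cycles.
#' @param annotations Data.frame with one row per cycle: `t_mid`, `pos_bin`,
#'   `direction`, `epoch` (see [annotate_cycles()]).
#' @param event_windows Data.frame of event intervals to exclude around
#'   (e.g. aborts/pauses), or NULL.
#' @param margin Exclusion margin in seconds (default 1).
#' @param cap Maximum controls per target (default 10).
#' @param seed Integer seed.
#' @return A list, one integer vector of control row indices per target
#'   (empty, with a warning, when no eligible control exists).
#' @export
match_control_cycles <- function(targets, annotations, event_windows = NULL,
                                 margin = 1, cap = 10L, seed = 1L) {
  excluded <- rep(FALSE, nrow(annotations))
  if (!is.null(event_windows) && nrow(event_windows) > 0L) {
    padded <- data.frame(t_start = event_windows$t_start - margin,
                         t_end = event_windows$t_end + margin)
    excluded <- in_intervals(annotations$t_mid, padded)
  }
  with_seed(seed, lapply(targets, function(tg) {
    elig <- which(!excluded &
                    annotations$pos_bin == annotations$pos_bin[tg] &
                    annotations$direction == annotations$direction[tg] &
                    annotations$epoch == annotations$epoch[tg])
    elig <- setdiff(elig, targets)
    if (length(elig) == 0L) {
      warning("no eligible control cycles for target ", tg)
      return(integer(0))
    }
    if (length(elig) <= cap) return(elig)
    sample(elig, cap)
  }))
}

#' Annotate theta cycles with position, direction and epoch
#'
#' @param cycles A `theta_cycles` table.
#' @param traj Trajectory data.frame.
#' @param grid A [tuning_grid()].
#' @param split_time Pre/post split time in seconds.
#' @param stationary_speed Speed bound (cm/s).
#' @return Data.frame with `t_mid`, `pos_bin`, `direction`, `epoch`.
#' @export
annotate_cycles <- function(cycles, traj, grid, split_time = Inf,
                            stationary_speed = 5) {
  t_mid <- (cycles$t_peak + cycles$t_next_peak) / 2
  x <- stats::approx(traj$t, traj$x, xout = t_mid, rule = 2)$y
  vd <- track_direction(traj, stationary_speed)
  si <- pmin(pmax(findInterval(t_mid, traj$t), 1L), nrow(traj))
  data.frame(t_mid = t_mid, pos_bin = pos_bin_of(x, grid),
             direction = vd$direction[si],
             epoch = ifelse(t_mid < split_time, "pre", "post"))
}
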