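# Behavioral event classification: journeys, hesitations, mid-track aborts,
# on-track pauses, yoked pre/post splits and subject normalization.

#' Behavioral detection parameters
#'
#' @param feeder_exclusion_radius Radius (cm) around the nest feeder excluded
#'   from hesitation time (default 2).
#' @param mta_min_track_time Minimum time on track (s) for a mid-track abort
#'   (default 0.5).
#' @param mta_min_distance Minimum distance traveled on track (cm) for an
#'   abort (default 5).
#' @param pause_lowpass_cutoff Low-pass cutoff (Hz) applied to position before
#'   pause detection (default 2).
#' @param pause_max_displacement Maximum long-axis displacement (cm) within a
#'   pause (default 1).
#' @param pause_min_duration Minimum pause duration in seconds (default 0.5).
#' @param max_gap_bridge Maximum tracking-loss gap (s) bridged by linear
#'   interpolation (default 0.5).
#' @return A list of class `behavior_config`.
#' @export
behavior_config <- function(feeder_exclusion_radius = 2,
                            mta_min_track_time = 0.5,
                            mta_min_distance = 5,
                            pause_lowpass_cutoff = 2,
                            pause_max_displacement = 1,
                            pause_min_duration = 0.5,
                            max_gap_bridge = 0.5) {
  cfg <- list(feeder_exclusion_radius = feeder_exclusion_radius,
              mta_min_track_time = mta_min_track_time,
              mta_min_distance = mta_min_distance,
              pause_lowpass_cutoff = pause_lowpass_cutoff,
              pause_max_displacement = pause_max_displacement,
              pause_min_duration = pause_min_duration,
              max_gap_bridge = max_gap_bridge)
  if (any(unlist(cfg) <= 0)) stop("all behavior parameters must be positive")
  class(cfg) <- "behavior_config"
  cfg
}

# bridge tracking loss up to max_gap seconds by linear interpolation; longer
# gaps stay NA (and are flagged by the callers)
bridge_tracking <- function(traj, max_gap = 0.5) {
  x <- traj$x; y <- traj$y
  bad <- !traj$tracked | is.na(x)
  if (!any(bad)) return(traj)
  runs <- logical_runs(bad)
  ok <- which(!bad)
  for (r in seq_len(nrow(runs))) {
    i0 <- runs[r, "first"]; i1 <- runs[r, "last"]
    gap <- traj$t[min(i1 + 1L, nrow(traj))] - traj$t[max(i0 - 1L, 1L)]
    if (gap <= max_gap && i0 > 1L && i1 < nrow(traj)) {
      idx <- i0:i1
      x[idx] <- stats::approx(traj$t[c(i0 - 1L, i1 + 1L)],
                              x[c(i0 - 1L, i1 + 1L)], traj$t[idx])$y
      y[idx] <- stats::approx(traj$t[c(i0 - 1L, i1 + 1L)],
                              y[c(i0 - 1L, i1 + 1L)], traj$t[idx])$y
      traj$tracked[idx] <- TRUE
    }
  }
  traj$x <- x; traj$y <- y
  traj
}

# smoothed along-track velocity (cm/s) and direction class per sample
track_direction <- function(traj, stationary_speed = 5, smooth_s = 0.2) {
  dt <- stats::median(diff(traj$t))
  v <- c(0, diff(traj$x)) / dt
  v <- gaussian_smooth(v, smooth_s / dt)
  direction <- rep("stationary", nrow(traj))
  direction[v >= stationary_speed] <- "outbound"
  direction[v <= -stationary_speed] <- "inbound"
  data.frame(v = v, direction = direction)
}

#' Segment a trajectory into journeys and count laps
#'
#' An outbound journey starts when the rat leaves the doorway onto the track
#' and is completed when it triggers the track-feeder threshold; an inbound
#' journey is the reverse.  A lap is counted each time the rat triggers the
#' two feeder thresholds in alternation (one full out-and-back cycle).
#' Sub-2-cm excursions onto the track (tracking jitter at the boundary) are
#' labeled `micro` and take part in no further analysis.
#'
#' @param traj Trajectory data.frame with columns `t`, `x`, `y`, `tracked`.
#' @param geom An [arena_geometry()].
#' @param cfg A [behavior_config()].
#' @return A list with `journeys` (data.frame: `t_start`, `t_end`,
#'   `direction`, `completed`, `lap`, `classification`, `excursion`,
#'   `path_cm`, `uncertain`) and `n_laps`.
#' @export
segment_journeys <- function(traj, geom, cfg = behavior_config()) {
  traj <- bridge_tracking(traj, cfg$max_gap_bridge)
  z <- geom$zones
  door_end <- z$start[z$zone == "nest_side_track"]
  feeder_trig <- geom$feeder_positions[["track"]] - 2
  nest_trig <- geom$feeder_positions[["nest"]] + 2
  xs <- stats::runmed(ifelse(traj$tracked, traj$x, NA), 5)
  n <- length(xs)

  journeys <- list()
  state <- if (!is.na(xs[1]) && xs[1] >= door_end) "out" else "nest"
  j_start <- 1L
  lap <- 0L
  last_feeder <- "nest"
  add_journey <- function(i0, i1, direction, completed) {
    seg <- xs[i0:i1]
    untracked <- anyNA(seg) || any(!traj$tracked[i0:i1])
    seg <- seg[!is.na(seg)]
    exc <- if (direction == "outbound") max(seg) - door_end else
      (geom$feeder_positions[["track"]] - 2) - min(seg)
    path <- sum(abs(diff(seg)))
    journeys[[length(journeys) + 1L]] <<- data.frame(
      t_start = traj$t[i0], t_end = traj$t[i1], direction = direction,
      completed = completed, lap = lap + 1L,
      classification = if (untracked) "uncertain"
        else if (completed) "completed"
        else if (exc < 2) "micro" else "incomplete",
      excursion = exc, path_cm = path, uncertain = untracked)
  }
  for (i in seq_len(n)) {
    x <- xs[i]
    if (is.na(x)) next
    if (state == "nest") {
      if (x <= nest_trig && last_feeder == "track") {
        lap <- lap + 1L
        last_feeder <- "nest"
      }
      if (x >= door_end) { state <- "out"; j_start <- i }
    } else if (state == "out") {
      if (x >= feeder_trig) {
        add_journey(j_start, i, "outbound", TRUE)
        state <- "feeder"
        last_feeder <- "track"
      } else if (x < door_end) {
        add_journey(j_start, i, "outbound", FALSE)
        state <- "nest"
      }
    } else if (state == "feeder") {
      if (x < feeder_trig) { state <- "in"; j_start <- i }
    } else {                                     # inbound
      if (x < door_end) {
        add_journey(j_start, i, "inbound", TRUE)
        state <- "nest"
      } else if (x >= feeder_trig) {
        add_journey(j_start, i, "inbound", FALSE)
        state <- "feeder"
      }
    }
  }
  journeys <- if (length(journeys) == 0L) {
    data.frame(t_start = numeric(0), t_end = numeric(0),
               direction = character(0), completed = logical(0),
               lap = integer(0), classification = character(0),
               excursion = numeric(0), path_cm = numeric(0),
               uncertain = logical(0))
  } else do.call(rbind, journeys)
  list(journeys = journeys, n_laps = lap)
}

#' Measure hesitation events in the nest and doorway
#'
#' A hesitation is a contiguous occupancy of the nest + doorway zones that
#' begins at entry from the track and ends at exit onto the track.  Reported
#' duration excludes time spent within `feeder_exclusion_radius` of the nest
#' feeder.  Occupancies that start the session (no entry from the track) or
#' run into the end of the recording (no exit) are returned with
#' `entered_from_track`/`exited_to_track` set to `FALSE` so callers can
#' exclude them from duration analyses.
#'
#' @inheritParams segment_journeys
#' @return Data.frame with `t_start`, `t_end`, `duration` (feeder-excluded,
#'   s), `feeder_time`, `entered_from_track`, `exited_to_track`,
#'   `uncertain`.
#' @export
measure_hesitation <- function(traj, geom, cfg = behavior_config()) {
  traj <- bridge_tracking(traj, cfg$max_gap_bridge)
  z <- geom$zones
  door_end <- z$start[z$zone == "nest_side_track"]
  xs <- stats::runmed(ifelse(traj$tracked, traj$x, NA), 5)
  inside <- !is.na(xs) & xs < door_end
  runs <- logical_runs(inside)
  if (nrow(runs) == 0L) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), feeder_time = numeric(0),
                      entered_from_track = logical(0),
                      exited_to_track = logical(0),
                      uncertain = logical(0)))
  }
  dt <- stats::median(diff(traj$t))
  fx <- geom$feeder_positions[["nest"]]
  fy <- geom$track_width / 2
  out <- lapply(seq_len(nrow(runs)), function(r) {
    i0 <- runs[r, "first"]; i1 <- runs[r, "last"]
    idx <- i0:i1
    near_feeder <- sqrt((traj$x[idx] - fx)^2 + (traj$y[idx] - fy)^2) <=
      cfg$feeder_exclusion_radius
    feeder_t <- sum(near_feeder, na.rm = TRUE) * dt
    total <- (i1 - i0 + 1L) * dt
    boundary <- c(max(i0 - 1L, 1L), min(i1 + 1L, nrow(traj)))
    data.frame(t_start = traj$t[i0], t_end = traj$t[i1] + dt,
               duration = total - feeder_t, feeder_time = feeder_t,
               entered_from_track = i0 > 1L,
               exited_to_track = i1 < nrow(traj),
               uncertain = any(!traj$tracked[c(boundary, idx)]))
  })
  do.call(rbind, out)
}

#' Detect mid-track aborts
#'
#' A mid-track abort (MTA) is an incomplete journey during which the rat was
#' on the track for at least `mta_min_track_time` seconds and advanced at
#' least `mta_min_distance` cm onto it, and which does not contain a robot
#' attack (retreats from attacks are excluded).  Requiring the advance — the
#' excursion beyond the entry boundary — rather than the round-trip path also
#' screens out doorway "stretches" in which the body never leaves the entry.
#' The event timestamp is a head-turn proxy: the first sample at which the
#' smoothed along-track velocity changes sign within the abort interval.
#'
#' @inheritParams segment_journeys
#' @param journeys The `journeys` table from [segment_journeys()].
#' @param attack_log Optional data.frame with a `t` column of attack times.
#' @return Data.frame with `t_start`, `t_end`, `t_turn`, `lap`, `direction`,
#'   `duration`, `path_cm`, `excursion`.
#' @export
detect_mtas <- function(traj, journeys, attack_log = NULL,
                        cfg = behavior_config()) {
  traj <- bridge_tracking(traj, cfg$max_gap_bridge)
  cand <- journeys[!journeys$completed &
                     journeys$classification %in% "incomplete", ,
                   drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      t_turn = numeric(0), lap = integer(0),
                      direction = character(0), duration = numeric(0),
                      path_cm = numeric(0), excursion = numeric(0)))
  }
  dur <- cand$t_end - cand$t_start
  keep <- dur >= cfg$mta_min_track_time &
    cand$excursion >= cfg$mta_min_distance
  if (!is.null(attack_log) && nrow(attack_log) > 0L) {
    contains_attack <- vapply(seq_len(nrow(cand)), function(i) {
      any(attack_log$t >= cand$t_start[i] & attack_log$t <= cand$t_end[i])
    }, logical(1))
    keep <- keep & !contains_attack
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      t_turn = numeric(0), lap = integer(0),
                      direction = character(0), duration = numeric(0),
                      path_cm = numeric(0), excursion = numeric(0)))
  }
  vd <- track_direction(traj)
  t_turn <- vapply(seq_len(nrow(cand)), function(i) {
    idx <- which(traj$t >= cand$t_start[i] & traj$t <= cand$t_end[i])
    v <- vd$v[idx]
    sgn <- if (cand$direction[i] == "outbound") 1 else -1
    flip <- which(sign(v) == -sgn)
    if (length(flip) > 0L) traj$t[idx[flip[1L]]] else
      traj$t[idx[which.min(sgn * v)]]
  }, numeric(1))
  data.frame(t_start = cand$t_start, t_end = cand$t_end, t_turn = t_turn,
             lap = cand$lap, direction = cand$direction,
             duration = cand$t_end - cand$t_start, path_cm = cand$path_cm,
             excursion = cand$excursion)
}

#' Detect on-track pauses
#'
#' Position is low-pass filtered (zero-phase Butterworth at
#' `pause_lowpass_cutoff`) and a pause spans every maximal interval during a
#' journey in which the long-axis displacement stays below
#' `pause_max_displacement` for longer than `pause_min_duration`.
#'
#' @inheritParams detect_mtas
#' @return Data.frame with `t_start`, `t_end`, `duration`, `lap`,
#'   `direction`.
#' @export
detect_pauses <- function(traj, journeys, cfg = behavior_config()) {
  traj <- bridge_tracking(traj, cfg$max_gap_bridge)
  fs <- 1 / stats::median(diff(traj$t))
  xs <- butter_lowpass(traj$x, fs, cfg$pause_lowpass_cutoff, order = 2L)
  res <- list()
  act <- journeys[journeys$classification %in% c("completed", "incomplete"), ,
                  drop = FALSE]
  for (j in seq_len(nrow(act))) {
    idx <- which(traj$t >= act$t_start[j] & traj$t <= act$t_end[j])
    if (length(idx) < 2L) next
    seg <- xs[idx]
    i <- 1L
    while (i < length(seg)) {
      lo <- seg[i]; hi <- seg[i]
      k <- i
      while (k < length(seg)) {
        nlo <- min(lo, seg[k + 1L]); nhi <- max(hi, seg[k + 1L])
        if (nhi - nlo >= cfg$pause_max_displacement) break
        lo <- nlo; hi <- nhi; k <- k + 1L
      }
      dur <- traj$t[idx[k]] - traj$t[idx[i]]
      if (k > i && dur > cfg$pause_min_duration) {
        res[[length(res) + 1L]] <- data.frame(
          t_start = traj$t[idx[i]], t_end = traj$t[idx[k]], duration = dur,
          lap = act$lap[j], direction = act$direction[j])
        i <- k + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), lap = integer(0),
                      direction = character(0)))
  }
  do.call(rbind, res)
}

#' Assign yoked pre/post split laps to non-attack sessions
#'
#' Attack sessions keep their true first-attack lap.  The multiset of those
#' lap indices is randomly permuted (seeded) and assigned one-to-one to the
#' non-attack sessions, so pre/post comparisons are matched in experience.
#'
#' @param attack_first_laps Integer vector: first-attack lap per attack
#'   session.
#' @param non_attack_sessions Character/integer ids of the non-attack
#'   sessions (same length).
#' @param seed Integer seed.
#' @return Data.frame with `session`, `split_lap`, `provenance`.
#' @export
yoke_split <- function(attack_first_laps, non_attack_sessions, seed = 1L) {
  n_a <- length(attack_first_laps)
  n_s <- length(non_attack_sessions)
  if (n_a != n_s) {
    stop(sprintf(
      "count mismatch: %d attack first-lap indices vs %d non-attack sessions",
      n_a, n_s))
  }
  perm <- with_seed(seed, attack_first_laps[sample.int(n_a, n_a)])
  data.frame(session = non_attack_sessions, split_lap = perm,
             provenance = "yoked")
}

#' Z-score values within subject
#'
#' Subtracts each subject's mean and divides by that subject's standard
#' deviation (n - 1 denominator).
#'
#' @param values Data.frame with columns `subject` and `value`.
#' @return The input with a `z` column appended.
#' @export
normalize_by_subject <- function(values) {
  stopifnot(all(c("subject", "value") %in% names(values)))
  split_idx <- split(seq_len(nrow(values)), values$subject)
  z <- numeric(nrow(values))
  for (s in names(split_idx)) {
    idx <- split_idx[[s]]
    if (length(idx) < 2L) {
      stop("subject ", s, " has fewer than 2 values")
    }
    sdv <- stats::sd(values$value[idx])
    if (!is.finite(sdv) || sdv == 0) {
      stop("subject ", s, " has zero within-subject standard deviation")
    }
    z[idx] <- (values$value[idx] - mean(values$value[idx])) / sdv
  }
  values$z <- z
  values
}
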