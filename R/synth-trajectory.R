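# Synthetic behavior: attack schedules and scripted lap-running trajectories.

#' Simulate the robot attack schedule for a session
#'
#' On Attack sessions, each lap from `first_eligible_lap` onward is attacked
#' independently with probability `attack_probability` when the rat crosses
#' the attack threshold.  Eligibility is inclusive at `first_eligible_lap`.
#' Non-attack session types never contain attacks.
#'
#' @param cfg A [task_config()].
#' @param n_laps Number of laps to schedule over (>= 0).
#' @param seed Integer seed (defaults to a stream derived from `cfg$seed`).
#' @return Strictly increasing integer vector of attacked lap indices.
#' @export
generate_attack_schedule <- function(cfg, n_laps,
                                     seed = derive_seed(cfg$seed, "attacks")) {
  stopifnot(inherits(cfg, "task_config"))
  if (!is.numeric(n_laps) || length(n_laps) != 1L || n_laps < 0) {
    stop("n_laps must be a non-negative number")
  }
  n_laps <- as.integer(n_laps)
  if (cfg$session_type != "attack" || n_laps < cfg$first_eligible_lap) {
    return(integer(0))
  }
  eligible <- seq.int(cfg$first_eligible_lap, n_laps)
  hit <- with_seed(seed,
                   stats::runif(length(eligible)) < cfg$attack_probability)
  eligible[hit]
}

#' Scripted behavior rates for the trajectory generator
#'
#' Controls how often and how strongly the generator scripts the behavioral
#' events the detectors are built to find.  Post-attack multipliers emulate
#' the behavioral change after the first attack (more aborts and pauses,
#' longer hesitation in the nest).
#'
#' @param mta_prob Probability of a scripted outbound mid-track abort per lap.
#' @param mta_prob_inbound Probability of a scripted inbound abort per lap.
#' @param pause_rate Expected number of scripted on-track pauses per outbound
#'   journey (Poisson).
#' @param pause_rate_inbound Expected pauses per inbound journey.
#' @param pause_duration Range (s) of scripted pause durations.
#' @param hesitation_meanlog,hesitation_sdlog Log-normal parameters of the
#'   nest hesitation dwell (s).
#' @param feeder_dwell Range (s) of dwell within 2 cm of the nest feeder.
#' @param mta_excursion Range (cm) of how far a scripted abort advances onto
#'   the track beyond the doorway.
#' @param run_speed Mean and SD (cm/s) of the running speed per journey.
#' @param post_attack_event_scale Multiplier on abort/pause rates after the
#'   first attack.
#' @param post_attack_hesitation_scale Multiplier on hesitation dwell after
#'   the first attack.
#' @param position_noise_sd SD (cm) of per-sample tracking jitter.
#' @return A list of class `behavior_rates`.
#' @export
behavior_rates <- function(mta_prob = 0.05,
                           mta_prob_inbound = 0.02,
                           pause_rate = 0.10,
                           pause_rate_inbound = 0.05,
                           pause_duration = c(0.7, 1.5),
                           hesitation_meanlog = log(4),
                           hesitation_sdlog = 0.4,
                           feeder_dwell = c(0.8, 1.6),
                           mta_excursion = c(10, 25),
                           run_speed = c(35, 3),
                           post_attack_event_scale = 2,
                           post_attack_hesitation_scale = 1.5,
                           position_noise_sd = 0.15) {
  rates <- list(mta_prob = mta_prob, mta_prob_inbound = mta_prob_inbound,
                pause_rate = pause_rate,
                pause_rate_inbound = pause_rate_inbound,
                pause_duration = pause_duration,
                hesitation_meanlog = hesitation_meanlog,
                hesitation_sdlog = hesitation_sdlog,
                feeder_dwell = feeder_dwell,
                mta_excursion = mta_excursion,
                run_speed = run_speed,
                post_attack_event_scale = post_attack_event_scale,
                post_attack_hesitation_scale = post_attack_hesitation_scale,
                position_noise_sd = position_noise_sd)
  probs <- c(mta_prob, mta_prob_inbound)
  if (any(probs < 0 | probs > 1)) stop("abort probabilities must be in [0, 1]")
  if (pause_rate < 0 || pause_rate_inbound < 0) {
    stop("pause rates must be non-negative")
  }
  if (any(pause_duration <= 0) || any(feeder_dwell <= 0)) {
    stop("durations must be positive")
  }
  class(rates) <- "behavior_rates"
  rates
}

# time spent with x in [xlo, xhi] between t0 and t1 on a piecewise-linear
# trace given by keypoints (kt, kx); exact integration per segment
pl_time_within <- function(kt, kx, t0, t1, xlo, xhi) {
  total <- 0
  n <- length(kt)
  i0 <- max(1L, findInterval(t0, kt))
  i1 <- min(n - 1L, findInterval(t1, kt) + 1L)
  if (i1 < i0) return(0)
  for (i in i0:i1) {
    ta <- kt[i]; tb <- kt[i + 1L]
    if (tb <= t0 || ta >= t1) next
    xa <- kx[i]; xb <- kx[i + 1L]
    # clip segment to [t0, t1]
    if (ta < t0) { xa <- xa + (xb - xa) * (t0 - ta) / (tb - ta); ta <- t0 }
    if (tb > t1) { xb <- kx[i] + (kx[i + 1L] - kx[i]) * (t1 - kt[i]) /
                     (kt[i + 1L] - kt[i]); tb <- t1 }
    if (tb <= ta) next
    if (xa == xb) {
      if (xa >= xlo && xa <= xhi) total <- total + (tb - ta)
    } else {
      # fraction of [ta, tb] with x in [xlo, xhi]
      f <- function(x) (x - xa) / (xb - xa)
      lo <- max(min(f(xlo), f(xhi)), 0)
      hi <- min(max(f(xlo), f(xhi)), 1)
      if (hi > lo) total <- total + (hi - lo) * (tb - ta)
    }
  }
  total
}

#' Generate a scripted lap-running trajectory with ground-truth labels
#'
#' Produces a 30 Hz position trace of a rat shuttling between the nest feeder
#' and the track feeder on the linear track, with scripted hesitations in the
#' nest/doorway, mid-track aborts, on-track pauses, and (on Attack sessions)
#' retreats immediately after crossing the attack threshold on attacked laps.
#' All scripted events are returned as ground truth, so behavior detectors
#' can be validated by round trip.
#'
#' @param cfg A [task_config()].
#' @param geom An [arena_geometry()].
#' @param rates A [behavior_rates()].
#' @param attack_laps Optional pre-drawn attack lap indices; by default drawn
#'   with [generate_attack_schedule()].
#' @param seed Integer seed (defaults to a stream derived from `cfg$seed`).
#' @return A list with `trajectory` (data.frame `t`, `x`, `y`, `tracked`),
#'   `ground_truth` (hesitations, mtas, pauses, attacks, laps, movement
#'   intervals) and `n_laps`.
#' @export
generate_trajectory <- function(cfg, geom, rates = behavior_rates(),
                                attack_laps = NULL,
                                seed = derive_seed(cfg$seed, "trajectory")) {
  stopifnot(inherits(cfg, "task_config"), inherits(geom, "arena_geometry"))
  z <- geom$zones
  door_end <- z$start[z$zone == "nest_side_track"]  # nest+doorway | track
  x_feed_nest <- geom$feeder_positions[["nest"]]
  x_feed_track <- geom$feeder_positions[["track"]]
  x_decel <- z$start[z$zone == "feeder"]          # slow approach to feeder
  v_slow <- 12
  x_stage <- (z$start[z$zone == "doorway"] + door_end) / 2  # doorway staging
  duration <- cfg$session_duration

  if (is.null(attack_laps)) {
    max_laps <- ceiling(duration / 5) + 10L
    attack_laps <- generate_attack_schedule(cfg, max_laps)
  }

  with_seed(seed, {
    # keypoint buffers (piecewise-linear noiseless trace)
    kt <- numeric(4096); kx <- numeric(4096); nk <- 0L
    push <- function(t, x) {
      nk <<- nk + 1L
      if (nk > length(kt)) {
        kt <<- c(kt, numeric(length(kt)))
        kx <<- c(kx, numeric(length(kx)))
      }
      kt[nk] <<- t; kx[nk] <<- x
    }
    tt <- 0; xx <- x_feed_nest
    push(tt, xx)
    dwell <- function(d) { tt <<- tt + d; push(tt, xx) }
    move_to <- function(x1, v) {
      if (abs(x1 - xx) < 1e-9) return(invisible())
      tt <<- tt + abs(x1 - xx) / v
      xx <<- x1
      push(tt, xx)
    }
    # time at which a move from (t0, x0) to (tt, xx) crossed xc
    crossing <- function(t0, x0, xc) t0 + (tt - t0) * (xc - x0) / (xx - x0)

    hes <- list(); mtas <- list(); pauses <- list(); attacks <- list()
    laps <- list()
    nest_entry <- 0; entered_from_track <- FALSE
    post_attack <- FALSE

    close_hesitation <- function(t_exit) {
      feeder_t <- pl_time_within(kt[seq_len(nk)], kx[seq_len(nk)],
                                 nest_entry, t_exit,
                                 x_feed_nest - 2, x_feed_nest + 2)
      hes[[length(hes) + 1L]] <<- data.frame(
        t_start = nest_entry, t_end = t_exit,
        duration = (t_exit - nest_entry) - feeder_t,
        feeder_time = feeder_t,
        entered_from_track = entered_from_track)
    }
    # outbound excursion past the doorway that turns back into the nest
    script_abort <- function(lap, v) {
      exc <- stats::runif(1, rates$mta_excursion[1], rates$mta_excursion[2])
      t0 <- tt; x0 <- xx
      move_to(door_end + exc, v)
      t_out <- crossing(t0, x0, door_end)
      close_hesitation(t_out)
      turn_dwell <- stats::runif(1, 0.25, 0.45)
      t_turn <- tt + turn_dwell / 2
      dwell(turn_dwell)
      t0 <- tt; x0 <- xx
      move_to(x_stage, v)
      t_back <- crossing(t0, x0, door_end)
      nest_entry <<- t_back; entered_from_track <<- TRUE
      dwell(stats::runif(1, 0.4, 0.8))
      mtas[[length(mtas) + 1L]] <<- data.frame(
        t_start = t_out, t_end = t_back, t_turn = t_turn, lap = lap,
        direction = "outbound", excursion = exc)
    }
    script_pauses <- function(lap, direction, xa, xb, v, rate) {
      n_p <- stats::rpois(1, rate)
      if (n_p == 0L) return(invisible())
      lo <- min(xa, xb) + 8; hi <- max(xa, xb) - 8
      xs <- sort(stats::runif(n_p, lo, hi))
      if (direction == "inbound") xs <- rev(xs)
      for (xp in xs) {
        move_to(xp, v)
        d_p <- stats::runif(1, rates$pause_duration[1],
                            rates$pause_duration[2])
        t0 <- tt
        dwell(d_p)
        pauses[[length(pauses) + 1L]] <<- data.frame(
          t_start = t0, t_end = tt, lap = lap, direction = direction,
          x = xp)
      }
    }

    lap <- 0L
    while (tt < duration) {
      lap <- lap + 1L
      esc <- if (post_attack) rates$post_attack_event_scale else 1
      hsc <- if (post_attack) rates$post_attack_hesitation_scale else 1
      # nest phase: feed then hesitate near the doorway
      move_to(x_feed_nest, 15)
      dwell(stats::runif(1, rates$feeder_dwell[1], rates$feeder_dwell[2]))
      move_to(x_stage, 15)
      dwell(hsc * stats::rlnorm(1, rates$hesitation_meanlog,
                                rates$hesitation_sdlog))
      v <- max(20, stats::rnorm(1, rates$run_speed[1], rates$run_speed[2]))
      if (stats::runif(1) < min(1, rates$mta_prob * esc)) script_abort(lap, v)
      # committed outbound run
      attacked <- lap %in% attack_laps
      t0 <- tt; x0 <- xx
      if (attacked) {
        move_to(geom$attack_threshold + 3, v)
        t_out <- crossing(t0, x0, door_end)
        close_hesitation(t_out)
        t_attack <- crossing(t0, x0, geom$attack_threshold)
        attacks[[length(attacks) + 1L]] <- data.frame(lap = lap,
                                                      t = t_attack)
        dwell(0.2)
        t0 <- tt; x0 <- xx
        move_to(x_stage, 50)                      # retreat to the nest
        nest_entry <- crossing(t0, x0, door_end)
        entered_from_track <- TRUE
        post_attack <- TRUE
        dwell(stats::rlnorm(1, rates$hesitation_meanlog + 0.5,
                            rates$hesitation_sdlog))
        t0 <- tt; x0 <- xx                        # re-run the outbound
        t_cross_out <- t0 + (door_end - x0) / v   # crossing is in first move
        script_pauses(lap, "outbound", door_end, x_decel, v,
                      rates$pause_rate * rates$post_attack_event_scale)
        move_to(x_decel, v)
        move_to(x_feed_track, v_slow)             # decelerate into the feeder
        close_hesitation(t_cross_out)
      } else {
        t_cross_out <- t0 + (door_end - x0) / v
        script_pauses(lap, "outbound", door_end, x_decel, v,
                      rates$pause_rate * esc)
        move_to(x_decel, v)
        move_to(x_feed_track, v_slow)
        close_hesitation(t_cross_out)
      }
      t_lap_start <- hes[[length(hes)]]$t_end
      t_out_feeder <- tt
      dwell(stats::runif(1, 1.0, 1.6))            # eat at the track feeder
      # inbound run, possibly with a scripted inbound abort
      v2 <- max(20, stats::rnorm(1, rates$run_speed[1], rates$run_speed[2]))
      if (stats::runif(1) < min(1, rates$mta_prob_inbound * esc)) {
        exc <- stats::runif(1, rates$mta_excursion[1], rates$mta_excursion[2])
        t0 <- tt
        move_to(x_feed_track - exc - 3, v2)
        turn_dwell <- stats::runif(1, 0.25, 0.45)
        t_turn <- tt + turn_dwell / 2
        dwell(turn_dwell)
        move_to(x_feed_track, v2)
        mtas[[length(mtas) + 1L]] <- data.frame(
          t_start = t0, t_end = tt, t_turn = t_turn, lap = lap,
          direction = "inbound", excursion = exc)
        dwell(0.5)
      }
      move_to(x_decel, v_slow)                   # pull away from the feeder
      script_pauses(lap, "inbound", x_decel, door_end, v2,
                    rates$pause_rate_inbound * esc)
      t0 <- tt; x0 <- xx
      move_to(x_feed_nest, v2)
      nest_entry <- crossing(t0, x0, door_end)
      entered_from_track <- TRUE
      laps[[lap]] <- data.frame(lap = lap, t_start = t_lap_start,
                                t_out_feeder = t_out_feeder, t_end = tt,
                                attacked = attacked)
    }

    kt <- kt[seq_len(nk)]; kx <- kx[seq_len(nk)]
    tg <- seq(0, duration, by = 1 / geom$position_rate)
    x_clean <- stats::approx(kt, kx, xout = tg, rule = 2)$y
    x <- x_clean + stats::rnorm(length(tg), 0, rates$position_noise_sd)
    x <- pmin(pmax(x, 0), geom$track_length)
    y <- geom$track_width / 2 +
      stats::rnorm(length(tg), 0, rates$position_noise_sd)
    traj <- data.frame(t = tg, x = x, y = y, tracked = TRUE)

    bind <- function(lst, empty_cols) {
      if (length(lst) == 0L) return(empty_cols)
      do.call(rbind, lst)
    }
    gt_hes <- bind(hes, data.frame(t_start = numeric(0), t_end = numeric(0),
                                   duration = numeric(0),
                                   feeder_time = numeric(0),
                                   entered_from_track = logical(0)))
    gt_mta <- bind(mtas, data.frame(t_start = numeric(0), t_end = numeric(0),
                                    t_turn = numeric(0), lap = integer(0),
                                    direction = character(0),
                                    excursion = numeric(0)))
    gt_pause <- bind(pauses, data.frame(t_start = numeric(0),
                                        t_end = numeric(0), lap = integer(0),
                                        direction = character(0),
                                        x = numeric(0)))
    gt_attack <- bind(attacks, data.frame(lap = integer(0), t = numeric(0)))
    gt_laps <- bind(laps, data.frame(lap = integer(0), t_start = numeric(0),
                                     t_out_feeder = numeric(0),
                                     t_end = numeric(0),
                                     attacked = logical(0)))
    # drop events past the session end and laps not completed
    clamp <- function(df) df[df$t_end <= duration & df$t_start >= 0, ,
                             drop = FALSE]
    gt_hes <- clamp(gt_hes); gt_mta <- clamp(gt_mta)
    gt_pause <- clamp(gt_pause); gt_laps <- clamp(gt_laps)
    gt_attack <- gt_attack[gt_attack$t <= duration, , drop = FALSE]

    # movement epochs from the noiseless trace (|v| >= 5 cm/s)
    v_clean <- c(0, diff(x_clean)) * geom$position_rate
    moving <- abs(gaussian_smooth(v_clean, 3)) >= 5
    runs <- logical_runs(moving)
    movement <- if (nrow(runs) == 0L) empty_intervals() else
      data.frame(t_start = tg[runs[, "first"]], t_end = tg[runs[, "last"]])

    list(trajectory = traj,
         ground_truth = list(hesitations = gt_hes, mtas = gt_mta,
                             pauses = gt_pause, attacks = gt_attack,
                             laps = gt_laps, movement = movement),
         n_laps = nrow(gt_laps),
         x_clean = x_clean)
  })
}
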