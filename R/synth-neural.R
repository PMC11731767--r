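# Synthetic neural activity: generative place fields, a theta cycle schedule,
# and inhomogeneous-Poisson spike emission.

#' Generate direction-selective generative place fields
#'
#' Pre-attack fields tile the nest, doorway and running track uniformly with
#' alternating direction preference, and over-represent the reward site (the
#' feeder platform holds 20% of the cells, as hippocampal maps over-represent
#' goal locations).  The robot bay frontage — walled off outside Attack
#' sessions — carries passage occupancy but no pre-attack field centers.
#' After the first attack a fraction of cells remaps: remapping cells are
#' drawn preferentially from those tuned to the reward site, and each gains a
#' post-attack-only field clustered tightly on the robot bay center, so the
#' remapped population carries a coherent representation of the threat
#' location traded against the reward representation.
#'
#' @param n_cells Number of cells.
#' @param geom An [arena_geometry()].
#' @param remap_fraction Fraction of cells gaining a robot-zone field after
#'   the first attack (default 0.3).
#' @param peak_rate Range (spikes/s) of field peak rates (default 4-10).
#' @param width Range (cm) of field Gaussian SD.
#' @param remap_peak_rate Range (spikes/s) of the new threat fields
#'   (default 4-10, same as established fields).
#' @param post_attack_pre_scale Multiplier applied post-attack to the
#'   original field of a remapping cell (default 1: the old field keeps its
#'   strength and the threat field is purely additive).
#' @param seed Integer seed.
#' @return A data.frame of class `place_fields` with one row per field:
#'   `cell_id`, `center`, `width`, `peak_rate`, `direction`
#'   (outbound/inbound/both/stationary), `post_attack_only`, `post_scale`
#'   (rate multiplier once the first attack has happened).
#' @export
generate_place_fields <- function(n_cells, geom, remap_fraction = 0.3,
                                  peak_rate = c(4, 10), width = c(4, 8),
                                  remap_peak_rate = c(4, 10),
                                  post_attack_pre_scale = 1,
                                  seed = 1L) {
  if (remap_fraction < 0 || remap_fraction > 1) {
    stop("remap_fraction must be in [0, 1]")
  }
  empty <- data.frame(cell_id = integer(0), center = numeric(0),
                      width = numeric(0), peak_rate = numeric(0),
                      direction = character(0), post_attack_only = logical(0),
                      post_scale = numeric(0))
  if (n_cells == 0L) return(structure(empty, class = c("place_fields",
                                                       "data.frame")))
  with_seed(seed, {
    # pre-attack coverage: nest through the running track, plus the feeder
    # platform; the robot bay frontage (walled off outside Attack sessions)
    # is crossed at speed but carries no pre-attack field centers
    z0 <- geom$zones
    main_span <- c(2, z0$start[z0$zone == "robot"])
    feeder_span <- c(z0$start[z0$zone == "feeder"] - 1,
                     geom$track_length - 1.5)
    n_feeder <- max(1L, round(0.2 * n_cells))   # reward-site over-representation
    n_main <- n_cells - n_feeder
    centers <- c(seq(main_span[1], main_span[2], length.out = n_main) +
                   stats::runif(n_main, -2, 2),
                 stats::runif(n_feeder, feeder_span[1], feeder_span[2]))
    centers <- pmin(pmax(centers, 0), geom$track_length)
    pre <- data.frame(
      cell_id = seq_len(n_cells),
      center = centers[sample.int(n_cells)],
      width = stats::runif(n_cells, width[1], width[2]),
      peak_rate = stats::runif(n_cells, peak_rate[1], peak_rate[2]),
      direction = rep_len(c("outbound", "inbound"), n_cells),
      post_attack_only = FALSE, post_scale = 1)
    n_remap <- round(remap_fraction * n_cells)
    if (n_remap > 0L) {
      # new threat fields concentrate on the final approach and the robot
      # bay itself (the far portion of the robot-side track plus the robot
      # zone), where the tuning shift is observed
      z <- geom$zones
      lo <- z$end[z$zone == "robot_side_track"] - 6
      hi <- z$end[z$zone == "robot"]
      # cells formerly tuned to the reward site remap preferentially: the
      # representation trades the feeder for the threat
      w <- exp((pre$center - geom$track_length) / 6)
      remap_cells <- sample.int(n_cells, n_remap, prob = w)
      # new fields cluster on the robot itself, so the remapped population
      # carries a coherent representation of the threat location
      robot_center <- (z$start[z$zone == "robot"] +
                         z$end[z$zone == "robot"]) / 2
      centers_new <- pmin(pmax(stats::rnorm(n_remap, robot_center, 3),
                               lo + 2), hi - 2)
      post <- data.frame(
        cell_id = remap_cells,
        center = centers_new,
        width = stats::runif(n_remap, width[1], width[2]),
        peak_rate = stats::runif(n_remap, remap_peak_rate[1],
                                 remap_peak_rate[2]),
        direction = sample(c("outbound", "inbound"), n_remap, replace = TRUE),
        post_attack_only = TRUE, post_scale = 1)
      pre$post_scale[pre$cell_id %in% remap_cells] <- post_attack_pre_scale
      pre <- rbind(pre, post)
    }
    structure(pre[order(pre$cell_id), ],
              class = c("place_fields", "data.frame"))
  })
}

#' Generate a theta cycle schedule over movement epochs
#'
#' Lays down a peak/trough/next-peak schedule at the given base frequency
#' within each movement interval.  The descending (peak to trough) and
#' ascending (trough to next peak) half-cycle durations follow the configured
#' ascending:descending ratio, so the cycle-by-cycle segmentation of the
#' matching LFP has a closed-form truth.
#'
#' @param movement Intervals data.frame (`t_start`, `t_end`) of movement.
#' @param freq Base theta frequency in Hz (default 8).
#' @param asym_ratio Ascending/descending duration ratio (default 1 =
#'   symmetric).
#' @param period_jitter Fractional SD of cycle-period jitter (default 0.02).
#' @param seed Integer seed.
#' @return A data.frame of class `theta_schedule` with `t_peak`, `t_trough`,
#'   `t_next_peak`.
#' @export
generate_theta_schedule <- function(movement, freq = 8, asym_ratio = 1,
                                    period_jitter = 0.02, seed = 1L) {
  stopifnot(freq > 0, asym_ratio > 0)
  with_seed(seed, {
    peaks <- numeric(0); troughs <- numeric(0); nxt <- numeric(0)
    for (i in seq_len(nrow(movement))) {
      t0 <- movement$t_start[i]; t1 <- movement$t_end[i]
      tt <- t0
      repeat {
        period <- (1 / freq) * max(0.5, 1 + stats::rnorm(1, 0, period_jitter))
        d_desc <- period / (1 + asym_ratio)
        d_asc <- period - d_desc
        if (tt + period > t1) break
        peaks <- c(peaks, tt)
        troughs <- c(troughs, tt + d_desc)
        nxt <- c(nxt, tt + period)
        tt <- tt + period
      }
    }
    structure(data.frame(t_peak = peaks, t_trough = troughs,
                         t_next_peak = nxt),
              class = c("theta_schedule", "data.frame"))
  })
}

# Evaluate a cell's field map at positions x: sum over its field rows that
# match the direction (+1 outbound, -1 inbound, 0 stationary) and epoch.
# Post-attack, post_attack_only rows switch on and original rows of
# remapping cells are scaled by post_scale.  direction = NULL pools all
# field rows at full strength (the epoch-invariant union map used for
# offline event participation).
eval_fields <- function(rows, x, direction = NULL, post_attack = FALSE) {
  out <- numeric(length(x))
  for (j in seq_len(nrow(rows))) {
    f <- rows[j, ]
    amp <- f$peak_rate
    if (!is.null(direction)) {
      if (isTRUE(f$post_attack_only)) {
        if (!post_attack) next
      } else if (post_attack) {
        amp <- amp * (f$post_scale %||% 1)
      }
      ok <- switch(f$direction,
                   outbound = direction > 0,
                   inbound = direction < 0,
                   stationary = direction == 0,
                   both = rep(TRUE, length(x)))
      if (!any(ok)) next
    } else {
      ok <- rep(TRUE, length(x))
    }
    d2 <- (x - f$center)^2
    g <- amp * exp(-d2 / (2 * f$width^2))
    out <- out + ifelse(ok, g, 0)
  }
  out
}

#' Emit spike trains from generative fields under theta gating
#'
#' During movement, each cell fires as an inhomogeneous Poisson process whose
#' rate is its field map evaluated at the animal's current position and
#' direction.  The local component is gated to the descending phase of theta;
#' an optional look-ahead offset shifts the position at which fields are
#' evaluated during the ascending phase (emulating prospective sweeps).
#' Gating is compensated by the inverse half-cycle fraction so the expected
#' in-field spike count still equals rate x occupancy time.  During scripted
#' high-synchrony windows, each cell participates stochastically with
#' probability proportional to its field value at the window's content
#' location, evaluated on the epoch-invariant union map (plus a small
#' content-free participation floor shared by all cells); a participating
#' cell emits one or a few spikes within the window.  Sparse participation
#' keeps single-event posteriors graded rather than degenerate, as in real
#' population burst decoding.
#'
#' @param traj Trajectory data.frame (`t`, `x`, ...).
#' @param fields A [generate_place_fields()] table.
#' @param theta A [generate_theta_schedule()] table covering movement.
#' @param hse_windows Data.frame (`t_start`, `t_end`, `x_content`) of scripted
#'   population-burst windows in stillness, or NULL.
#' @param attack_time Time (s) of the first attack; post-attack-only fields
#'   are inactive before it (`Inf` = never active).
#' @param lookahead_cm Ascending-phase look-ahead offset in cm (default 8).
#' @param baseline_rate Baseline rate (spikes/s) for cells with any positive
#'   field (default 0.3); totally silent cells stay silent.
#' @param hse_participation Peak participation probability: a cell whose
#'   union-map field value at the content location equals the ensemble's
#'   maximum peak rate participates with this probability (default 0.85).
#' @param hse_p0 Content-free participation floor shared by all cells
#'   (default 0.05).
#' @param hse_extra_spikes Poisson mean of extra spikes beyond the first for
#'   a participating cell (default 1.5).
#' @param stationary_speed Speed threshold (cm/s) between moving and
#'   stationary (default 5).
#' @param dt Emission grid step in seconds (default 0.004).
#' @param seed Integer seed.
#' @param cell_ids Optional vector of known cell ids; fields referencing any
#'   other id raise an integrity error.
#' @return A data.frame of class `spike_ensemble` with `cell_id` and `t`,
#'   sorted by time.
#' @export
generate_spike_trains <- function(traj, fields, theta, hse_windows = NULL,
                                  attack_time = Inf, lookahead_cm = 8,
                                  baseline_rate = 0.3,
                                  hse_participation = 0.85, hse_p0 = 0.05,
                                  hse_extra_spikes = 1.5,
                                  stationary_speed = 5,
                                  dt = 0.004, seed = 1L, cell_ids = NULL) {
  if (!is.null(cell_ids) && !all(fields$cell_id %in% cell_ids)) {
    bad <- setdiff(unique(fields$cell_id), cell_ids)
    stop("fields reference unknown cell ids: ", paste(bad, collapse = ", "))
  }
  cells <- sort(unique(fields$cell_id))
  if (!is.null(hse_windows) && nrow(hse_windows) > 0L &&
      is.null(hse_windows$x_content)) {
    stop("hse_windows must carry an x_content column")
  }
  t_end <- max(traj$t)
  tf <- seq(0, t_end, by = dt)
  xf <- stats::approx(traj$t, traj$x, xout = tf, rule = 2)$y
  vf <- gaussian_smooth(c(0, diff(xf)) / dt, 0.1 / dt)
  dirf <- integer(length(tf))
  dirf[vf >= stationary_speed] <- 1L
  dirf[vf <= -stationary_speed] <- -1L

  # theta half-cycle membership and gating gain on the fine grid
  n_cyc <- nrow(theta)
  in_desc <- rep(FALSE, length(tf)); in_asc <- rep(FALSE, length(tf))
  gain_desc <- numeric(length(tf)); gain_asc <- numeric(length(tf))
  if (n_cyc > 0L) {
    idx <- findInterval(tf, theta$t_peak)
    has <- idx > 0L
    i <- idx[has]
    period <- theta$t_next_peak - theta$t_peak
    d_desc <- theta$t_trough - theta$t_peak
    d_asc <- theta$t_next_peak - theta$t_trough
    tt <- tf[has]
    desc <- tt < theta$t_trough[i]
    asc <- !desc & tt < theta$t_next_peak[i]
    in_desc[has] <- desc
    in_asc[has] <- asc
    gain_desc[has][desc] <- (period[i] / d_desc[i])[desc]
    gain_asc[has][asc] <- (period[i] / d_asc[i])[asc]
  }
  in_theta <- in_desc | in_asc
  moving <- dirf != 0L
  post <- tf >= attack_time

  # per-window participation reference: the union-map value of the cell best
  # tuned to that window's content, so each burst recruits its own coalition
  hse_ref <- NULL
  if (!is.null(hse_windows) && nrow(hse_windows) > 0L) {
    vals <- vapply(cells, function(cid) {
      eval_fields(fields[fields$cell_id == cid, , drop = FALSE],
                  hse_windows$x_content, direction = NULL)
    }, numeric(nrow(hse_windows)))
    hse_ref <- apply(matrix(vals, nrow = nrow(hse_windows)), 1L, max)
  }

  with_seed(seed, {
    all_spikes <- vector("list", length(cells))
    for (k in seq_along(cells)) {
      rows <- fields[fields$cell_id == cells[k], , drop = FALSE]
      if (max(rows$peak_rate) <= 0) next
      spikes <- numeric(0)
      # moving, theta-gated local + look-ahead components
      mv <- which(moving)
      if (length(mv) > 0L) {
        r <- numeric(length(mv))
        sub_desc <- in_desc[mv]; sub_asc <- in_asc[mv]
        sub_none <- !in_theta[mv]
        x_mv <- xf[mv]; d_mv <- dirf[mv]; p_mv <- post[mv]
        a_local_pre <- eval_fields(rows, x_mv, d_mv, post_attack = FALSE)
        a_local_post <- eval_fields(rows, x_mv, d_mv, post_attack = TRUE)
        a_local <- ifelse(p_mv, a_local_post, a_local_pre)
        x_ahead <- x_mv + lookahead_cm * d_mv
        a_ahead_pre <- eval_fields(rows, x_ahead, d_mv, post_attack = FALSE)
        a_ahead_post <- eval_fields(rows, x_ahead, d_mv, post_attack = TRUE)
        a_ahead <- ifelse(p_mv, a_ahead_post, a_ahead_pre)
        r[sub_desc] <- a_local[sub_desc] * gain_desc[mv][sub_desc]
        r[sub_asc] <- a_ahead[sub_asc] * gain_asc[mv][sub_asc]
        r[sub_none] <- a_local[sub_none]
        counts <- stats::rpois(length(mv), r * dt)
        nz <- which(counts > 0L)
        if (length(nz) > 0L) {
          st <- rep(tf[mv][nz], counts[nz]) +
            stats::runif(sum(counts[nz])) * dt
          spikes <- c(spikes, st)
        }
      }
      # stationary-preferring / omnidirectional fields outside movement
      st_rows <- rows[rows$direction %in% c("stationary", "both"), ,
                      drop = FALSE]
      if (nrow(st_rows) > 0L) {
        still <- which(!moving)
        if (length(still) > 0L) {
          r <- eval_fields(st_rows, xf[still], dirf[still],
                           post_attack = FALSE)
          counts <- stats::rpois(length(still), r * dt)
          nz <- which(counts > 0L)
          if (length(nz) > 0L) {
            spikes <- c(spikes, rep(tf[still][nz], counts[nz]) +
                          stats::runif(sum(counts[nz])) * dt)
          }
        }
      }
      # homogeneous baseline
      if (baseline_rate > 0) {
        n_b <- stats::rpois(1, baseline_rate * t_end)
        spikes <- c(spikes, stats::runif(n_b, 0, t_end))
      }
      # scripted high-synchrony participation (epoch-invariant union map):
      # a cell joins a burst with probability proportional to its field
      # value at the content location, emitting one or a few spikes
      if (!is.null(hse_windows) && nrow(hse_windows) > 0L) {
        w_dur <- hse_windows$t_end - hse_windows$t_start
        w_val <- eval_fields(rows, hse_windows$x_content, direction = NULL)
        ref <- hse_ref                           # per-window best-tuned cell
        p <- pmin(hse_p0 + hse_participation * w_val / pmax(ref, 1e-9), 0.95)
        joins <- stats::runif(length(p)) < p
        n_w <- ifelse(joins, 1L + stats::rpois(length(p), hse_extra_spikes),
                      0L)
        nz <- which(n_w > 0L)
        if (length(nz) > 0L) {
          st <- rep(hse_windows$t_start[nz], n_w[nz]) +
            stats::runif(sum(n_w[nz])) * rep(w_dur[nz], n_w[nz])
          spikes <- c(spikes, st)
        }
      }
      if (length(spikes) > 0L) {
        all_spikes[[k]] <- data.frame(cell_id = cells[k], t = sort(spikes))
      }
    }
    out <- do.call(rbind, all_spikes)
    if (is.null(out)) out <- data.frame(cell_id = integer(0), t = numeric(0))
    out <- out[order(out$t), ]
    rownames(out) <- NULL
    structure(out, class = c("spike_ensemble", "data.frame"))
  })
}
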