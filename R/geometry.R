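# Task configuration, arena geometry and the spatial tuning grid.

#' Task configuration for a session
#'
#' Describes one behavioral session on the L-shaped linear track. On Attack
#' sessions the guarding robot may attack when the rat crosses an unmarked
#' threshold on the track: the first attack cannot occur before
#' `first_eligible_lap` and from that lap onward each threshold crossing is
#' attacked independently with probability `attack_probability`.
#'
#' @param session_type One of `"linear_track"`, `"novelty"`, `"attack"`.
#' @param attack_probability Per-eligible-lap attack probability (default 0.2).
#' @param first_eligible_lap First lap (inclusive) on which an attack may
#'   occur (default 15).
#' @param session_duration Session length in seconds (default 3600).
#' @param pellet_count_per_feeder Pellets delivered per feeder visit
#'   (metadata; default 2).
#' @param seed Master integer seed for the synthetic generators.
#' @return An object of class `task_config`.
#' @export
task_config <- function(session_type = c("attack", "linear_track", "novelty"),
                        attack_probability = 0.2,
                        first_eligible_lap = 15L,
                        session_duration = 3600,
                        pellet_count_per_feeder = 2L,
                        seed = 1L) {
  session_type <- match.arg(session_type)
  if (!is.numeric(attack_probability) || attack_probability < 0 ||
      attack_probability > 1) {
    stop("attack_probability must lie in [0, 1]")
  }
  if (first_eligible_lap < 1) stop("first_eligible_lap must be >= 1")
  if (session_duration <= 0) stop("session_duration must be positive")
  structure(
    list(session_type = session_type,
         attack_probability = attack_probability,
         first_eligible_lap = as.integer(first_eligible_lap),
         session_duration = session_duration,
         pellet_count_per_feeder = as.integer(pellet_count_per_feeder),
         seed = as.integer(seed)),
    class = "task_config")
}

#' Arena geometry for the predator-guarded linear track
#'
#' The long axis of the arena is tiled by six contiguous, ordered zones:
#' Nest, Doorway, Nest-Side Track, Robot-Side Track, Robot, and Feeder.
#' The attack threshold is the boundary between the nest-side and robot-side
#' halves of the track.  Default boundaries are derived proportionally from
#' the published arena dimensions (19 cm nest, 67 cm track, 22 cm robot bay,
#' 111 cm total); exact zone coordinates are configurable.
#'
#' @param track_length Arena long-axis length in cm (default 111).
#' @param zone_bounds Named numeric vector of zone start positions (cm) in the
#'   order nest, doorway, nest_side_track, robot_side_track, robot, feeder.
#'   Zones tile `[0, track_length]`.
#' @param position_rate Position sampling rate in Hz (default 30).
#' @param track_width Arena width in cm (default 26).
#' @return An object of class `arena_geometry` with a `zones` table, the
#'   `attack_threshold` and feeder positions.
#' @export
arena_geometry <- function(track_length = 111,
                           zone_bounds = c(nest = 0, doorway = 15,
                                           nest_side_track = 19,
                                           robot_side_track = 52.5,
                                           robot = 86, feeder = 104),
                           position_rate = 30,
                           track_width = 26) {
  needed <- c("nest", "doorway", "nest_side_track", "robot_side_track",
              "robot", "feeder")
  if (!identical(names(zone_bounds), needed)) {
    stop("zone_bounds must be named, in order: ",
         paste(needed, collapse = ", "))
  }
  starts <- as.numeric(zone_bounds)
  ends <- c(starts[-1L], track_length)
  if (starts[1L] != 0 || any(diff(starts) <= 0) ||
      ends[length(ends)] != track_length || any(ends <= starts)) {
    stop("zones must be contiguous, ordered and tile [0, track_length]")
  }
  if (position_rate <= 0) stop("position_rate must be positive")
  zones <- data.frame(zone = needed, start = starts, end = ends,
                      stringsAsFactors = FALSE)
  structure(
    list(track_length = track_length,
         zones = zones,
         attack_threshold = zone_bounds[["robot_side_track"]],
         feeder_positions = c(nest = mean(c(starts[1L], ends[1L])),
                              track = track_length - 1.5),
         position_rate = position_rate,
         track_width = track_width),
    class = "arena_geometry")
}

#' Classify long-axis positions into arena zones
#'
#' @param x Long-axis positions in cm.
#' @param geom An [arena_geometry()].
#' @return A factor with the zone label of each position (levels in arena
#'   order); `NA` for positions outside `[0, track_length]` or untracked.
#' @export
zone_of <- function(x, geom) {
  z <- geom$zones
  idx <- findInterval(x, c(z$start, geom$track_length),
                      rightmost.closed = TRUE)
  idx[idx < 1L | idx > nrow(z)] <- NA_integer_
  factor(z$zone[idx], levels = z$zone)
}

# zone labels covering the running track proper
track_zones <- function() c("nest_side_track", "robot_side_track")

#' Spatial tuning grid: 64 positional bins by 3 direction bins
#'
#' Spiking activity is binned into 64 equal-width spatial segments along the
#' long axis of the track crossed with 3 direction-of-travel bins (moving
#' toward the robot, stationary, moving toward the nest), giving 192 bins.
#'
#' @param geom An [arena_geometry()].
#' @param n_pos Number of positional bins (default 64).
#' @return An object of class `tuning_grid` with bin edges, centers, the
#'   direction levels and the total bin count.
#' @export
tuning_grid <- function(geom, n_pos = 64L) {
  n_pos <- as.integer(n_pos)
  if (n_pos < 1L) stop("n_pos must be >= 1")
  edges <- seq(0, geom$track_length, length.out = n_pos + 1L)
  directions <- c("outbound", "stationary", "inbound")
  structure(
    list(edges = edges,
         centers = (edges[-1L] + edges[-length(edges)]) / 2,
         bin_width = diff(edges[1:2]),
         directions = directions,
         n_pos = n_pos,
         n_bins = n_pos * length(directions)),
    class = "tuning_grid")
}

# flat bin index for (direction index, positional bin index); direction-major
grid_bin <- function(grid, dir_idx, pos_idx) {
  (dir_idx - 1L) * grid$n_pos + pos_idx
}

# positional bin of long-axis positions (clamped into [1, n_pos])
pos_bin_of <- function(x, grid) {
  b <- findInterval(x, grid$edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), grid$n_pos)
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("Arena geometry:", x$track_length, "cm long axis,",
      "attack threshold at", x$attack_threshold, "cm\n")
  print(x$zones, row.names = FALSE)
  invisible(x)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Session type:", x$session_type,
      "| duration:", x$session_duration, "s",
      "| seed:", x$seed, "\n")
  if (x$session_type == "attack") {
    cat("Attack probability", x$attack_probability,
        "per eligible lap from lap", x$first_eligible_lap, "\n")
  }
  invisible(x)
}
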