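# Session-bundle I/O and the end-to-end analysis pipeline.

#' Write a session bundle to disk
#'
#' Writes `positions.csv` (t_s, x_cm, y_cm, tracked), `spikes.csv` (cell_id,
#' t_s), `cells.csv` (waveform metrics), `lfp.csv` (one column per channel,
#' microvolts; sampling rate in the metadata), `ground_truth.json` (when the
#' session is synthetic) and `session.yaml` (configuration and geometry).
#'
#' @param session A [generate_session()] result (or a compatible list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- session$trajectory
  data.table::fwrite(data.frame(t_s = tr$t, x_cm = tr$x, y_cm = tr$y,
                                tracked = tr$tracked),
                     file.path(dir, "positions.csv"))
  data.table::fwrite(data.frame(cell_id = session$spikes$cell_id,
                                t_s = session$spikes$t),
                     file.path(dir, "spikes.csv"))
  data.table::fwrite(session$cells, file.path(dir, "cells.csv"))
  meta <- list(
    session_type = session$config$session_type,
    session_duration = session$config$session_duration,
    attack_probability = session$config$attack_probability,
    first_eligible_lap = session$config$first_eligible_lap,
    pellet_count_per_feeder = session$config$pellet_count_per_feeder,
    seed = session$config$seed,
    geometry = list(track_length = session$geometry$track_length,
                    zone_start = as.list(stats::setNames(
                      session$geometry$zones$start,
                      session$geometry$zones$zone)),
                    position_rate = session$geometry$position_rate,
                    track_width = session$geometry$track_width))
  if (!is.null(session$lfp)) {
    data.table::fwrite(as.data.frame(session$lfp$samples),
                       file.path(dir, "lfp.csv"))
    meta$lfp <- list(fs_hz = session$lfp$fs, t0_s = session$lfp$t0,
                     channels = session$lfp$channel_ids)
  }
  yaml::write_yaml(meta, file.path(dir, "session.yaml"))
  if (!is.null(session$ground_truth)) {
    jsonlite::write_json(session$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a session bundle from disk
#'
#' Validates the schema (required columns, monotone position timestamps) and
#' reports offending files and line numbers.
#'
#' @param dir Bundle directory written by [write_bundle()] (or assembled by
#'   hand in the same layout).
#' @return An object of class `session_bundle`.
#' @export
read_bundle <- function(dir) {
  need <- file.path(dir, c("positions.csv", "spikes.csv", "cells.csv",
                           "session.yaml"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) {
    stop("bundle incomplete; missing: ",
         paste(basename(missing), collapse = ", "))
  }
  pos <- as.data.frame(data.table::fread(file.path(dir, "positions.csv")))
  for (col in c("t_s", "x_cm", "y_cm")) {
    if (!col %in% names(pos)) {
      stop("positions.csv: missing column ", col)
    }
  }
  bad <- which(diff(pos$t_s) <= 0)
  if (length(bad) > 0L) {
    stop("positions.csv: time not strictly increasing at line ", bad[1L] + 2L)
  }
  spk <- as.data.frame(data.table::fread(file.path(dir, "spikes.csv")))
  if (!all(c("cell_id", "t_s") %in% names(spk))) {
    stop("spikes.csv: needs columns cell_id, t_s")
  }
  cells <- as.data.frame(data.table::fread(file.path(dir, "cells.csv")))
  meta <- yaml::read_yaml(file.path(dir, "session.yaml"))
  lfp <- NULL
  lfp_file <- file.path(dir, "lfp.csv")
  if (file.exists(lfp_file)) {
    if (is.null(meta$lfp$fs_hz)) stop("session.yaml: missing lfp fs_hz")
    m <- as.matrix(data.table::fread(lfp_file))
    lfp <- lfp_signal(m, meta$lfp$fs_hz, t0 = meta$lfp$t0_s %||% 0)
  }
  gt <- NULL
  gt_file <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_file)) {
    gt <- jsonlite::fromJSON(gt_file)
  }
  tracked <- if ("tracked" %in% names(pos)) as.logical(pos$tracked) else
    rep(TRUE, nrow(pos))
  geom_meta <- meta$geometry
  geom <- if (is.null(geom_meta)) arena_geometry() else
    arena_geometry(track_length = geom_meta$track_length,
                   zone_bounds = unlist(geom_meta$zone_start),
                   position_rate = geom_meta$position_rate %||% 30,
                   track_width = geom_meta$track_width %||% 26)
  structure(list(
    trajectory = data.frame(t = pos$t_s, x = pos$x_cm, y = pos$y_cm,
                            tracked = tracked),
    spikes = data.frame(cell_id = spk$cell_id, t = spk$t_s),
    cells = cells, lfp = lfp, meta = meta, geometry = geom,
    ground_truth = gt, path = dir),
    class = "session_bundle")
}

#' Run the full analysis pipeline on one session bundle
#'
#' Executes the stages in dependency order — behavior, LFP state, transient
#' events, tuning curves, decoding — and returns a report.  Stages that
#' cannot run (no LFP, fewer than 10 putative pyramidal cells, no pre/post
#' split) are skipped with an explicit report entry, never silently.
#'
#' @param bundle A [read_bundle()] result or a [generate_session()] object.
#' @param split_lap Optional yoked split lap for non-attack sessions; attack
#'   sessions split at their first recorded attack.
#' @param seed Integer seed for any stage randomness.
#' @param state_bin Spectrogram bin length (s) for state classification.
#' @return An object of class `analysis_report`.
#' @export
run_session <- function(bundle, split_lap = NULL, seed = 1L,
                        state_bin = 1) {
  geom <- bundle$geometry %||% arena_geometry()
  traj <- bundle$trajectory
  spikes <- bundle$spikes
  skipped <- list()
  log <- list()

  # --- behavior ------------------------------------------------------------
  seg <- segment_journeys(traj, geom)
  attacks <- NULL
  gt <- bundle$ground_truth
  if (!is.null(gt) && !is.null(gt$attacks) && length(gt$attacks) > 0 &&
      NROW(gt$attacks) > 0) {
    attacks <- as.data.frame(gt$attacks)
  }
  hes <- measure_hesitation(traj, geom)
  mtas <- detect_mtas(traj, seg$journeys, attacks)
  pauses <- detect_pauses(traj, seg$journeys)
  log$behavior <- c(journeys = nrow(seg$journeys), laps = seg$n_laps,
                    hesitations = nrow(hes), mtas = nrow(mtas),
                    pauses = nrow(pauses))

  # --- LFP state -----------------------------------------------------------
  state <- NULL; cycles <- NULL; psd <- NULL
  if (is.null(bundle$lfp)) {
    skipped$lfpstate <- "no LFP in bundle"
  } else {
    lfp <- maybe_decimate(bundle$lfp)
    state <- classify_state(lfp, bin_length = state_bin)
    cycles <- segment_theta_cycles(lfp, state)
    psd <- compute_psd(lfp, bin_length = state_bin)
    log$lfpstate <- c(theta_bins = sum(state$state == "theta"),
                      lia_bins = sum(state$state == "lia"),
                      theta_cycles = nrow(cycles))
  }

  # --- transients ----------------------------------------------------------
  pyramidal <- classify_pyramidal(bundle$cells)
  pyr_ids <- bundle$cells$cell_id[pyramidal]
  pyr_spikes <- spikes[spikes$cell_id %in% pyr_ids, , drop = FALSE]
  swrs <- NULL; hses <- NULL; overlap <- NULL
  if (!is.null(bundle$lfp)) {
    ch <- unname(select_swr_channel(bundle$lfp)[1L])
    swrs <- detect_swrs(bundle$lfp, ch)
  } else {
    skipped$swr <- "no LFP in bundle"
  }
  if (nrow(pyr_spikes) > 0L) {
    hses <- detect_hses(pyr_spikes,
                        t_range = c(min(traj$t), max(traj$t)))
  } else {
    skipped$hse <- "no putative pyramidal spikes"
  }
  if (!is.null(swrs) && !is.null(hses)) overlap <- overlap_summary(swrs, hses)
  log$transients <- c(swrs = NROW(swrs), hses = NROW(hses),
                      pyramidal_cells = length(pyr_ids))

  # --- split time ----------------------------------------------------------
  split_time <- NULL
  if (!is.null(attacks) && nrow(attacks) > 0L) {
    split_time <- min(attacks$t)
  } else if (!is.null(split_lap)) {
    laps <- if (!is.null(gt) && NROW(gt$laps) > 0) as.data.frame(gt$laps)
      else NULL
    if (!is.null(laps) && split_lap <= nrow(laps)) {
      split_time <- laps$t_start[laps$lap == split_lap]
    }
  }

  # --- tuning + decoding ---------------------------------------------------
  curves <- NULL; shift <- NULL; cross <- NULL; theta_dec <- NULL
  if (is.null(cycles) || nrow(cycles) == 0L) {
    skipped$tuning <- "no theta cycles available"
  } else {
    grid <- tuning_grid(geom)
    t_end <- max(traj$t)
    curves <- build_tuning_curves(pyr_spikes, traj, cycles, state, grid,
                                  cell_ids = pyr_ids)
    if (length(pyr_ids) < 10L) {
      skipped$decoding <- sprintf(
        "only %d putative pyramidal cells (minimum 10)", length(pyr_ids))
    } else if (is.null(split_time)) {
      skipped$cross_decoding <- "no attack or yoked split available"
      theta_dec <- decode_theta_cycles(cycles, pyr_spikes, curves, traj)
    } else {
      pre_cv <- build_tuning_curves(pyr_spikes, traj, cycles, state, grid,
                                    epoch = c(0, split_time),
                                    epoch_label = "pre_attack",
                                    cell_ids = pyr_ids)
      post_cv <- build_tuning_curves(pyr_spikes, traj, cycles, state, grid,
                                     epoch = c(split_time, t_end),
                                     epoch_label = "post_attack",
                                     cell_ids = pyr_ids)
      shift <- compute_tuning_shift(pre_cv, post_cv, geom)
      if (!is.null(hses) && nrow(hses) > 0L) {
        nest_end <- geom$zones$end[geom$zones$zone == "doorway"]
        xi <- stats::approx(traj$t, traj$x,
                            xout = (hses$t_start + hses$t_end) / 2,
                            rule = 2)$y
        in_nest <- hses[xi < nest_end, , drop = FALSE]
        if (nrow(in_nest) > 0L) {
          cross <- decode_hse_events(in_nest, pyr_spikes, pre_cv, post_cv,
                                     split_time, geom)
        } else {
          skipped$cross_decoding <- "no in-nest high-synchrony events"
        }
      }
      theta_dec <- decode_theta_cycles(cycles, pyr_spikes, curves, traj)
    }
  }

  structure(list(
    behavior = list(journeys = seg$journeys, n_laps = seg$n_laps,
                    hesitations = hes, mtas = mtas, pauses = pauses),
    lfpstate = list(state = state, cycles = cycles, psd = psd),
    transients = list(swrs = swrs, hses = hses, overlap = overlap),
    tuning = list(curves = curves, shift = shift),
    decoding = list(cross = cross, theta = theta_dec),
    skipped = skipped,
    provenance = list(package = "aatrack",
                      version = as.character(utils::packageVersion("aatrack")),
                      seed = seed, split_lap = split_lap,
                      counts = log)),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n")
  for (nm in names(x$provenance$counts)) {
    cat(sprintf("  %s: %s\n", nm,
                paste(names(x$provenance$counts[[nm]]),
                      x$provenance$counts[[nm]], sep = "=",
                      collapse = ", ")))
  }
  if (length(x$skipped) > 0L) {
    for (nm in names(x$skipped)) {
      cat("  skipped", nm, "-", x$skipped[[nm]], "\n")
    }
  }
  invisible(x)
}

#' Write / read an analysis report as JSON
#'
#' Tables are serialized column-wise; reals survive the round trip to at
#' least 1e-12.
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @return `path` invisibly for the writer; the parsed report for the reader.
#' @export
write_report <- function(report, path) {
  serializable <- list(
    behavior = lapply(report$behavior, as_plain),
    transients = list(swrs = as_plain(report$transients$swrs),
                      hses = as_plain(report$transients$hses),
                      overlap = unclass(report$transients$overlap)),
    tuning_shift = if (!is.null(report$tuning$shift)) list(
      mean_shift = report$tuning$shift$mean_shift,
      zones = report$tuning$shift$zones) else NULL,
    cross_decoding = if (!is.null(report$decoding$cross))
      report$decoding$cross$summary else NULL,
    skipped = report$skipped,
    provenance = within(report$provenance,
                        counts <- lapply(counts, as.list)))
  jsonlite::write_json(serializable, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

as_plain <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    class(x) <- "data.frame"
    attr(x, "kind") <- NULL
    return(x)
  }
  x
}
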