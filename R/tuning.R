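# Spatial tuning: pyramidal cell classification, occupancy-normalized
# directional tuning curves on the 64 x 3 grid, and pre/post shift maps.

#' Classify putative pyramidal cells from waveform metrics
#'
#' A cell is a putative pyramidal cell when its mean firing rate is below
#' 10 spikes/s and its peak-to-valley duration ratio exceeds 0.4 (both
#' strict).
#'
#' @param metrics Data.frame with `cell_id`, `mean_rate_hz`,
#'   `peak_valley_ratio`.
#' @param max_rate Rate bound in spikes/s (default 10).
#' @param min_ratio Peak-to-valley duration ratio bound (default 0.4).
#' @return Logical vector, one flag per row of `metrics`.
#' @export
classify_pyramidal <- function(metrics, max_rate = 10, min_ratio = 0.4) {
  need <- c("mean_rate_hz", "peak_valley_ratio")
  if (!all(need %in% names(metrics))) {
    stop("metrics must contain ", paste(need, collapse = ", "))
  }
  if (anyNA(metrics[, need])) stop("missing waveform metrics")
  metrics$mean_rate_hz < max_rate & metrics$peak_valley_ratio > min_ratio
}

# mass-preserving Gaussian smoothing matrix over positional bins: each
# source bin distributes exactly its mass (column sums are 1), so totals of
# counts and occupancy are unchanged
smoothing_matrix <- function(n, sd_bins, radius = ceiling(3 * sd_bins)) {
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- max(1L, j - radius):min(n, j + radius)
    k <- stats::dnorm(i - j, sd = sd_bins)
    S[i, j] <- k / sum(k)
  }
  S
}

# per-sample inclusion mask: theta state, descending half-cycle, epoch
included_sample_mask <- function(t, cycles, state = NULL, epoch = NULL) {
  desc <- data.frame(t_start = cycles$t_peak, t_end = cycles$t_trough)
  mask <- in_intervals(t, desc)
  if (!is.null(state)) {
    mask <- mask & in_intervals(t, state_epochs(state, "theta"))
  }
  if (!is.null(epoch)) mask <- mask & t >= epoch[1] & t < epoch[2]
  mask
}

#' Build occupancy-normalized directional tuning curves
#'
#' Counts each cell's spikes per (positional bin x direction bin), restricted
#' to time when the LFP is theta-dominated and within the descending phase of
#' the theta cycle (minimizing the influence of ripples and prospective theta
#' sweeps), then divides by the occupancy (included time) in each bin.  Bins
#' never occupied under the mask carry `NA`, never 0.
#'
#' @param spikes Data.frame with `cell_id`, `t` (putative pyramidal cells).
#' @param traj Trajectory data.frame (`t`, `x`, ...).
#' @param cycles A `theta_cycles` table (detected or scheduled) supplying the
#'   descending-phase intervals.
#' @param state Optional `state_series`; when supplied, only theta-labeled
#'   bins are included.
#' @param grid A [tuning_grid()].
#' @param epoch Optional length-2 time interval restricting the fit (e.g.
#'   pre-attack laps); label it via `epoch_label`.
#' @param epoch_label Label stored with the curves (default `"whole"`).
#' @param occupancy_mode `"matched"` restricts occupancy to the same
#'   theta-descending mask as the spikes (default); `"direction_all"` uses
#'   all time in the direction bin within the epoch.
#' @param smooth_sd_bins SD (in positional bins) of the mass-preserving
#'   Gaussian applied to spike counts and occupancy along position before
#'   the ratio (default 1; 0 disables).  Smoothing shares information
#'   between neighboring bins, the standard stabilization for
#'   occupancy-normalized rate maps, and leaves the count/occupancy
#'   conservation identity exact.
#' @param stationary_speed Speed bound (cm/s) of the stationary direction bin.
#' @param cell_ids Cells to fit (default: all cells present in `spikes`).
#' @return An object of class `tuning_curves`: expected rate matrix
#'   (cells x 192 bins, spikes/s), occupancy vector (s per bin), spike counts
#'   per cell, the grid and epoch label.
#' @export
build_tuning_curves <- function(spikes, traj, cycles, state = NULL,
                                grid = NULL, epoch = NULL,
                                epoch_label = "whole",
                                occupancy_mode = c("matched",
                                                   "direction_all"),
                                stationary_speed = 5, cell_ids = NULL,
                                smooth_sd_bins = 1) {
  occupancy_mode <- match.arg(occupancy_mode)
  if (is.null(grid)) grid <- tuning_grid(arena_geometry())
  if (is.null(cell_ids)) cell_ids <- sort(unique(spikes$cell_id))
  t <- traj$t
  dt <- stats::median(diff(t))
  dir <- track_direction(traj, stationary_speed)$direction
  dir_idx <- match(dir, grid$directions)
  pos_idx <- pos_bin_of(traj$x, grid)
  bin <- grid_bin(grid, dir_idx, pos_idx)

  mask <- included_sample_mask(t, cycles, state, epoch)
  if (occupancy_mode == "direction_all") {
    occ_mask <- if (is.null(epoch)) rep(TRUE, length(t)) else
      t >= epoch[1] & t < epoch[2]
  } else {
    occ_mask <- mask
  }
  if (!any(mask)) stop("no included time under the theta-descending mask")
  occupancy <- numeric(grid$n_bins)
  tab <- tapply(rep(dt, sum(occ_mask)), bin[occ_mask], sum)
  occupancy[as.integer(names(tab))] <- tab

  # spikes: inclusion/direction from the containing sample, position
  # interpolated at the spike time (avoids a systematic half-sample lag)
  samp <- findInterval(spikes$t, t)
  valid <- samp >= 1L & samp <= length(t)
  counts <- matrix(0, nrow = length(cell_ids), ncol = grid$n_bins,
                   dimnames = list(cell_ids, NULL))
  inc <- valid & mask[pmax(samp, 1L)] & spikes$cell_id %in% cell_ids
  if (any(inc)) {
    x_spk <- stats::approx(t, traj$x, xout = spikes$t[inc], rule = 2)$y
    spk_bin <- grid_bin(grid, dir_idx[samp[inc]], pos_bin_of(x_spk, grid))
    # a spike interpolated into a never-occupied bin falls back to its
    # sample's bin so rate x occupancy conservation holds exactly
    fallback <- occupancy[spk_bin] == 0
    spk_bin[fallback] <- bin[samp[inc]][fallback]
    tb <- table(factor(spikes$cell_id[inc], levels = cell_ids),
                factor(spk_bin, levels = seq_len(grid$n_bins)))
    counts <- counts + unclass(tb)
  }
  if (smooth_sd_bins > 0) {
    S <- smoothing_matrix(grid$n_pos, smooth_sd_bins)
    for (d in seq_along(grid$directions)) {
      idx <- grid_bin(grid, d, seq_len(grid$n_pos))
      counts[, idx] <- counts[, idx, drop = FALSE] %*% t(S)
      occupancy[idx] <- as.numeric(S %*% occupancy[idx])
    }
  }
  rates <- sweep(counts, 2L, occupancy, "/")
  rates[, occupancy == 0] <- NA_real_
  structure(list(rates = rates, occupancy = occupancy,
                 n_spikes = rowSums(counts), cells = cell_ids, grid = grid,
                 epoch = epoch_label, occupancy_mode = occupancy_mode),
            class = "tuning_curves")
}

#' @export
print.tuning_curves <- function(x, ...) {
  cat(sprintf(
    "Tuning curves (%s epoch): %d cells x %d bins (%d positions x %d directions)\n",
    x$epoch, length(x$cells), x$grid$n_bins, x$grid$n_pos,
    length(x$grid$directions)))
  cat(sprintf("  occupancy %.1f s over %d visited bins; %d spikes included\n",
              sum(x$occupancy), sum(x$occupancy > 0), sum(x$n_spikes)))
  invisible(x)
}

#' @export
plot.tuning_curves <- function(x, cells = NULL, direction = "outbound", ...) {
  d <- match(direction, x$grid$directions)
  idx <- grid_bin(x$grid, d, seq_len(x$grid$n_pos))
  m <- x$rates[, idx, drop = FALSE]
  if (!is.null(cells)) m <- m[match(cells, x$cells), , drop = FALSE]
  graphics::matplot(x$grid$centers, t(m), type = "l", lty = 1,
                    xlab = "position (cm)", ylab = "rate (spikes/s)", ...)
  invisible(x)
}

# direction-marginalized positional rate per cell, weighting direction bins
# by their occupancy
marginal_rates <- function(curves) {
  g <- curves$grid
  n_dir <- length(g$directions)
  out <- matrix(NA_real_, nrow = nrow(curves$rates), ncol = g$n_pos,
                dimnames = list(rownames(curves$rates), NULL))
  for (p in seq_len(g$n_pos)) {
    idx <- grid_bin(g, seq_len(n_dir), p)
    occ <- curves$occupancy[idx]
    if (sum(occ) == 0) next
    r <- curves$rates[, idx, drop = FALSE]
    w <- matrix(occ, nrow = nrow(r), ncol = n_dir, byrow = TRUE)
    w[is.na(r)] <- 0
    out[, p] <- rowSums(r * w, na.rm = TRUE) / pmax(rowSums(w), .Machine$double.xmin)
    out[rowSums(w) == 0, p] <- NA_real_
  }
  out
}

#' Pre/post spatial tuning shift map
#'
#' Computes each cell's occupancy-weighted direction-marginal tuning per
#' positional bin in both epochs, takes the per-cell difference (post minus
#' pre), averages across cells per bin, and aggregates by arena zone.  Cells
#' with fewer than `min_spikes` included spikes in either epoch are excluded
#' from the average.  Bins undefined (zero occupancy) in either epoch are
#' excluded, never treated as zero rate.
#'
#' @param pre,post `tuning_curves` for the pre- and post-attack (or yoked)
#'   epochs, on identical grids and cell sets.
#' @param geom An [arena_geometry()] for zone aggregation.
#' @param min_spikes Minimum included spikes per cell per epoch (default 10).
#' @return An object of class `tuning_shift` with the per-cell shift matrix,
#'   the cross-cell mean per positional bin and a per-zone summary.
#' @export
compute_tuning_shift <- function(pre, post, geom = arena_geometry(),
                                 min_spikes = 10) {
  if (!identical(pre$cells, post$cells)) {
    bad <- union(setdiff(pre$cells, post$cells),
                 setdiff(post$cells, pre$cells))
    stop("cell sets differ between epochs: ", paste(bad, collapse = ", "))
  }
  if (!identical(pre$grid$n_bins, post$grid$n_bins)) {
    stop("tuning grids differ between epochs")
  }
  keep <- pre$n_spikes >= min_spikes & post$n_spikes >= min_spikes
  m_pre <- marginal_rates(pre)
  m_post <- marginal_rates(post)
  shift <- m_post - m_pre
  shift[!keep, ] <- NA_real_
  mean_shift <- colMeans(shift, na.rm = TRUE)
  mean_shift[colSums(!is.na(shift)) == 0] <- NA_real_
  zones <- zone_of(pre$grid$centers, geom)
  zone_tab <- data.frame(
    zone = levels(zones),
    mean_shift = vapply(levels(zones), function(z) {
      mean(mean_shift[zones == z], na.rm = TRUE)
    }, numeric(1)),
    n_bins = as.integer(table(zones)))
  structure(list(per_cell = shift, mean_shift = mean_shift,
                 centers = pre$grid$centers, zones = zone_tab,
                 n_cells_used = sum(keep)),
            class = "tuning_shift")
}

#' @export
print.tuning_shift <- function(x, ...) {
  cat(sprintf("Spatial tuning shift (post - pre), %d cells\n", x$n_cells_used))
  print(x$zones, row.names = FALSE)
  invisible(x)
}

#' @export
plot.tuning_shift <- function(x, ...) {
  graphics::plot(x$centers, x$mean_shift, type = "h",
                 xlab = "position (cm)",
                 ylab = "mean tuning shift (spikes/s)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
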