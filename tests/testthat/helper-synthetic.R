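# Shared fixtures: cached synthetic sessions and event-matching helpers.

.session_cache <- new.env(parent = emptyenv())

# memoised session generation so several test files can share one fixture
cached_session <- function(type = "linear_track", duration = 120, seed = 11,
                           n_cells = 50, with_lfp = TRUE, ...) {
  key <- paste(type, duration, seed, n_cells, with_lfp,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (!is.null(.session_cache[[key]])) return(.session_cache[[key]])
  cfg <- task_config(type, session_duration = duration, seed = seed)
  s <- generate_session(cfg, arena_geometry(), n_cells = n_cells,
                        with_lfp = with_lfp, ...)
  .session_cache[[key]] <- s
  s
}

# precision/recall of detected intervals against ground-truth intervals,
# matched by any temporal overlap
event_recovery <- function(detected, truth) {
  hit <- aatrack:::intervals_overlap_any(detected, truth)
  rec <- aatrack:::intervals_overlap_any(truth, detected)
  list(precision = if (nrow(detected) > 0L) mean(hit) else NA_real_,
       recall = if (nrow(truth) > 0L) mean(rec) else NA_real_)
}

# a 30 Hz trajectory from keypoints (t, x), with constant y and no noise
keypoint_traj <- function(kt, kx, rate = 30, y = 13) {
  tg <- seq(0, max(kt), by = 1 / rate)
  data.frame(t = tg, x = stats::approx(kt, kx, xout = tg, rule = 2)$y,
             y = y, tracked = TRUE)
}

# descending-only cycle table covering [t0, t1] as one pseudo-cycle, for
# tuning tests that need a fully-included mask
full_desc_cycles <- function(t0, t1) {
  data.frame(t_peak = t0, t_trough = t1, t_next_peak = t1)
}

# tiny hand-made tuning curve object on a custom positional grid; only the
# outbound direction is occupied so the effective grid is `rates`' columns
toy_curves <- function(rates, occupancy = NULL, geom = arena_geometry()) {
  n_pos <- ncol(rates)
  grid <- tuning_grid(geom, n_pos = n_pos)
  full <- matrix(NA_real_, nrow = nrow(rates), ncol = grid$n_bins)
  full[, seq_len(n_pos)] <- rates
  occ <- numeric(grid$n_bins)
  occ[seq_len(n_pos)] <- if (is.null(occupancy)) 1 else occupancy
  structure(list(rates = full, occupancy = occ,
                 n_spikes = rowSums(rates, na.rm = TRUE),
                 cells = seq_len(nrow(rates)), grid = grid, epoch = "whole",
                 occupancy_mode = "matched"),
            class = "tuning_curves")
}

# independent brute-force evaluation of the one-step Bayesian posterior on a
# small instance: direct product arithmetic over bins, no log space
brute_posterior <- function(counts, rates, tau, floor = 0.01) {
  a <- pmax(rates, floor)
  n_bins <- ncol(a)
  p <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    lik <- 1
    for (i in seq_len(nrow(a))) lik <- lik * a[i, b]^counts[i]
    p[b] <- lik * (1 / n_bins) / exp(tau * sum(a[, b]))
  }
  p / sum(p)
}
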