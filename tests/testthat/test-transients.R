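# Sharp-wave ripple and high-synchrony event detection.

fs <- 1250

# white background with ripple bursts at given times/durations; amplitude is
# calibrated in SDs of the background ripple-band envelope.  A Tukey envelope
# holds the burst at full amplitude over most of its duration so the
# supra-threshold interval tracks the scripted one.
ripple_signal <- function(duration, starts, durs, amp_sd = 6, seed = 1,
                          flat = 0.7) {
  set.seed(seed)
  n <- duration * fs + 1
  t <- (seq_len(n) - 1) / fs
  x <- rnorm(n, 0, 20)
  bp <- aatrack:::butter_bandpass(x, fs, c(150, 250))
  env <- Mod(aatrack:::analytic_signal(bp))
  target <- mean(env) + amp_sd * stats::sd(env)
  for (k in seq_along(starts)) {
    idx <- which(t >= starts[k] & t <= starts[k] + durs[k])
    u <- seq(0, 1, length.out = length(idx))
    r <- (1 - flat) / 2
    taper <- ifelse(u < r, 0.5 - 0.5 * cos(pi * u / r),
                    ifelse(u > 1 - r, 0.5 - 0.5 * cos(pi * (1 - u) / r), 1))
    x[idx] <- x[idx] + target * taper * sin(2 * pi * 200 * t[idx])
  }
  lfp_signal(x, fs)
}

test_that("ripple detection finds injected bursts and nothing in noise", {
  # noise only: no events
  quiet <- ripple_signal(20, numeric(0), numeric(0))
  expect_identical(nrow(detect_swrs(quiet, 1)), 0L)

  # one 50 ms burst at 6 SD: exactly one event overlapping the injection
  one <- ripple_signal(20, 10, 0.05)
  ev <- detect_swrs(one, 1)
  expect_identical(nrow(ev), 1L)
  inter <- min(ev$t_end, 10.05) - max(ev$t_start, 10)
  union <- max(ev$t_end, 10.05) - min(ev$t_start, 10)
  expect_gte(inter / union, 0.5)                  # Jaccard overlap

  # a 15 ms burst fails the minimum-duration criterion
  short <- ripple_signal(20, 10, 0.015)
  expect_identical(nrow(detect_swrs(short, 1)), 0L)

  expect_error(detect_swrs(lfp_signal(rep(0, fs * 5), fs), 1),
               "zero variance")
})

test_that("candidate merging follows both gap rules to a fixpoint", {
  # two 25 ms bursts separated by a 3 ms gap merge into one event
  two <- ripple_signal(20, c(10, 10.028), c(0.025, 0.025), amp_sd = 10,
                       flat = 0.9)
  ev <- detect_swrs(two, 1)
  expect_identical(nrow(ev), 1L)
  expect_gt(ev$duration, 0.04)

  # merging is idempotent and order-independent
  raw <- data.frame(t_start = c(1.000, 1.030, 1.002, 2.0),
                    t_end = c(1.010, 1.060, 1.022, 2.5),
                    peak_z = c(5, 6, 7, 8))
  m1 <- aatrack:::merge_events(raw, 0.005, 0.020)
  m2 <- aatrack:::merge_events(raw[sample.int(4, 4), ], 0.005, 0.020)
  m1 <- m1[order(m1$t_start), ]; m2 <- m2[order(m2$t_start), ]
  expect_equal(m1$t_start, m2$t_start)
  expect_equal(m1$t_end, m2$t_end)
  again <- aatrack:::merge_events(m1, 0.005, 0.020)
  expect_equal(m1$t_start, again$t_start)
  # merged events never overlap
  expect_true(all(diff(m1$t_start) >= 0))
  expect_true(all(m1$t_start[-1L] >= m1$t_end[-nrow(m1)]))
})

test_that("ripple channel selection targets residual ripple-band power", {
  set.seed(4)
  n <- 30 * fs
  t <- (seq_len(n) - 1) / fs
  base <- replicate(3, aatrack:::colored_noise(n, fs, 2, 20))
  bumpy <- base
  starts <- seq(2, 28, by = 1.5)
  for (s0 in starts) {
    idx <- which(t >= s0 & t < s0 + 0.06)
    bumpy[idx, 2L] <- bumpy[idx, 2L] + 30 * sin(2 * pi * 200 * t[idx])
  }
  expect_identical(unname(select_swr_channel(lfp_signal(bumpy, fs))), 2L)
  # a single channel selects itself; identical channels tie-break low
  expect_identical(unname(select_swr_channel(lfp_signal(base[, 1L], fs))), 1L)
  same <- lfp_signal(cbind(base[, 1L], base[, 1L]), fs)
  expect_identical(unname(select_swr_channel(same)), 1L)
})

test_that("high-synchrony events respect both duration bounds", {
  set.seed(2)
  mk_spikes <- function(burst_start, burst_dur, n_cells = 30,
                        t_end = 60, bg = 2, burst_rate = 600) {
    bg_n <- rpois(1, bg * n_cells * t_end)
    spk <- data.frame(cell_id = sample.int(n_cells, bg_n, TRUE),
                      t = runif(bg_n, 0, t_end))
    if (burst_dur > 0) {
      nb <- rpois(1, burst_rate * burst_dur)
      spk <- rbind(spk, data.frame(
        cell_id = sample.int(n_cells, nb, TRUE),
        t = runif(nb, burst_start, burst_start + burst_dur)))
    }
    spk[order(spk$t), ]
  }
  # a scripted 100 ms synchronous burst gives exactly one covering event
  ev <- detect_hses(mk_spikes(30, 0.1), t_range = c(0, 60))
  expect_identical(nrow(ev), 1L)
  expect_lt(ev$t_start, 30.1)
  expect_gt(ev$t_end, 30)

  # a brief 10 ms burst stays below the minimum event duration
  ev <- detect_hses(mk_spikes(30, 0.01, burst_rate = 250),
                    t_range = c(0, 60))
  expect_identical(nrow(ev), 0L)

  # a 900 ms elevated plateau exceeds the maximum duration
  ev <- detect_hses(mk_spikes(30, 0.9), t_range = c(0, 60))
  expect_true(all(ev$duration < 0.75))
  expect_false(any(ev$t_start < 30.85 & ev$t_end > 30.05 &
                     ev$duration > 0.75))

  expect_error(detect_hses(data.frame(cell_id = integer(0), t = numeric(0))),
               "empty")
})

test_that("detector output is invariant to uniform time translation", {
  set.seed(3)
  spk <- data.frame(cell_id = sample.int(20, 4000, TRUE),
                    t = sort(runif(4000, 0, 60)))
  burst <- data.frame(cell_id = sample.int(20, 150, TRUE),
                      t = runif(150, 30, 30.08))
  spk <- rbind(spk, burst); spk <- spk[order(spk$t), ]
  ev1 <- detect_hses(spk, t_range = c(0, 60))
  spk2 <- transform(spk, t = t + 100)
  ev2 <- detect_hses(spk2, t_range = c(100, 160))
  expect_identical(nrow(ev1), nrow(ev2))
  expect_equal(ev2$t_start - 100, ev1$t_start, tolerance = 1e-6)
})

test_that("overlap percentages are reported from both reference sets", {
  a <- data.frame(t_start = c(1, 5, 9), t_end = c(2, 6, 10))
  expect_identical(overlap_summary(a, a)$pct_swr, 100)
  expect_identical(overlap_summary(a, a)$pct_hse, 100)
  b <- data.frame(t_start = c(20, 30), t_end = c(21, 31))
  expect_identical(overlap_summary(a, b)$pct_swr, 0)
  # hand-counted toy: 2 of 3 SWRs overlap; 4 of 5 HSEs overlap
  swr <- data.frame(t_start = c(1, 5, 9), t_end = c(2, 6, 10))
  hse <- data.frame(t_start = c(1.5, 5.5, 5.8, 9.2, 50),
                    t_end = c(1.6, 5.6, 5.9, 9.3, 51))
  ov <- overlap_summary(swr, hse)
  expect_equal(ov$pct_swr, 100 * 3 / 3)
  expect_equal(ov$pct_hse, 100 * 4 / 5)
  swr2 <- data.frame(t_start = c(1, 5, 90), t_end = c(2, 6, 91))
  ov2 <- overlap_summary(swr2, hse)
  expect_equal(ov2$pct_swr, 100 * 2 / 3)
})

test_that("injected events are recovered on a full synthetic session", {
  s <- cached_session("linear_track", duration = 120, seed = 11)
  gt <- s$ground_truth
  expect_identical(unname(select_swr_channel(s$lfp)), 2L)
  swrs <- detect_swrs(s$lfp, 2)
  pr <- event_recovery(swrs, gt$swr_windows)
  expect_gte(pr$precision, 0.9)
  expect_gte(pr$recall, 0.9)

  pyr <- s$cells$cell_id[classify_pyramidal(s$cells)]
  hses <- detect_hses(s$spikes[s$spikes$cell_id %in% pyr, ],
                      t_range = c(0, 120))
  still <- hses[aatrack:::in_intervals((hses$t_start + hses$t_end) / 2,
                                       gt$stillness), ]
  pr <- event_recovery(still, gt$hse_windows)
  expect_gte(pr$precision, 0.9)
  rec <- event_recovery(hses, gt$hse_windows)
  expect_gte(rec$recall, 0.9)
})
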