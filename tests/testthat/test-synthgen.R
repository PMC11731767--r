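# Synthetic session generator: attack schedules, fields, spikes, sessions.

test_that("attack schedules respect session type, eligibility and rate", {
  cfg <- task_config("linear_track", seed = 1)
  expect_identical(generate_attack_schedule(cfg, 100), integer(0))

  cfg <- task_config("attack", seed = 1)
  expect_error(generate_attack_schedule(cfg, -5), "non-negative")

  sched <- generate_attack_schedule(cfg, 10014)
  expect_true(all(diff(sched) > 0))
  expect_gte(min(sched), 15)
  # 10,000 eligible laps at p = 0.2: binomial 99% CI on the fraction
  n_elig <- 10014 - 15 + 1
  frac <- length(sched) / n_elig
  half <- stats::qnorm(0.995) * sqrt(0.2 * 0.8 / n_elig)
  expect_lt(abs(frac - 0.2), half)

  # determinism under an explicit seed
  expect_identical(generate_attack_schedule(cfg, 200, seed = 7),
                   generate_attack_schedule(cfg, 200, seed = 7))
})

test_that("first-attack offset follows the geometric law", {
  cfg <- task_config("attack", seed = 1)
  offsets <- vapply(seq_len(3000), function(k) {
    s <- generate_attack_schedule(cfg, 200, seed = k)
    if (length(s) == 0L) NA_integer_ else s[1L] - cfg$first_eligible_lap
  }, integer(1))
  offsets <- offsets[!is.na(offsets)]
  # P(first attack on the first eligible lap) = 0.2
  p0 <- mean(offsets == 0)
  expect_lt(abs(p0 - 0.2), 3 * sqrt(0.2 * 0.8 / length(offsets)))
  # mean of the geometric offset = (1 - p) / p = 4
  expect_lt(abs(mean(offsets) - 4), 0.5)
})

test_that("generative place fields cover the arena and remap as configured", {
  geom <- arena_geometry()
  f0 <- generate_place_fields(0, geom)
  expect_identical(nrow(f0), 0L)
  expect_error(generate_place_fields(10, geom, remap_fraction = 1.5),
               "remap_fraction")

  f <- generate_place_fields(50, geom, remap_fraction = 0.3, seed = 3)
  expect_true(all(f$center >= 0 & f$center <= geom$track_length))
  expect_true(all(f$peak_rate >= 0))
  remap <- f[f$post_attack_only, ]
  expect_identical(length(unique(remap$cell_id)), 15L)  # round(0.3 * 50)
  z <- zone_of(remap$center, geom)
  expect_true(all(z %in% c("robot_side_track", "robot")))

  # remap_fraction = 0: pre- and post-attack generative maps identical
  f_none <- generate_place_fields(50, geom, remap_fraction = 0, seed = 3)
  expect_false(any(f_none$post_attack_only))
  x <- seq(0, 111, by = 1)
  rows <- f_none[f_none$cell_id == 1, ]
  expect_equal(aatrack:::eval_fields(rows, x, rep(1, length(x)), FALSE),
               aatrack:::eval_fields(rows, x, rep(1, length(x)), TRUE))
})

test_that("spike emission is Poisson-consistent and respects silent cells", {
  traj <- data.frame(t = seq(0, 100, by = 1 / 30), x = 50, y = 13,
                     tracked = TRUE)
  theta <- data.frame(t_peak = numeric(0), t_trough = numeric(0),
                      t_next_peak = numeric(0))
  silent <- data.frame(cell_id = 1L, center = 50, width = 5, peak_rate = 0,
                       direction = "both", post_attack_only = FALSE,
                       post_scale = 1)
  spk <- generate_spike_trains(traj, silent, theta, baseline_rate = 0.3,
                               seed = 1)
  expect_identical(nrow(spk), 0L)

  # constant-rate cell: count within the Poisson 99% CI of r * T
  const <- data.frame(cell_id = 1L, center = 50, width = Inf, peak_rate = 4,
                      direction = "both", post_attack_only = FALSE,
                      post_scale = 1)
  spk <- generate_spike_trains(traj, const, theta, baseline_rate = 0,
                               seed = 5)
  lambda <- 4 * 100
  expect_lt(abs(nrow(spk) - lambda), stats::qnorm(0.995) * sqrt(lambda))

  expect_error(
    generate_spike_trains(traj, const, theta, cell_ids = 2L),
    "unknown cell ids")
})

test_that("spike counts are Poisson-dispersed across repeats", {
  traj <- data.frame(t = seq(0, 50, by = 1 / 30), x = 50, y = 13,
                     tracked = TRUE)
  theta <- data.frame(t_peak = numeric(0), t_trough = numeric(0),
                      t_next_peak = numeric(0))
  const <- data.frame(cell_id = 1L, center = 50, width = Inf, peak_rate = 3,
                      direction = "both", post_attack_only = FALSE,
                      post_scale = 1)
  counts <- vapply(1:40, function(k) {
    nrow(generate_spike_trains(traj, const, theta, baseline_rate = 0,
                               seed = k))
  }, integer(1))
  disp <- stats::var(counts) / mean(counts)
  expect_gt(disp, 0.45)                           # Fano factor near 1
  expect_lt(disp, 2.2)
})

test_that("scripted behaviors and attacks appear in the trajectory", {
  geom <- arena_geometry()
  cfg <- task_config("attack", session_duration = 400, seed = 23)
  rates <- behavior_rates(mta_prob = 0, mta_prob_inbound = 0, pause_rate = 0,
                          pause_rate_inbound = 0)
  tr <- generate_trajectory(cfg, geom, rates)
  expect_identical(nrow(tr$ground_truth$mtas), 0L)
  expect_identical(nrow(tr$ground_truth$pauses), 0L)

  gt <- tr$ground_truth
  if (nrow(gt$attacks) > 0L) {
    # on an attacked lap the rat crosses the threshold then retreats
    t_att <- gt$attacks$t[1L]
    idx <- tr$trajectory$t > t_att & tr$trajectory$t < t_att + 5
    expect_lt(min(tr$trajectory$x[idx]), geom$zones$start[3L] + 2)
  }
  expect_true(all(tr$trajectory$x >= 0 &
                    tr$trajectory$x <= geom$track_length))
})

test_that("sessions are deterministic given the seed and fully labeled", {
  s1 <- cached_session("attack", duration = 200, seed = 9, with_lfp = FALSE)
  cfg <- task_config("attack", session_duration = 200, seed = 9)
  s2 <- generate_session(cfg, arena_geometry(), n_cells = 50,
                         with_lfp = FALSE)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$cells, s2$cells)

  gt <- s1$ground_truth
  dur <- 200
  for (tab in list(gt$hesitations, gt$mtas, gt$pauses, gt$hse_windows)) {
    if (nrow(tab) > 0L) expect_true(all(tab$t_end <= dur + 1e-9))
  }
  if (nrow(gt$attacks) > 0L) {
    expect_true(all(gt$attacks$lap >= s1$config$first_eligible_lap))
  }
})

test_that("movement epochs of the LFP carry theta-band power", {
  s <- cached_session("linear_track", duration = 120, seed = 11)
  gt <- s$ground_truth
  mv <- gt$movement[which.max(gt$movement$t_end - gt$movement$t_start), ]
  i0 <- floor(mv$t_start * s$lfp$fs) + 1L
  i1 <- floor(mv$t_end * s$lfp$fs)
  seg <- s$lfp$samples[i0:i1, 1L]
  psd <- compute_psd(seg, fs = s$lfp$fs, bin_length = 0.5)
  pk <- psd$freq[psd$freq > 2][which.max(psd$power[psd$freq > 2])]
  expect_gte(pk, 6)
  expect_lte(pk, 10)
  expect_error(generate_lfp(gt$movement, 10, gt$theta, fs = 500),
               ">= 600")
})
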