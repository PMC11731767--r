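# One-step Bayesian decoding and its applications.

geom <- arena_geometry()

test_that("log-space decoding matches brute-force products on toy instances", {
  cfg <- decoder_config(min_cells = 1)
  set.seed(42)
  for (n_bins in c(3, 5)) {
    for (n_cells in 1:3) {
      rates <- matrix(round(runif(n_cells * n_bins, 0, 5), 1),
                      nrow = n_cells)
      cv <- toy_curves(rates)
      for (rep in 1:8) {
        counts <- sample(0:3, n_cells, replace = TRUE)
        tau <- runif(1, 0.02, 0.5)
        got <- decode_posterior(counts, cv, tau, cfg)
        want <- brute_posterior(counts, rates, tau)
        expect_equal(got$prob[seq_len(n_bins)], want, tolerance = 1e-9)
        expect_equal(sum(got$prob), 1, tolerance = 1e-9)
        expect_true(all(got$prob >= 0))
      }
    }
  }
})

test_that("worked 3-bin example and closed forms hold", {
  rates <- matrix(c(1, 2, 4,
                    4, 2, 1), nrow = 2, byrow = TRUE)
  cv <- toy_curves(rates)
  cfg <- decoder_config(min_cells = 1)
  got <- decode_posterior(c(2L, 0L), cv, 0.1, cfg)
  want <- brute_posterior(c(2, 0), rates, 0.1)
  expect_equal(got$prob[1:3], want, tolerance = 1e-9)
  expect_identical(which.max(got$prob), 3L)       # cell 1 fired, peak at 4

  # zero spikes: posterior proportional to exp(-tau * sum A)
  z <- decode_posterior(c(0L, 0L), cv, 0.5, cfg)
  expect_identical(which.max(z$prob[1:3]),
                   which.min(colSums(pmax(rates, 0.01))))

  # identical flat curves: uniform over defined bins
  flat <- toy_curves(matrix(2, nrow = 2, ncol = 4))
  u <- decode_posterior(c(1L, 1L), flat, 0.1, cfg)
  expect_equal(u$prob[1:4], rep(0.25, 4), tolerance = 1e-12)
})

test_that("the decoder refuses ensembles below ten cells by default", {
  rates <- matrix(runif(9 * 4, 0, 5), nrow = 9)
  expect_error(decode_posterior(rep(1L, 9), toy_curves(rates), 0.1),
               "9 cells .* minimum of 10")
  rates10 <- rbind(rates, runif(4, 0, 5))
  p <- decode_posterior(rep(1L, 10), toy_curves(rates10), 0.1)
  expect_s3_class(p, "posterior")
  expect_error(decode_posterior(c(-1L, rep(1L, 9)), toy_curves(rates10), 0.1),
               "non-negative")
  expect_error(decode_posterior(rep(1L, 10), toy_curves(rates10), 0),
               "tau")
})

test_that("zone masses partition the position marginal", {
  grid <- tuning_grid(geom)
  marg <- rep(1 / 64, 64)
  post <- structure(list(prob = rep(marg / 3, 3), marginal = marg,
                         grid = grid, n_cells = 10L, tau = 0.1,
                         n_spikes = 0L), class = "posterior")
  z <- geom$zones
  masses <- vapply(z$zone, function(zn) zone_mass(post, geom, zn), numeric(1))
  expect_equal(sum(masses), 1, tolerance = 1e-9)
  n_robot <- sum(grid$centers >= 86 & grid$centers < 104)
  expect_equal(unname(masses["robot"]), n_robot / 64, tolerance = 1e-12)
  expect_error(zone_mass(post, geom, "moon"), "unknown zone")
})

test_that("identical curve epochs give identical cross-decoding rows", {
  s <- cached_session("linear_track", duration = 200, seed = 9,
                      with_lfp = FALSE)
  gt <- s$ground_truth
  pyr <- s$cells$cell_id[classify_pyramidal(s$cells)]
  spk <- s$spikes[s$spikes$cell_id %in% pyr, ]
  cv <- build_tuning_curves(spk, s$trajectory, gt$theta,
                            grid = tuning_grid(geom), cell_ids = pyr)
  ev <- gt$hse_windows[seq_len(min(10, nrow(gt$hse_windows))), ]
  cd <- decode_hse_events(ev, spk, cv, cv, split_time = 100, geom = geom)
  pre_rows <- cd$per_event[cd$per_event$curve_epoch == "pre", ]
  post_rows <- cd$per_event[cd$per_event$curve_epoch == "post", ]
  expect_equal(pre_rows$robot_mass, post_rows$robot_mass, tolerance = 1e-12)
  expect_equal(pre_rows$feeder_mass, post_rows$feeder_mass,
               tolerance = 1e-12)
})

test_that("theta half-cycle decoding is local when generation is local", {
  cfg <- task_config("linear_track", session_duration = 300, seed = 31)
  s <- generate_session(cfg, geom, n_cells = 50, with_lfp = FALSE,
                        lookahead_cm = 0)
  gt <- s$ground_truth
  pyr <- s$cells$cell_id[classify_pyramidal(s$cells)]
  spk <- s$spikes[s$spikes$cell_id %in% pyr, ]
  grid <- tuning_grid(geom)
  cv <- build_tuning_curves(spk, s$trajectory, gt$theta, grid = grid,
                            cell_ids = pyr)
  td <- decode_theta_cycles(gt$theta, spk, cv, s$trajectory)
  d <- td$per_half[td$per_half$n_spikes >= 2, ]
  a <- d[d$phase == "ascending", ]; de <- d[d$phase == "descending", ]
  # local generation in both phases: no systematic ascending displacement
  expect_lt(abs(stats::median(a$signed_com) - stats::median(de$signed_com)),
            1)
  # the averaged descending-ascending difference map is near zero
  expect_lt(max(abs(td$diff_map)), 0.05)
})

test_that("decoding error shrinks with ensemble size", {
  s <- cached_session("linear_track", duration = 420, seed = 14,
                      with_lfp = FALSE)
  gt <- s$ground_truth
  pyr <- s$cells$cell_id[classify_pyramidal(s$cells)]
  grid <- tuning_grid(geom)
  err_for <- function(cells) {
    spk <- s$spikes[s$spikes$cell_id %in% cells, ]
    cv <- build_tuning_curves(spk, s$trajectory, gt$theta, grid = grid,
                              cell_ids = cells)
    td <- decode_theta_cycles(gt$theta, spk, cv, s$trajectory)
    d <- td$per_half
    d <- d[d$phase == "descending" & !d$zero_spikes, ]
    stats::median(abs(d$com_bin - d$true_bin))
  }
  e10 <- err_for(pyr[seq_len(10)])
  e40 <- err_for(pyr[seq_len(40)])
  expect_lte(e40, e10)
})

test_that("matched controls share bin, direction and epoch", {
  ann <- data.frame(
    t_mid = seq(1, 400, by = 1),
    pos_bin = rep(1:20, 20),
    direction = rep(c("outbound", "inbound"), 200),
    epoch = rep(c("pre", "post"), each = 200))
  targets <- c(5L, 210L)
  ctl <- match_control_cycles(targets, ann, cap = 10, seed = 1)
  for (k in seq_along(targets)) {
    tg <- targets[k]
    expect_lte(length(ctl[[k]]), 10L)
    expect_false(tg %in% ctl[[k]])
    expect_true(all(ann$pos_bin[ctl[[k]]] == ann$pos_bin[tg]))
    expect_true(all(ann$direction[ctl[[k]]] == ann$direction[tg]))
    expect_true(all(ann$epoch[ctl[[k]]] == ann$epoch[tg]))
  }
  # an exclusion window removes nearby cycles from eligibility
  win <- data.frame(t_start = 0, t_end = 400)
  ctl2 <- suppressWarnings(
    match_control_cycles(targets, ann, event_windows = win, margin = 1,
                         seed = 1))
  expect_identical(lengths(ctl2), c(0L, 0L))

  lone <- data.frame(t_mid = 1, pos_bin = 1L, direction = "outbound",
                     epoch = "pre")
  expect_warning(ctl3 <- match_control_cycles(1L, lone, seed = 1),
                 "no eligible")
  expect_identical(ctl3[[1L]], integer(0))
})
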