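# Behavioral classification: journeys, hesitations, aborts, pauses, yoking.

geom <- arena_geometry()

test_that("journey segmentation handles degenerate and scripted paths", {
  # never leaves the nest
  traj <- keypoint_traj(c(0, 20), c(10, 10))
  seg <- segment_journeys(traj, geom)
  expect_identical(nrow(seg$journeys), 0L)
  expect_identical(seg$n_laps, 0L)

  # one full nest -> feeder -> nest traversal
  traj <- keypoint_traj(c(0, 1, 4, 5, 8, 9), c(8, 8, 109.5, 109.5, 8, 8))
  seg <- segment_journeys(traj, geom)
  expect_identical(nrow(seg$journeys), 2L)
  expect_identical(seg$journeys$direction, c("outbound", "inbound"))
  expect_true(all(seg$journeys$completed))
  expect_identical(seg$n_laps, 1L)
})

test_that("mid-track aborts require both time and distance, excluding attacks", {
  mta_case <- function(excursion, track_s, attack_t = NULL) {
    traj <- keypoint_traj(
      c(0, 1, 1 + track_s / 2, 1 + track_s, 3 + track_s),
      c(17, 19, 19 + excursion, 17, 17))
    seg <- segment_journeys(traj, geom)
    log <- if (is.null(attack_t)) NULL else data.frame(t = attack_t)
    detect_mtas(traj, seg$journeys, log)
  }
  expect_identical(nrow(mta_case(10, 1.0)), 1L)   # 10 cm over 1 s: abort
  expect_identical(nrow(mta_case(4, 2.0)), 0L)    # distance criterion fails
  expect_identical(nrow(mta_case(10, 0.3)), 0L)   # time criterion fails
  # a retreat from an attack is not an abort
  expect_identical(nrow(mta_case(40, 2.0, attack_t = 2.5)), 0L)
  expect_identical(nrow(mta_case(40, 2.0)), 1L)
})

test_that("pauses require sub-centimeter displacement for over half a second", {
  pause_case <- function(stop_s, drift = 0, flank = 10) {
    legA <- (55 - 19) / flank
    legB <- (109.5 - 55 - drift) / flank
    kt <- c(0, 1, 1 + legA, 1 + legA + stop_s, 1 + legA + stop_s + legB,
            2 + legA + stop_s + legB)
    kx <- c(10, 19, 55, 55 + drift, 109.5, 109.5)
    traj <- keypoint_traj(kt, kx)
    seg <- segment_journeys(traj, geom)
    detect_pauses(traj, seg$journeys)
  }
  expect_identical(nrow(pause_case(0.7)), 1L)
  expect_identical(nrow(pause_case(0.4)), 0L)
  expect_identical(nrow(pause_case(0.6, drift = 0.8)), 1L)
})

test_that("hesitation excludes feeder-proximal time and needs a nest visit", {
  # 3 s within 2 cm of the nest feeder inside a 10 s nest visit
  fx <- geom$feeder_positions[["nest"]]
  kt <- c(0, 1, 2, 4, 4.5, 7.5, 8, 11, 12, 13)
  kx <- c(30, 19 - 1e-3, 16, 16, fx, fx, 16, 16, 19.5, 30)
  traj <- keypoint_traj(kt, kx)
  hes <- measure_hesitation(traj, geom)
  hes <- hes[hes$entered_from_track, ]
  expect_identical(nrow(hes), 1L)
  expect_lt(abs(hes$feeder_time - 3), 0.35)
  expect_lt(abs(hes$duration - ((hes$t_end - hes$t_start) - 3)), 0.35)

  # never in the nest: no hesitations
  traj <- keypoint_traj(c(0, 5), c(50, 90))
  expect_identical(nrow(measure_hesitation(traj, geom)), 0L)
})

test_that("scripted events are recovered with high precision and recall", {
  cfg <- task_config("attack", session_duration = 600, seed = 7)
  rates <- behavior_rates(mta_prob = 0.15, pause_rate = 0.3)
  tr <- generate_trajectory(cfg, geom, rates)
  gt <- tr$ground_truth
  seg <- segment_journeys(tr$trajectory, geom)
  expect_identical(seg$n_laps, nrow(gt$laps))

  mtas <- detect_mtas(tr$trajectory, seg$journeys, gt$attacks)
  pr <- event_recovery(mtas, gt$mtas)
  expect_gte(pr$precision, 0.95)
  expect_gte(pr$recall, 0.95)

  pauses <- detect_pauses(tr$trajectory, seg$journeys)
  pr <- event_recovery(pauses, gt$pauses)
  expect_gte(pr$precision, 0.95)
  expect_gte(pr$recall, 0.95)

  hes <- measure_hesitation(tr$trajectory, geom)
  hes <- hes[hes$entered_from_track & hes$exited_to_track, ]
  gth <- gt$hesitations[gt$hesitations$entered_from_track, ]
  expect_identical(nrow(hes), nrow(gth))
  # durations recovered within two position samples
  expect_lt(stats::median(abs(hes$duration - gth$duration)), 2 / 30)

  # every track entry is classified
  expect_true(all(seg$journeys$classification %in%
                    c("completed", "incomplete", "micro", "uncertain")))
})

test_that("tracking loss is bridged briefly and flagged when long", {
  kt <- c(0, 1, 2, 4, 4.5, 7.5, 8, 11, 12, 13)
  kx <- c(30, 19 - 1e-3, 16, 16, 9.5, 9.5, 16, 16, 19.5, 30)
  traj <- keypoint_traj(kt, kx)
  lost <- traj$t > 4.6 & traj$t < 5.4              # 0.8 s gap inside the visit
  traj$tracked[lost] <- FALSE
  traj$x[lost] <- NA
  hes <- measure_hesitation(traj, geom)
  hes <- hes[hes$entered_from_track, ]
  expect_true(any(hes$uncertain))
})

test_that("yoked splits permute the attack-lap multiset", {
  expect_error(yoke_split(c(15, 19, 16, 18), c("lt1", "lt2")),
               "count mismatch: 4 .* 2")
  y <- yoke_split(c(15, 19, 16, 18), c("lt1", "lt2", "nov1", "nov2"),
                  seed = 2)
  expect_setequal(y$split_lap, c(15, 19, 16, 18))
  y1 <- yoke_split(42L, "only", seed = 1)
  expect_identical(y1$split_lap, 42L)
})

test_that("subject normalization gives mean 0 and sd 1 per subject", {
  v <- data.frame(subject = rep(c("a", "b"), each = 4),
                  value = c(2, 4, 6, 8, 1, 1, 2, 3))
  z <- normalize_by_subject(v)
  for (s in c("a", "b")) {
    expect_equal(mean(z$z[z$subject == s]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z$z[z$subject == s]), 1, tolerance = 1e-12)
  }
  two <- normalize_by_subject(data.frame(subject = "a", value = c(2, 4)))
  expect_equal(two$z, c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-9)
  expect_error(
    normalize_by_subject(data.frame(subject = "flat", value = c(3, 3))),
    "flat")
})
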