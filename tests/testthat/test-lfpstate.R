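# LFP spectral analysis, state classification, theta cycle segmentation.

fs <- 1250

test_that("Welch PSD localizes tones and conserves variance", {
  t <- seq(0, 20, by = 1 / fs)
  x <- 3 * sin(2 * pi * 8 * t)
  psd <- compute_psd(x, fs = fs, bin_length = 1)
  expect_lt(abs(psd$freq[which.max(psd$power)] - 8), 1)

  # Parseval: integrating the one-sided PSD recovers the variance
  df <- diff(psd$freq[1:2])
  expect_lt(abs(sum(psd$power) * df - stats::var(x)) / stats::var(x), 0.05)

  # two tones dominate their own bands
  x2 <- sin(2 * pi * 2 * t) + sin(2 * pi * 8 * t)
  psd2 <- compute_psd(x2, fs = fs, bin_length = 1)
  bands <- band_definitions()
  expect_gt(band_power(psd2, bands$delta), band_power(psd2, bands$beta))
  expect_gt(band_power(psd2, bands$theta), band_power(psd2, bands$beta))
  expect_error(compute_psd(x[1:100], fs = fs, bin_length = 1), "bin longer")
})

test_that("white noise spreads power evenly across equal-width bands", {
  set.seed(5)
  x <- rnorm(fs * 30)
  psd <- compute_psd(x, fs = fs, bin_length = 1)
  p1 <- band_power(psd, c(50, 100))
  p2 <- band_power(psd, c(200, 250))
  expect_lt(abs(log(p1 / p2)), 0.2)
})

test_that("robust aperiodic fit isolates oscillatory bumps", {
  f <- seq(1, 500, by = 0.5)
  # exact power law: residual should vanish
  psd <- structure(data.frame(freq = f, power = 100 * f^-2),
                   class = c("psd", "data.frame"))
  res <- fit_aperiodic_residual(psd)
  expect_lt(max(abs(res$power) / (100 * res$freq^-2)), 0.01)
  expect_lt(abs(attr(res, "slope") - (-2)), 1e-6)

  # power law + Gaussian bump at 180 Hz
  bump <- 40 * f^-2 * 50 * exp(-(f - 180)^2 / (2 * 15^2))
  psd_b <- structure(data.frame(freq = f, power = 100 * f^-2 + bump),
                     class = c("psd", "data.frame"))
  res_b <- fit_aperiodic_residual(psd_b)
  expect_lt(abs(res_b$freq[which.max(res_b$power)] - 180), 10)
  # outlier resistance: robust slope within 5% of the bump-free slope,
  # closer than ordinary least squares
  sel <- psd_b$freq >= 80 & psd_b$freq <= 400
  ols <- stats::coef(stats::lm(log10(power) ~ log10(freq),
                               data = psd_b[sel, ]))[2L]
  expect_lt(abs(attr(res_b, "slope") - (-2)) / 2, 0.05)
  expect_lt(abs(attr(res_b, "slope") - (-2)), abs(ols - (-2)))

  expect_error(fit_aperiodic_residual(psd[1:5, ]), "fewer than 10")
})

test_that("cross-frequency correlation flags comodulated bands only", {
  set.seed(8)
  x <- rnorm(fs * 300)
  spec <- compute_spectrogram(x, fs = fs, bin_length = 1)
  cc <- crossfreq_correlation(spec)
  expect_true(all(abs(diag(cc) - 1) < 1e-12))
  offdiag <- cc[abs(row(cc) - col(cc)) > 3]
  expect_lt(stats::quantile(abs(offdiag), 0.95, na.rm = TRUE), 0.25)

  # comodulated ripple-band bursts (band-limited noise transients) produce a
  # high-correlation block across the band
  t <- seq_along(x) / fs
  band_noise <- aatrack:::butter_bandpass(rnorm(length(x), 0, 10), fs,
                                          c(150, 250))
  burst <- rep(0, length(x))
  starts <- seq(5.4, 290, by = 3)                # mid-bin, clear of the taper
  for (s0 in starts) {
    idx <- which(t >= s0 & t <= s0 + 0.08)
    burst[idx] <- band_noise[idx] * 6
  }
  cc2 <- crossfreq_correlation(compute_spectrogram(x + burst, fs = fs,
                                                   bin_length = 1))
  fr <- as.numeric(rownames(cc2))
  blk <- fr >= 160 & fr <= 240
  expect_gt(mean(cc2[blk, blk], na.rm = TRUE), 0.5)
  expect_error(
    crossfreq_correlation(compute_spectrogram(x[1:(20 * fs)], fs = fs)),
    "30 time bins")
})

test_that("state classification separates theta from large-amplitude states", {
  t <- seq(0, 120, by = 1 / fs)
  theta_epoch <- t >= 40 & t < 80
  x <- ifelse(theta_epoch, 120 * sin(2 * pi * 8 * t), 100 * sin(2 * pi * 2 * t)) +
    rnorm(length(t), 0, 10)
  st <- classify_state(lfp_signal(x, fs))
  expect_true(all(st$state[st$time > 41 & st$time < 79] == "theta"))
  expect_true(all(st$state[st$time < 39 | st$time > 81] == "lia"))

  # gain invariance: labels depend on the band-power ratio only
  st10 <- classify_state(lfp_signal(10 * x, fs))
  expect_identical(st$state, st10$state)

  # an infinite threshold labels everything LIA
  st_inf <- classify_state(lfp_signal(x, fs), threshold = Inf)
  expect_true(all(st_inf$state == "lia"))
})

test_that("state labels match ground-truth movement on synthetic sessions", {
  s <- cached_session("linear_track", duration = 120, seed = 11)
  gt <- s$ground_truth
  st <- classify_state(s$lfp)
  bl <- attr(st, "bin_length")
  a <- aatrack:::in_intervals(st$time - bl / 2 + 1e-9, gt$movement)
  b <- aatrack:::in_intervals(st$time + bl / 2 - 1e-9, gt$movement)
  unambiguous <- (a & b) | (!a & !b)
  truth <- ifelse(a & b, "theta", "lia")
  expect_gte(mean((st$state == truth)[unambiguous]), 0.95)
})

test_that("cycle segmentation recovers symmetric and asymmetric theta", {
  # pure sinusoid: both halves are 62.5 ms and the asymmetry index is 0
  t <- seq(0, 30, by = 1 / fs)
  cyc <- segment_theta_cycles(lfp_signal(150 * cos(2 * pi * 8 * t), fs))
  expect_lt(abs(stats::median(cyc$dur_asc) - 0.0625), 0.002)
  expect_lt(abs(stats::median(cyc$dur_desc) - 0.0625), 0.002)
  expect_lt(abs(stats::median(cyc$asymmetry)), 0.05)

  # saw-tooth with ascending:descending = 2:1 reads log2(2) = 1
  mov <- data.frame(t_start = 0, t_end = 60)
  meds <- vapply(c(0.5, 1, 2), function(ar) {
    sch <- generate_theta_schedule(mov, freq = 8, asym_ratio = ar,
                                   period_jitter = 0, seed = 1)
    w <- aatrack:::theta_waveform(t <- seq(0, 60, by = 1 / fs), sch) * 150 +
      rnorm(length(t), 0, 5)
    stats::median(segment_theta_cycles(lfp_signal(w, fs))$asymmetry)
  }, numeric(1))
  expect_lt(abs(meds[2L]), 0.05)
  expect_lt(abs(meds[3L] - 1), 0.1)
  expect_lt(abs(meds[1L] + 1), 0.1)
  expect_true(all(diff(meds) > 0))               # monotone in the knob
})

test_that("cycles tile theta epochs and stay within them", {
  s <- cached_session("linear_track", duration = 120, seed = 11)
  st <- classify_state(s$lfp)
  cyc <- segment_theta_cycles(s$lfp, st)
  expect_true(all(cyc$dur_desc > 0 & cyc$dur_asc > 0))
  # abutting halves: each cycle spans peak -> next peak exactly
  expect_equal(cyc$t_peak + cyc$dur_desc + cyc$dur_asc, cyc$t_next_peak,
               tolerance = 1e-9)
  ep <- aatrack:::state_epochs(st, "theta")
  expect_true(all(aatrack:::in_intervals(cyc$t_peak, ep)))
})
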