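test_that("r2_peak_to_peak is max minus min inside the anchored window", {
  fs <- 5000
  flat <- emg_trace(numeric(1001), fs, 10, "MAS")
  expect_equal(r2_peak_to_peak(flat, 1, response_window(27, 87)), 0)

  # inserted biphasic pulse with extremes +80 / -40 inside the window
  s <- numeric(1001)
  s[300] <- 80; s[320] <- -40      # 59.8 ms and 63.8 ms, inside 37-97 ms
  tr <- emg_trace(s, fs, 10, "MAS")
  expect_equal(r2_peak_to_peak(tr, 1, response_window(27, 87)), 120)
  # pulse outside a later window is not seen
  expect_equal(r2_peak_to_peak(tr, 1, response_window(70, 87)), 0)

  expect_error(r2_peak_to_peak(tr, 1, response_window(27, 500)), "outside")
  expect_error(r2_peak_to_peak(tr, 5), "out of range")
})

test_that("peak-to-peak extraction equals the brute-force oracle on noisy sweeps", {
  set.seed(7)
  fs <- 5000
  for (i in 1:20) {
    s <- rnorm(2001, sd = 10)
    tr <- emg_trace(s, fs, stimulus_onsets = 50, stim_side = "LAS")
    w <- response_window(27, 87)
    expect_equal(r2_peak_to_peak(tr, 1, w), oracle_ptp(s, fs, 77, 137))
  }
})

test_that("noise adds the positive bias predicted by a max-min oracle", {
  # programmed complex of known peak-to-peak A with additive noise: the mean
  # extracted amplitude exceeds A by a bias that a brute-force noise oracle
  # (max-min selection on the same window) predicts within Monte-Carlo error
  set.seed(11)
  A <- 100; sdev <- 4; n_rep <- 400
  cfg <- cohort_config(noise_sd_uv = 0, n_trials = 1L, n_uncond_trials = 1L)
  clean <- synth_sweep_for_test(A, cfg)
  w <- response_window(27, 87)
  i0 <- ceiling((10 + 27) * cfg$sampling_rate_hz / 1000) + 1
  i1 <- floor((10 + 87) * cfg$sampling_rate_hz / 1000) + 1
  seg <- clean$samples[i0:i1]
  extracted <- replicate(n_rep, {
    noisy <- emg_trace(clean$samples + rnorm(length(clean$samples), 0, sdev),
                       cfg$sampling_rate_hz, 10, "MAS")
    r2_peak_to_peak(noisy, 1, w)
  })
  oracle_bias <- mean(replicate(n_rep, {
    z <- seg + rnorm(length(seg), 0, sdev)
    (max(z) - min(z)) - A
  }))
  mc_err <- 3 * sdev / sqrt(n_rep)   # generous Monte-Carlo margin
  expect_gt(mean(extracted) - A, 0)            # bias is positive
  expect_lt(abs(mean(extracted) - A - oracle_bias), 3 * mc_err)
})

test_that("recovery ratio is the percentage of conditioned over unconditioned", {
  expect_equal(recovery_ratio(50, 100), 50)
  expect_equal(recovery_ratio(7.3, 7.3), 100)
  expect_equal(recovery_ratio(0, 100), 0)
  expect_equal(recovery_ratio(150, 100), 150)  # facilitation allowed
  expect_error(recovery_ratio(10, 0), "degenerate")
  expect_error(recovery_ratio(-1, 10), ">= 0")
})

test_that("a noise-free battery reproduces its programmed recovery cycle exactly", {
  prog <- c(10, 20, 40, 60, 80, 90, 100)
  batt <- make_clean_battery(prog)
  cv <- build_recovery_cycle(batt$MAS)
  expect_equal(unname(unlist(cv$ratios)), prog)
  expect_identical(as.numeric(names(cv$ratios)), as.numeric(ISI_BATTERY))
  expect_equal(cv$unconditioned_amplitude, 200)
  # short ISIs whose test window opens early are flagged, not dropped
  expect_true(100 %in% cv$window_overlap)
})

test_that("an incomplete battery raises a protocol error naming the missing ISI", {
  batt <- make_clean_battery(c(10, 20, 40, 60, 80, 90, 100))
  drop300 <- Filter(function(tr) length(tr$stimulus_onsets) == 1 ||
                      abs(diff(tr$stimulus_onsets) - 300) > 1, batt$MAS)
  expect_error(build_recovery_cycle(drop300), "300")
  no_uncond <- Filter(function(tr) length(tr$stimulus_onsets) == 2, batt$MAS)
  expect_error(build_recovery_cycle(no_uncond), "unconditioned")
})

test_that("noisy-battery ratios equal the mean-of-amplitudes oracle on raw sweeps", {
  set.seed(3)
  cfg <- cohort_config(noise_sd_uv = 3, n_trials = 10L, n_uncond_trials = 2L)
  r <- stats::setNames(c(15, 25, 40, 60, 80, 90, 100), ISI_BATTERY)
  targ <- list(MAS = r2_recovery_curve("MAS", as.list(r)),
               LAS = r2_recovery_curve("LAS", as.list(r)))
  batt <- generate_blink_traces(targ, cfg)$MAS
  cv <- build_recovery_cycle(batt)
  # independent recomputation straight from the raw vectors
  w0 <- 27; w1 <- 87; fs <- cfg$sampling_rate_hz
  uncond <- Filter(function(tr) length(tr$stimulus_onsets) == 1, batt)
  u_amp <- mean(sapply(uncond, function(tr)
    oracle_ptp(tr$samples, fs, tr$stimulus_onsets + w0, tr$stimulus_onsets + w1)))
  for (isi in ISI_BATTERY) {
    sel <- Filter(function(tr) length(tr$stimulus_onsets) == 2 &&
                    abs(diff(tr$stimulus_onsets) - isi) < 0.5, batt)
    amps <- sapply(sel, function(tr) {
      on <- tr$stimulus_onsets[2]
      oracle_ptp(tr$samples, fs, on + w0, on + w1)
    })
    expect_equal(cv$ratios[[as.character(isi)]], 100 * mean(amps) / u_amp)
  }
})

test_that("recovery ratios are invariant to a common rescaling of all sweeps", {
  set.seed(5)
  cfg <- cohort_config(noise_sd_uv = 2, n_trials = 3L, n_uncond_trials = 2L)
  r <- stats::setNames(c(10, 20, 40, 60, 80, 90, 100), ISI_BATTERY)
  targ <- list(MAS = r2_recovery_curve("MAS", as.list(r)),
               LAS = r2_recovery_curve("LAS", as.list(r)))
  batt <- generate_blink_traces(targ, cfg)$MAS
  scaled <- lapply(batt, function(tr) {
    tr$samples <- tr$samples * 3.7
    tr
  })
  expect_equal(unlist(build_recovery_cycle(scaled)$ratios),
               unlist(build_recovery_cycle(batt)$ratios))
})

test_that("ten noisy trials recover the programmed ratio within five points", {
  set.seed(21)
  cfg <- cohort_config(n_trials = 10L)   # default noise level
  r <- stats::setNames(c(2, 10, 30, 55, 75, 90, 100), ISI_BATTERY)
  targ <- list(MAS = r2_recovery_curve("MAS", as.list(r)),
               LAS = r2_recovery_curve("LAS", as.list(r)))
  for (rep in 1:5) {
    cv <- build_recovery_cycle(generate_blink_traces(targ, cfg)$MAS)
    expect_lt(max(abs(unlist(cv$ratios) - r)), 5)
  }
})
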