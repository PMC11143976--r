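test_that("onset backtracks to the edge of a force step", {
  f <- c(rep(700, 2000), rep(700 - 10 * 2, 1000))  # step of -10 quiet SDs
  tr <- force_trial(f, 1000)
  expect_identical(detect_onset(tr, 700, 2), 2001L)
})

test_that("pure quiet noise yields a no-movement error", {
  set.seed(3)
  tr <- force_trial(700 + rnorm(3000, 0, 2), 1000)
  expect_error(detect_onset(tr, 700, 2, k = 5), class = "no_movement")
})

test_that("detected onset lies within 30 ms of generator truth", {
  spec <- cohort_spec(n_participants = 10, conditions = "baseline",
                      trials_per_session = 3, seed = 14)
  fx <- list(baseline = fatigue_effect())
  cohort <- simulate_cohort(spec, jump_profile_params(noise_sd = 5), fx)
  for (tr in cohort$trials) {
    tru <- attr(tr, "truth")
    bw <- compute_body_weight(tr)
    onset <- detect_onset(tr, bw$body_weight_N, bw$quiet_sd_N,
                          search_from = 1000)
    expect_lt(abs(onset - tru$onset_index) / tr$sampling_rate, 0.030)
  }
})

test_that("integration reproduces constant-acceleration closed forms", {
  m <- 70
  f <- c(rep(m * 9.81, 1000), rep(m * (9.81 + 2), 501))  # net a = 2 for 0.5 s
  tr <- short_trial(f)
  kin <- integrate_motion(tr, body_mass = m, onset = 1001L)
  expect_equal(kin$velocity[1501], 1.0, tolerance = 1e-9)
  expect_equal(kin$displacement[1501], 0.25, tolerance = 1e-6)
})

test_that("body-weight force gives identically zero motion and power", {
  tr <- short_trial(rep(70 * 9.81, 2000))
  kin <- integrate_motion(tr, body_mass = 70, onset = 1L)
  expect_true(all(abs(kin$velocity) < 1e-12))
  expect_true(all(abs(kin$power) < 1e-12))
})

test_that("take-off detection matches generator truth within 5 ms", {
  set.seed(8)
  for (i in 1:5) {
    tr <- simulate_trial(jump_profile_params(noise_sd = 5))
    tru <- attr(tr, "truth")
    to <- detect_takeoff(tr, onset = tru$onset_index)
    expect_lt(abs(to - tru$takeoff_index) / tr$sampling_rate, 0.005)
    ## threshold sensitivity: 10 N vs 20 N differ by at most 2 ms
    to20 <- detect_takeoff(tr, onset = tru$onset_index, threshold = 20)
    expect_lte(abs(to - to20) / tr$sampling_rate, 0.002)
  }
})

test_that("a trial truncated before flight has no take-off", {
  p <- quiet_params()
  tr <- simulate_trial(p)
  tru <- attr(tr, "truth")
  cut <- short_trial(tr$force[1:(tru$takeoff_index - 50)])
  expect_error(detect_takeoff(cut, onset = tru$onset_index),
               class = "no_flight")
})

test_that("segmentation finds the analytic zero crossing of a sine velocity", {
  t <- (0:1000) / 1000
  v <- -sin(2 * pi * t)
  kin <- manual_kinematics(v)
  seg <- segment_phases(kin, onset = 1L, takeoff = 1001L)
  expect_equal(kin$time[seg$min_velocity_index], 0.25, tolerance = 1e-3)
  expect_equal(seg$eob_time, 0.5, tolerance = 1e-6)
  expect_identical(seg$end_of_braking_index, 502L)  # snapped to later sample
  expect_true(seg$onset_index < seg$min_velocity_index &&
                seg$min_velocity_index < seg$end_of_braking_index &&
                seg$end_of_braking_index <= seg$takeoff_index)
})

test_that("monotone positive velocity (no countermovement) is rejected", {
  kin <- manual_kinematics(seq(0, 2, length.out = 500))
  expect_error(segment_phases(kin, onset = 1L, takeoff = 500L),
               class = "no_countermovement")
})

test_that("segmented phase durations match the generating values", {
  tr <- simulate_trial(quiet_params(ecc_duration = 0.35, con_duration = 0.25))
  tru <- attr(tr, "truth")
  kin <- integrate_motion(tr, body_mass = 65.7, onset = tru$onset_index)
  seg <- segment_phases(kin, takeoff = tru$takeoff_index)
  rate <- tr$sampling_rate
  expect_lte(abs((seg$end_of_braking_index - seg$onset_index) / rate - 0.35),
             1 / rate + 1e-12)
  expect_lte(abs((seg$takeoff_index - seg$end_of_braking_index) / rate - 0.25),
             1 / rate + 1e-12)
})

test_that("impulse-momentum holds over the phases", {
  tr <- simulate_trial(quiet_params())
  tru <- attr(tr, "truth")
  kin <- integrate_motion(tr, body_mass = 65.7, onset = tru$onset_index)
  seg <- segment_phases(kin, takeoff = tru$takeoff_index)
  v_eob <- approx(kin$time, kin$velocity, xout = seg$eob_time)$y
  ## eccentric net impulse vanishes at the interpolated boundary
  expect_lt(abs(v_eob), 1e-6)
  ## concentric net impulse equals take-off velocity
  expect_lt(abs((kin$velocity[seg$takeoff_index] - v_eob) - tru$v_takeoff),
            1e-3)
})

test_that("integration error shrinks superlinearly with the time step", {
  err <- sapply(c(500, 1000, 2000, 4000), function(rate) {
    p <- quiet_params(sampling_rate = rate)
    kin <- simulate_velocity_profile(p)
    tr <- velocity_to_force(kin, quiet_duration = 1, landing = FALSE)
    k2 <- integrate_motion(tr, body_mass = p$body_mass, onset = rate + 1L)
    abs(k2$velocity[length(k2$velocity)] - p$takeoff_velocity)
  })
  ## quadrupling the rate cuts the error by well over 4x (near O(h^2);
  ## single-step ratios fluctuate with how the grid straddles phase kinks)
  expect_gt(err[1] / err[3], 4)
  expect_gt(err[2] / err[4], 4)
})
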