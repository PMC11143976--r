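test_that("velocity profile satisfies its endpoint constraints", {
  p <- quiet_params(peak_downward_velocity = 1.35, takeoff_velocity = 3.08)
  kin <- simulate_velocity_profile(p)
  ## grid may straddle the analytic minimum by half a sample
  expect_lt(abs(min(kin$velocity) - -1.35), 1e-4)
  expect_gte(min(kin$velocity), -1.35 - 1e-9)
  expect_equal(kin$velocity[length(kin$velocity)], 3.08, tolerance = 1e-9)
  expect_equal(kin$velocity[1], 0)
  expect_equal(kin$acceleration[1], 0)
  ## zero plate force at take-off
  expect_equal(kin$acceleration[length(kin$acceleration)], -kin$gravity)
  ## exactly one upward zero crossing
  v <- kin$velocity[-c(1, length(kin$velocity))]
  s <- sign(v[v != 0])
  expect_identical(sum(diff(s) > 0), 1L)
})

test_that("phase durations are realized on the sample grid", {
  p <- quiet_params(ecc_duration = 0.35, con_duration = 0.25)
  kin <- simulate_velocity_profile(p)
  dt <- 1 / p$sampling_rate
  v <- kin$velocity
  i_cross <- which(v[-length(v)] <= 0 & v[-1] > 0)[1] + 1L
  expect_lt(abs(kin$time[i_cross] - 0.35), dt + 1e-12)
  expect_lt(abs(kin$time[length(v)] - kin$time[i_cross] - 0.25), dt + 1e-12)
})

test_that("doubling the sampling rate leaves the velocity model unchanged", {
  p1 <- quiet_params(sampling_rate = 1000)
  p2 <- quiet_params(sampling_rate = 2000)
  k1 <- simulate_velocity_profile(p1)
  k2 <- simulate_velocity_profile(p2)
  shared <- seq(1, length(k2$velocity), by = 2)[seq_along(k1$velocity)]
  expect_lt(max(abs(k1$velocity - k2$velocity[shared])), 1e-9)
})

test_that("infeasible parameter combinations raise an explicit error", {
  ## unweighting would require more than free fall
  p <- quiet_params(peak_downward_velocity = 3.5, ecc_duration = 0.2)
  expect_error(simulate_velocity_profile(p), class = "infeasible_profile")
  expect_error(quiet_params(ecc_duration = -0.1), class = "invalid_parameter")
})

test_that("static kinematics invert to body weight", {
  kin <- manual_kinematics(rep(0, 1000), acceleration = rep(0, 1000))
  tr <- velocity_to_force(kin, body_mass = 70, quiet_duration = 0.5,
                          landing = FALSE)
  n_move <- 1000
  moving <- tail(tr$force, n_move)
  expect_true(all(abs(moving - 70 * 9.81) < 1e-9))
})

test_that("round trip through force and integration recovers take-off velocity", {
  p <- quiet_params()
  kin <- simulate_velocity_profile(p)
  tr <- velocity_to_force(kin, quiet_duration = 1.5)
  tru <- attr(tr, "truth")
  k2 <- integrate_motion(tr, body_mass = p$body_mass, onset = tru$onset_index)
  expect_lt(abs(k2$velocity[tru$takeoff_index] - p$takeoff_velocity), 1e-3)
  ## per-sample velocity agreement within trapezoidal O(h^2) error
  idx <- tru$onset_index:tru$takeoff_index
  expect_lt(max(abs(k2$velocity[idx] - kin$velocity)), 1e-4)
})

test_that("flight apex matches ballistic closed form", {
  p <- quiet_params()
  tr <- simulate_trial(p)
  tru <- attr(tr, "truth")
  kin <- integrate_motion(tr, body_mass = p$body_mass, onset = tru$onset_index)
  d <- kin$displacement
  apex <- max(d) - d[tru$takeoff_index]
  expect_lt(abs(apex - tru$v_takeoff^2 / (2 * 9.81)) * 100, 0.1)  # cm
})

test_that("windowed force reduction cuts window force by the stated fraction", {
  p <- quiet_params()
  tr0 <- simulate_trial(p)
  tr1 <- simulate_trial(p, fatigue_effect(0.15, c(50, 75), 1, 1, 1))
  tru <- attr(tr0, "truth")
  idx <- tru$onset_index:tru$takeoff_index
  t_rel <- (idx - tru$onset_index) / p$sampling_rate
  q <- ifelse(t_rel <= tru$ecc_duration, 50 * t_rel / tru$ecc_duration,
              50 + 50 * (t_rel - tru$ecc_duration) /
                (tru$takeoff_time - tru$onset_time - tru$ecc_duration))
  inside <- q >= 50 & q <= 75
  ratio <- mean(tr1$force[idx][inside]) / mean(tr0$force[idx][inside])
  expect_equal(ratio, 0.85, tolerance = 1e-9)
  outside_ecc <- q < 50
  expect_equal(tr1$force[idx][outside_ecc], tr0$force[idx][outside_ecc])
})

test_that("cohort generation is deterministic under seed", {
  spec <- cohort_spec(n_participants = 2, conditions = c("baseline", "3min"),
                      trials_per_session = 1, seed = 99)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(lapply(c1$trials, `[[`, "force"),
                   lapply(c2$trials, `[[`, "force"))
  expect_identical(c1$truth, c2$truth)
})

test_that("identity effects produce exchangeable conditions", {
  spec <- cohort_spec(n_participants = 30, conditions = c("baseline", "sham"),
                      trials_per_session = 2, seed = 5)
  fx <- list(baseline = fatigue_effect(), sham = fatigue_effect())
  tab <- draw_cohort_params(spec, effects = fx)
  agg <- tapply(tab$takeoff_velocity, tab$condition, mean)
  ## same generating distribution: means differ only by sampling noise
  expect_lt(abs(diff(agg)) / mean(agg), 0.02)
})

test_that("noise-free physical consistency holds across a parameter sweep", {
  spec <- cohort_spec(n_participants = 5, trials_per_session = 1, seed = 21)
  base <- quiet_params()
  cohort <- simulate_cohort(spec, base)
  for (tr in cohort$trials) {
    tru <- attr(tr, "truth")
    idx <- tru$onset_index:tru$takeoff_index
    t <- (idx - idx[1]) / tr$sampling_rate
    net_v <- pracma::trapz(t, tr$force[idx] / tr$body_mass - 9.81)
    expect_lt(abs(net_v - tru$v_takeoff), 1e-4)
  }
})

test_that("analysis pipeline recovers generating values on noise-free trials", {
  spec <- cohort_spec(n_participants = 5, conditions = c("baseline", "3min"),
                      trials_per_session = 2, seed = 31)
  cohort <- simulate_cohort(spec, quiet_params())
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    tru <- attr(tr, "truth")
    v <- analyze_trial(tr, Q = NULL)$variables
    expect_lt(abs(v$jh_cm - tru$jump_height_cm) / tru$jump_height_cm, 0.01)
    expect_lt(abs(v$eccdur_s - tru$ecc_duration), 0.005)
    expect_lt(abs(v$condur_s - tru$con_duration), 0.005)
  }
})

test_that("written cohorts round trip through the manifest", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_participants = 2, conditions = c("baseline", "3min"),
                      trials_per_session = 1, seed = 77)
  cohort <- simulate_cohort(spec)
  man <- write_cohort(cohort, dir)
  man2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man2), nrow(cohort$manifest))
  tr <- read_force_trial(file.path(dir, man$file[1]))
  expect_lt(max(abs(tr$force - cohort$trials[[1]]$force)), 1e-9)
})
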