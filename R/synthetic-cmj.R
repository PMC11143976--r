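## Synthetic countermovement-jump waveform generator.
##
## The centre-of-mass (COM) vertical velocity is built first, from piecewise
## polynomials satisfying the phase-boundary constraints of a CMJ (zero at
## movement onset, a single downward minimum, a single upward zero crossing at
## the end of braking, the take-off velocity at take-off with zero plate force
## there).  Vertical ground-reaction force then follows from Newton's second
## law, F = m (g + dv/dt), which guarantees that the analysis pipeline's
## impulse-momentum integration inverts the generator exactly.

#' Parameters of a synthetic countermovement jump
#'
#' Defines one jump waveform: the performer's mass, the duration of quiet
#' standing before the movement, the eccentric (onset to end of braking) and
#' concentric (end of braking to take-off) phase durations, the magnitude of
#' the downward COM velocity minimum, the take-off velocity, and the sampling
#' and noise characteristics of the simulated force plate.
#'
#' Defaults describe a male collegiate sprinter population: body mass 65.7 kg,
#' eccentric/concentric durations 0.35 s / 0.25 s, peak downward velocity
#' 1.35 m/s and take-off velocity 3.08 m/s (a ~49 cm jump), sampled at
#' 1000 Hz with 5 N additive plate noise.
#'
#' @param body_mass body mass in kg.
#' @param quiet_duration quiet-standing duration prepended before onset (s).
#' @param ecc_duration eccentric phase duration (s).
#' @param con_duration concentric phase duration (s).
#' @param peak_downward_velocity magnitude of the COM velocity minimum (m/s).
#' @param takeoff_velocity COM velocity at take-off (m/s).
#' @param concentric_shape fraction of the concentric phase at which net
#'   acceleration (hence force) peaks; skews the concentric force pulse.
#' @param noise_sd standard deviation of additive white Gaussian plate noise (N).
#' @param sampling_rate force-plate sampling rate (Hz).
#' @param min_velocity_frac fraction of the eccentric phase at which the
#'   downward velocity minimum occurs (unweighting/braking split).
#' @param braking_slope_factor end-of-braking net acceleration expressed as a
#'   multiple of the mean braking slope; must lie in (0, 3] so the braking
#'   velocity segment is monotone.
#' @param gravity gravitational acceleration (m/s^2).
#' @return An object of class `jump_profile_params`.
#' @export
jump_profile_params <- function(body_mass = 65.7,
                                quiet_duration = 1.5,
                                ecc_duration = 0.35,
                                con_duration = 0.25,
                                peak_downward_velocity = 1.35,
                                takeoff_velocity = 3.08,
                                concentric_shape = 0.1,
                                noise_sd = 5,
                                sampling_rate = 1000,
                                min_velocity_frac = 0.65,
                                braking_slope_factor = 1.5,
                                gravity = GRAVITY) {
  assert_scalar_pos(body_mass, "body_mass")
  assert_scalar_pos(quiet_duration, "quiet_duration")
  assert_scalar_pos(ecc_duration, "ecc_duration")
  assert_scalar_pos(con_duration, "con_duration")
  assert_scalar_pos(peak_downward_velocity, "peak_downward_velocity")
  assert_scalar_pos(takeoff_velocity, "takeoff_velocity")
  assert_fraction(concentric_shape, "concentric_shape")
  assert_fraction(min_velocity_frac, "min_velocity_frac")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_cmj("invalid_parameter", "`noise_sd` must be >= 0")
  assert_scalar_pos(sampling_rate, "sampling_rate")
  assert_scalar_pos(gravity, "gravity")
  if (braking_slope_factor <= 0 || braking_slope_factor > 3)
    stop_cmj("invalid_parameter", "`braking_slope_factor` must lie in (0, 3]")
  structure(list(
    body_mass = body_mass, quiet_duration = quiet_duration,
    ecc_duration = ecc_duration, con_duration = con_duration,
    peak_downward_velocity = peak_downward_velocity,
    takeoff_velocity = takeoff_velocity,
    concentric_shape = concentric_shape, noise_sd = noise_sd,
    sampling_rate = sampling_rate, min_velocity_frac = min_velocity_frac,
    braking_slope_factor = braking_slope_factor, gravity = gravity
  ), class = "jump_profile_params")
}

## Piecewise-polynomial COM velocity model evaluated at arbitrary times.
## Returns velocity, acceleration and displacement analytically.
velocity_model <- function(params) {
  Te <- params$ecc_duration
  Tc <- params$con_duration
  vd <- params$peak_downward_velocity
  vt <- params$takeoff_velocity
  g  <- params$gravity
  t1 <- params$min_velocity_frac * Te
  h  <- Te - t1
  s2 <- params$braking_slope_factor * vd / h   # net accel at end of braking

  ## Concentric quartic v(s) = a1 s + a2 s^2 + a3 s^3 + a4 s^4, s in [0,1].
  sig <- params$concentric_shape
  a1 <- s2 * Tc
  A <- rbind(c(1, 1, 1),
             c(2, 3, 4),
             c(2, 6 * sig, 12 * sig^2))
  b <- c(vt - a1, -g * Tc - a1, 0)
  a234 <- tryCatch(solve(A, b), error = function(e)
    stop_cmj("infeasible_profile", "concentric shape system is singular"))
  cq <- c(0, a1, a234)  # coefficients a0..a4

  ## Unweighting acceleration: raised-cosine trapezoid bump (taper fraction
  ## r), flatter than a polynomial bump so that deep unweighting stays above
  ## zero plate force (|a| stays below g with a margin).
  r <- 0.2
  unweight <- function(x) {
    w <- ifelse(x < r, 0.5 * (1 - cos(pi * x / r)),
                ifelse(x <= 1 - r, 1, 0.5 * (1 - cos(pi * (1 - x) / r))))
    W <- ifelse(x < r, 0.5 * (x - (r / pi) * sin(pi * x / r)),
                ifelse(x <= 1 - r, r / 2 + (x - r),
                       r / 2 + (1 - 2 * r) +
                         0.5 * r - 0.5 * ((1 - x) - (r / pi) * sin(pi * (1 - x) / r))))
    list(w = w, W = W)
  }

  eval_piece <- function(t) {
    v <- numeric(length(t)); a <- numeric(length(t))
    ## unweighting: descend 0 -> -vd on [0, t1], a(0) = a(t1) = 0
    i <- t >= 0 & t < t1
    if (any(i)) {
      u <- unweight(t[i] / t1)
      a[i] <- -vd / (t1 * (1 - r)) * u$w
      v[i] <- -vd / (1 - r) * u$W
    }
    ## braking: cubic Hermite -vd -> 0 with slopes 0 -> s2 on [t1, Te]
    i <- t >= t1 & t < Te
    if (any(i)) {
      x <- (t[i] - t1) / h
      h00 <- 2 * x^3 - 3 * x^2 + 1
      h11 <- x^3 - x^2
      v[i] <- -vd * h00 + s2 * h * h11
      a[i] <- (-vd * (6 * x^2 - 6 * x) + s2 * h * (3 * x^2 - 2 * x)) / h
    }
    ## concentric: quartic on [Te, Te + Tc]
    i <- t >= Te
    if (any(i)) {
      x <- pmin((t[i] - Te) / Tc, 1)
      v[i] <- cq[1] + cq[2] * x + cq[3] * x^2 + cq[4] * x^3 + cq[5] * x^4
      a[i] <- (cq[2] + 2 * cq[3] * x + 3 * cq[4] * x^2 + 4 * cq[5] * x^3) / Tc
    }
    list(velocity = v, acceleration = a)
  }
  list(eval = eval_piece, t_min = t1, t_eob = Te, t_takeoff = Te + Tc)
}


#' Simulate a COM velocity profile for one jump
#'
#' Builds the piecewise-polynomial COM velocity satisfying the jump's
#' endpoint constraints: v = 0 at onset with zero slope (force equals body
#' weight), a single minimum of magnitude `peak_downward_velocity`, a single
#' upward zero crossing at the end of braking, and `takeoff_velocity` at
#' take-off where net acceleration equals `-gravity` (zero plate force).
#' Acceleration and displacement are the exact analytic derivative/integral
#' of the velocity.
#'
#' @param params a [jump_profile_params()] object.
#' @return A `cmj_kinematics` object sampled at `params$sampling_rate`
#'   covering onset (t = 0) to take-off, with fields `time`, `acceleration`
#'   (net, m/s^2), `velocity` (m/s), `displacement` (m), `power` (W/kg),
#'   `gravity`, `sampling_rate`, `onset_index` and phase-boundary metadata.
#' @export
simulate_velocity_profile <- function(params) {
  stopifnot(inherits(params, "jump_profile_params"))
  vm <- velocity_model(params)
  rate <- params$sampling_rate
  n <- round(vm$t_takeoff * rate)
  if (n < 20)
    stop_cmj("infeasible_profile",
             "durations too short for the sampling rate (%d samples)", n)
  t <- (0:n) / rate
  ev <- vm$eval(t)
  ## physical feasibility: the plate cannot pull (F >= 0 <=> a >= -g)
  dense <- vm$eval(seq(0, vm$t_takeoff, length.out = 4001))
  if (min(dense$acceleration) < -params$gravity - 1e-6)
    stop_cmj("infeasible_profile",
             "implied force is negative (profile too violent)")
  s <- sign(dense$velocity[-c(1, length(dense$velocity))])
  up_cross <- sum(diff(s[s != 0]) > 0)
  if (up_cross != 1)
    stop_cmj("infeasible_profile",
             "velocity must cross zero upward exactly once (found %d)", up_cross)
  structure(list(
    time = t,
    acceleration = ev$acceleration,
    velocity = ev$velocity,
    displacement = drop(pracma::cumtrapz(t, ev$velocity)),
    power = (ev$acceleration + params$gravity) * ev$velocity,
    gravity = params$gravity,
    sampling_rate = rate,
    onset_index = 1L,
    body_mass = params$body_mass,
    boundaries = list(t_min = vm$t_min, t_eob = vm$t_eob,
                      t_takeoff = vm$t_takeoff),
    params = params
  ), class = "cmj_kinematics")
}

#' Convert a kinematic series to a force-plate trial
#'
#' Inverts Newton's second law, F = m (g + dv/dt), prepends a quiet-standing
#' segment at body weight, and appends a flight segment at zero force followed
#' by a half-sine landing pulse and a short quiet tail. Optional additive
#' white Gaussian noise emulates plate noise; negative samples are clamped to
#' zero (a force plate cannot pull).
#'
#' @param kin a `cmj_kinematics` object from [simulate_velocity_profile()].
#' @param body_mass body mass in kg.
#' @param quiet_duration quiet-standing duration before onset (s).
#' @param noise_sd additive noise SD (N); 0 for a noise-free trial.
#' @param participant,condition,trial identifier labels stored on the trial.
#' @param landing if `TRUE`, append the ballistic flight and landing segments.
#' @return A [force_trial()] object with a `truth` attribute holding the
#'   generating quantities (onset/end-of-braking/take-off times, take-off and
#'   peak velocity, phase durations, jump height).
#' @export
velocity_to_force <- function(kin, body_mass = kin$body_mass,
                              quiet_duration = 1.5, noise_sd = 0,
                              participant = NA_character_,
                              condition = NA_character_, trial = NA_integer_,
                              landing = TRUE) {
  stopifnot(inherits(kin, "cmj_kinematics"))
  g <- kin$gravity
  rate <- kin$sampling_rate
  f_move <- body_mass * (kin$acceleration + g)
  if (min(f_move) < -1e-6)
    stop_cmj("infeasible_profile", "implied force is negative (profile too violent)")
  assemble_trial(f_move, kin, body_mass, quiet_duration, noise_sd,
                 participant, condition, trial, landing)
}

## Shared assembly: quiet segment + movement force + flight/landing + noise.
assemble_trial <- function(f_move, kin, body_mass, quiet_duration, noise_sd,
                           participant, condition, trial, landing = TRUE) {
  g <- kin$gravity
  rate <- kin$sampling_rate
  bw <- body_mass * g
  n_quiet <- round(quiet_duration * rate)
  ## realized kinematics of the (possibly modified) movement force
  a <- f_move / body_mass - g
  v <- drop(pracma::cumtrapz(kin$time, a))
  v_takeoff <- v[length(v)]
  i_min <- which.min(v)
  cross <- which(v[-length(v)] <= 0 & v[-1] > 0)
  cross <- cross[cross >= i_min]
  i_eob <- if (length(cross)) cross[1] + 1L else NA_integer_
  v_peak <- max(v[seq(if (is.na(i_eob)) 1L else i_eob, length(v))])
  t_flight <- 2 * v_takeoff / g
  segs <- list(rep(bw, n_quiet), f_move)
  if (landing && v_takeoff > 0) {
    n_fl <- round(t_flight * rate)
    t_land <- 0.15
    n_land <- round(t_land * rate)
    amp <- pi * body_mass * (v_takeoff + g * t_land) / (2 * t_land)
    pulse <- amp * sin(pi * seq_len(n_land) / n_land)
    segs <- c(segs, list(rep(0, n_fl), pulse, rep(bw, round(0.3 * rate))))
  }
  force <- unlist(segs, use.names = FALSE)
  if (noise_sd > 0) force <- force + rnorm(length(force), 0, noise_sd)
  force[force < 0] <- 0
  tr <- force_trial(force, sampling_rate = rate, body_mass = body_mass,
                    participant = participant, condition = condition,
                    trial = trial, min_duration = 0)
  attr(tr, "truth") <- list(
    onset_time = n_quiet / rate,
    onset_index = n_quiet + 1L,
    eob_time = n_quiet / rate + (if (is.na(i_eob)) NA_real_ else kin$time[i_eob]),
    takeoff_time = n_quiet / rate + kin$time[length(kin$time)],
    takeoff_index = n_quiet + length(f_move),
    v_takeoff = v_takeoff, v_peak = v_peak, v_min = v[i_min],
    ecc_duration = if (is.na(i_eob)) NA_real_ else kin$time[i_eob],
    con_duration = if (is.na(i_eob)) NA_real_ else
      kin$time[length(kin$time)] - kin$time[i_eob],
    jump_height_cm = 100 * v_peak^2 / (2 * g),
    flight_time = t_flight
  )
  tr
}

#' Fatigue effect applied to a jump profile
#'
#' Describes how a fatigue condition alters the jump: multiplicative scaling
#' of the eccentric and concentric phase durations and of the take-off
#' velocity, plus a fractional force reduction applied over a window of
#' normalized movement time (eccentric phase mapped to 0-50%, concentric to
#' 50-100%). The default window, 50-75%, depresses force in the early
#' concentric region.
#'
#' @param con_force_reduction fraction in \[0, 1) by which force is reduced
#'   inside `window`.
#' @param window two-element numeric, normalized-time window in percent.
#' @param ecc_duration_scale,con_duration_scale,takeoff_velocity_scale
#'   positive multiplicative scales.
#' @return An object of class `fatigue_effect`.
#' @export
fatigue_effect <- function(con_force_reduction = 0, window = c(50, 75),
                           ecc_duration_scale = 1, con_duration_scale = 1,
                           takeoff_velocity_scale = 1) {
  assert_fraction(con_force_reduction, "con_force_reduction", open = FALSE)
  if (length(window) != 2 || any(!is.finite(window)) ||
      window[1] < 0 || window[2] > 100 || window[1] >= window[2])
    stop_cmj("invalid_parameter", "`window` must be an increasing pair within [0, 100]")
  for (nm in c("ecc_duration_scale", "con_duration_scale", "takeoff_velocity_scale"))
    assert_scalar_pos(get(nm), nm)
  structure(list(con_force_reduction = con_force_reduction, window = window,
                 ecc_duration_scale = ecc_duration_scale,
                 con_duration_scale = con_duration_scale,
                 takeoff_velocity_scale = takeoff_velocity_scale),
            class = "fatigue_effect")
}

#' Default per-condition fatigue effects
#'
#' Calibrated so that a default cohort approximates the recovery time-course
#' of a 400 m sprint fatigue protocol in trained sprinters: a large decrement
#' 3 min post-exercise, partial recovery by 10 min and 1 h, and a small
#' residual concentric deficit at 24 h, with a relatively lengthened
#' concentric phase throughout.
#'
#' @param conditions condition labels; `"baseline"` maps to an identity effect.
#' @return Named list of [fatigue_effect()] objects.
#' @export
default_fatigue_effects <- function(conditions = cmj_conditions()) {
  ## The windowed early-concentric force cut is the primary mechanism; its
  ## size is set so the realized take-off velocity (hence concentric impulse)
  ## reproduces the recovery time-course of the emulated protocol (about
  ## -19%, -10%, -5%, -3% at 3 min, 10 min, 1 h, 24 h), with phase-duration
  ## scales lengthening the concentric phase relative to the eccentric one.
  defaults <- list(
    baseline = fatigue_effect(),
    `3min`  = fatigue_effect(0.17, c(50, 75), 0.94, 1.12, 1),
    `10min` = fatigue_effect(0.09, c(50, 75), 0.91, 1.04, 1),
    `1hr`   = fatigue_effect(0.043, c(50, 75), 0.97, 1.08, 1),
    `24hr`  = fatigue_effect(0.027, c(50, 75), 0.97, 1.08, 1)
  )
  out <- lapply(conditions, function(cn) defaults[[cn]] %||% fatigue_effect())
  names(out) <- conditions
  out
}

#' Canonical session condition labels
#' @return Character vector `c("baseline","3min","10min","1hr","24hr")`.
#' @export
cmj_conditions <- function() c("baseline", "3min", "10min", "1hr", "24hr")

#' Specification of a simulated study cohort
#'
#' Sample sizes and variability of a whole simulated study:
#' `n_participants` athletes each measured in every condition with
#' `trials_per_session` jumps per session. Between-subject and within-subject
#' (trial-to-trial) variability act as lognormal multipliers on the profile
#' durations and velocities, keeping them positive.
#'
#' @param n_participants number of participants (>= 2).
#' @param conditions ordered condition labels; first is the reference.
#' @param trials_per_session jumps per participant per session (>= 1).
#' @param between_sd,within_sd named lists of lognormal sdlog values for
#'   `ecc_duration`, `con_duration`, `peak_downward_velocity`,
#'   `takeoff_velocity`.
#' @param body_mass_mean,body_mass_sd Gaussian body-mass distribution (kg).
#' @param rpe_means,rpe_sds optional named per-condition mean/SD of the Borg
#'   6-20 rating of perceived exertion; defaults emulate the acute spike and
#'   24 h recovery of a sprint fatigue protocol.
#' @param rpe_cor within-participant correlation of RPE across conditions.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 10,
                        conditions = cmj_conditions(),
                        trials_per_session = 3,
                        between_sd = list(ecc_duration = 0.12,
                                          con_duration = 0.12,
                                          peak_downward_velocity = 0.18,
                                          takeoff_velocity = 0.06),
                        within_sd = list(ecc_duration = 0.05,
                                         con_duration = 0.05,
                                         peak_downward_velocity = 0.05,
                                         takeoff_velocity = 0.02),
                        body_mass_mean = 65.7, body_mass_sd = 5.0,
                        rpe_means = NULL, rpe_sds = NULL, rpe_cor = 0.5,
                        seed = NULL) {
  if (n_participants < 2) stop_cmj("invalid_parameter", "`n_participants` must be >= 2")
  if (trials_per_session < 1) stop_cmj("invalid_parameter", "`trials_per_session` must be >= 1")
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop_cmj("invalid_parameter", "duplicate condition labels")
  rpe_def <- c(baseline = 10.4, `3min` = 18.8, `10min` = 16.6,
               `1hr` = 11.0, `24hr` = 9.2)
  rpe_sd_def <- c(baseline = 3.03, `3min` = 1.14, `10min` = 1.51,
                  `1hr` = 2.40, `24hr` = 3.26)
  if (is.null(rpe_means)) {
    rpe_means <- ifelse(conditions %in% names(rpe_def), rpe_def[conditions], 12)
    names(rpe_means) <- conditions
  }
  if (is.null(rpe_sds)) {
    rpe_sds <- ifelse(conditions %in% names(rpe_sd_def), rpe_sd_def[conditions], 2)
    names(rpe_sds) <- conditions
  }
  structure(list(n_participants = as.integer(n_participants),
                 conditions = conditions,
                 trials_per_session = as.integer(trials_per_session),
                 between_sd = between_sd, within_sd = within_sd,
                 body_mass_mean = body_mass_mean, body_mass_sd = body_mass_sd,
                 rpe_means = rpe_means, rpe_sds = rpe_sds, rpe_cor = rpe_cor,
                 seed = seed), class = "cohort_spec")
}

## Draw the per-trial generating parameter table for a cohort (no waveforms).
## Exposed because parameter-level nulls are useful for fast calibration
## studies of the downstream statistics.

#' Draw per-trial generating parameters for a cohort
#'
#' Performs all random draws of [simulate_cohort()] (participant body mass and
#' lognormal multipliers, trial-level multipliers, per-session RPE) and
#' returns the resulting per-trial parameter table without synthesizing any
#' waveform. `simulate_cohort()` builds its trials from exactly this table.
#'
#' @inheritParams simulate_cohort
#' @return A data frame with one row per trial: identifiers, body mass, RPE,
#'   and the effective profile parameters (after fatigue scaling, before the
#'   windowed force reduction, which is waveform-level).
#' @export
draw_cohort_params <- function(spec, baseline = jump_profile_params(),
                               effects = default_fatigue_effects(spec$conditions)) {
  stopifnot(inherits(spec, "cohort_spec"))
  missing_fx <- setdiff(spec$conditions, names(effects))
  if (length(missing_fx))
    stop_cmj("invalid_parameter", "no fatigue_effect for condition(s): %s",
             paste(missing_fx, collapse = ", "))
  with_seed(spec$seed, {
    n <- spec$n_participants
    ids <- sprintf("P%02d", seq_len(n))
    mass <- pmax(rnorm(n, spec$body_mass_mean, spec$body_mass_sd), 40)
    pnames <- c("ecc_duration", "con_duration", "peak_downward_velocity",
                "takeoff_velocity")
    bsd <- vapply(pnames, function(p) spec$between_sd[[p]] %||% 0, 0)
    wsd <- vapply(pnames, function(p) spec$within_sd[[p]] %||% 0, 0)
    bmult <- exp(matrix(rnorm(n * 4), n, 4,
                        dimnames = list(NULL, pnames)) %*% diag(bsd))
    colnames(bmult) <- pnames
    z_rpe <- rnorm(n)
    nc <- length(spec$conditions)
    ntr <- spec$trials_per_session
    nrow_total <- n * nc * ntr
    idx_p <- rep(seq_len(n), each = nc * ntr)
    idx_c <- rep(rep(seq_len(nc), each = ntr), times = n)
    rpe_tab <- matrix(NA_real_, n, nc)
    for (i in seq_len(n)) for (j in seq_len(nc)) {
      cn <- spec$conditions[j]
      r <- spec$rpe_means[[cn]] + spec$rpe_sds[[cn]] *
        (sqrt(spec$rpe_cor) * z_rpe[i] + sqrt(1 - spec$rpe_cor) * rnorm(1))
      rpe_tab[i, j] <- min(max(round(r), 6), 20)
    }
    wmult <- exp(matrix(rnorm(nrow_total * 4), nrow_total, 4) %*% diag(wsd))
    colnames(wmult) <- pnames
    fx_of <- function(j) effects[[spec$conditions[j]]]
    ecc_scale <- vapply(seq_len(nc), function(j) fx_of(j)$ecc_duration_scale, 0)
    con_scale <- vapply(seq_len(nc), function(j) fx_of(j)$con_duration_scale, 0)
    vto_scale <- vapply(seq_len(nc), function(j) fx_of(j)$takeoff_velocity_scale, 0)
    row_params <- function(r, w) {
      i <- idx_p[r]; j <- idx_c[r]
      c(ecc = baseline$ecc_duration * bmult[i, 1] * w[1] * ecc_scale[j],
        con = baseline$con_duration * bmult[i, 2] * w[2] * con_scale[j],
        vd = baseline$peak_downward_velocity * bmult[i, 3] * w[3],
        vto = baseline$takeoff_velocity * bmult[i, 4] * w[4] * vto_scale[j])
    }
    out <- matrix(NA_real_, nrow_total, 4,
                  dimnames = list(NULL, c("ecc_duration", "con_duration",
                                          "peak_downward_velocity",
                                          "takeoff_velocity")))
    for (r in seq_len(nrow_total)) {
      ## rejection-sample trial-level draws into the physically feasible
      ## region (non-negative plate force); extreme participant-level draws
      ## are progressively shrunk toward the population centre
      w <- wmult[r, ]
      pr <- row_params(r, w)
      attempt <- 1L
      while (!feasible_raw(pr[1], pr[2], pr[3], pr[4], baseline)) {
        attempt <- attempt + 1L
        if (attempt > 200L)
          stop_cmj("infeasible_profile",
                   "could not draw a feasible trial for %s/%s",
                   ids[idx_p[r]], spec$conditions[idx_c[r]])
        w <- exp(rnorm(4, 0, wsd))
        if (attempt > 100L) {
          shrink <- 1 - (attempt - 100L) / 100
          i <- idx_p[r]
          bm_save <- bmult[i, ]
          bmult[i, ] <- bm_save^shrink
          pr <- row_params(r, w)
          bmult[i, ] <- bm_save
        } else pr <- row_params(r, w)
      }
      out[r, ] <- pr
    }
    data.frame(participant = ids[idx_p],
               condition = spec$conditions[idx_c],
               trial = rep(seq_len(ntr), times = n * nc),
               body_mass = mass[idx_p],
               rpe = rpe_tab[cbind(idx_p, idx_c)],
               out,
               con_force_reduction = vapply(idx_c, function(j)
                 fx_of(j)$con_force_reduction, 0),
               window_lo = vapply(idx_c, function(j) fx_of(j)$window[1], 0),
               window_hi = vapply(idx_c, function(j) fx_of(j)$window[2], 0),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

## Fast feasibility check on raw parameter values: closed-form bound for the
## unweighting pulse, coarse grid for braking and the concentric quartic.
feasible_raw <- function(ecc, con, vd, vto, baseline, margin = 1.0,
                         tail_exempt = 0.05) {
  if (min(ecc, con, vd, vto) <= 0) return(FALSE)
  g <- baseline$gravity
  t1 <- baseline$min_velocity_frac * ecc
  ## unweighting peak net acceleration (taper fraction 0.2)
  if (vd / (t1 * 0.8) > g - margin) return(FALSE)
  h <- ecc - t1
  s2 <- baseline$braking_slope_factor * vd / h
  ## braking accel (quadratic in x): evaluate on coarse grid
  x <- seq(0, 1, length.out = 21)
  a_br <- (-vd * (6 * x^2 - 6 * x) + s2 * h * (3 * x^2 - 2 * x)) / h
  if (min(a_br) < -(g - margin)) return(FALSE)
  ## concentric quartic accel
  sig <- baseline$concentric_shape
  a1 <- s2 * con
  A <- rbind(c(1, 1, 1), c(2, 3, 4), c(2, 6 * sig, 12 * sig^2))
  cq <- tryCatch(c(0, a1, solve(A, c(vto - a1, -g * con - a1, 0))),
                 error = function(e) NULL)
  if (is.null(cq)) return(FALSE)
  s <- seq(0, 1, length.out = 41)
  a_con <- (cq[2] + 2 * cq[3] * s + 3 * cq[4] * s^2 + 4 * cq[5] * s^3) / con
  body <- s <= 1 - tail_exempt / con
  if (any(a_con < -g - 1e-9)) return(FALSE)
  if (min(a_con[body]) < -(g - margin)) return(FALSE)
  v_con <- cq[2] * s + cq[3] * s^2 + cq[4] * s^3 + cq[5] * s^4
  all(v_con[-1] > 0)
}

#' Simulate one CMJ force-plate trial
#'
#' Builds the COM velocity profile, applies an optional fatigue effect (its
#' duration/velocity scales modify the profile parameters; its windowed force
#' reduction multiplies the movement force inside the stated normalized-time
#' window), and assembles the full plate record (quiet standing, movement,
#' flight, landing). The `truth` attribute holds the realized (post-effect)
#' kinematic quantities obtained by re-integrating the final noise-free force.
#'
#' @param params a [jump_profile_params()] object.
#' @param effect optional [fatigue_effect()].
#' @param participant,condition,trial identifier labels.
#' @param noise_sd overrides `params$noise_sd` when not `NULL`.
#' @return A [force_trial()] with a `truth` attribute.
#' @export
simulate_trial <- function(params, effect = NULL,
                           participant = NA_character_,
                           condition = NA_character_, trial = NA_integer_,
                           noise_sd = NULL) {
  stopifnot(inherits(params, "jump_profile_params"))
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "fatigue_effect"))
    params <- jump_profile_params(
      body_mass = params$body_mass, quiet_duration = params$quiet_duration,
      ecc_duration = params$ecc_duration * effect$ecc_duration_scale,
      con_duration = params$con_duration * effect$con_duration_scale,
      peak_downward_velocity = params$peak_downward_velocity,
      takeoff_velocity = params$takeoff_velocity * effect$takeoff_velocity_scale,
      concentric_shape = params$concentric_shape, noise_sd = params$noise_sd,
      sampling_rate = params$sampling_rate,
      min_velocity_frac = params$min_velocity_frac,
      braking_slope_factor = params$braking_slope_factor,
      gravity = params$gravity)
  }
  kin <- simulate_velocity_profile(params)
  f_move <- params$body_mass * (kin$acceleration + params$gravity)
  if (!is.null(effect) && effect$con_force_reduction > 0) {
    q <- normalized_time_percent(kin$time, kin$boundaries$t_eob,
                                 kin$boundaries$t_takeoff)
    inside <- q >= effect$window[1] & q <= effect$window[2]
    f_move[inside] <- f_move[inside] * (1 - effect$con_force_reduction)
  }
  assemble_trial(f_move, kin, params$body_mass, params$quiet_duration,
                 noise_sd %||% params$noise_sd, participant, condition, trial)
}

## Map movement time to normalized percent: eccentric [0, t_eob] -> [0, 50],
## concentric [t_eob, t_takeoff] -> [50, 100].
normalized_time_percent <- function(t, t_eob, t_takeoff) {
  ifelse(t <= t_eob, 50 * t / t_eob,
         50 + 50 * (t - t_eob) / (t_takeoff - t_eob))
}

#' Simulate a whole study cohort
#'
#' Generates `n_participants x conditions x trials_per_session` force-plate
#' trials with participant- and trial-level lognormal variability and the
#' per-condition fatigue effects, together with a manifest and a ground-truth
#' table of the generating quantities. Deterministic under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param baseline a [jump_profile_params()] giving the population baseline.
#' @param effects named list of [fatigue_effect()], one per condition.
#' @return A list with elements `trials` (list of [force_trial()]), `manifest`
#'   (data frame: participant, condition, trial, body_mass, rpe) and `truth`
#'   (per-trial generating parameters and realized kinematic quantities).
#' @export
simulate_cohort <- function(spec, baseline = jump_profile_params(),
                            effects = default_fatigue_effects(spec$conditions)) {
  ptab <- draw_cohort_params(spec, baseline, effects)
  noise_seed <- with_seed(spec$seed, sample.int(.Machine$integer.max, 1L))
  with_seed(noise_seed, {
    trials <- vector("list", nrow(ptab))
    truths <- vector("list", nrow(ptab))
    for (r in seq_len(nrow(ptab))) {
      p <- ptab[r, ]
      params <- jump_profile_params(
        body_mass = p$body_mass, quiet_duration = baseline$quiet_duration,
        ecc_duration = p$ecc_duration, con_duration = p$con_duration,
        peak_downward_velocity = p$peak_downward_velocity,
        takeoff_velocity = p$takeoff_velocity,
        concentric_shape = baseline$concentric_shape,
        noise_sd = baseline$noise_sd, sampling_rate = baseline$sampling_rate,
        min_velocity_frac = baseline$min_velocity_frac,
        braking_slope_factor = baseline$braking_slope_factor,
        gravity = baseline$gravity)
      ## duration/velocity scales are already folded into the parameter
      ## table; only the windowed force reduction acts at waveform level
      fx <- effects[[p$condition]]
      fx_wave <- fatigue_effect(fx$con_force_reduction, fx$window, 1, 1, 1)
      tr <- simulate_trial(params, effect = fx_wave,
                           participant = p$participant,
                           condition = p$condition, trial = p$trial)
      trials[[r]] <- tr
      tru <- attr(tr, "truth")
      truths[[r]] <- cbind(p, data.frame(
        v_takeoff_true = tru$v_takeoff, v_peak_true = tru$v_peak,
        jump_height_true_cm = tru$jump_height_cm,
        ecc_duration_true = tru$ecc_duration,
        con_duration_true = tru$con_duration))
    }
    truth <- do.call(rbind, truths)
    rownames(truth) <- NULL
    manifest <- truth[, c("participant", "condition", "trial", "body_mass", "rpe")]
    list(trials = trials, manifest = manifest, truth = truth, spec = spec)
  })
}

#' Write a simulated cohort to disk
#'
#' Writes each trial as a delimited text file (columns `time_s`, `fz_N`), a
#' `manifest.csv` pointing at the files, and a `truth.csv` with the
#' generating parameters.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @param dialect a [trial_dialect()] controlling the trial-file format.
#' @return Invisibly, the manifest with a `file` column.
#' @export
write_cohort <- function(cohort, dir, dialect = trial_dialect()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$file <- sprintf("%s_%s_t%d.csv", man$participant, man$condition, man$trial)
  for (r in seq_len(nrow(man)))
    write_force_trial(cohort$trials[[r]], file.path(dir, man$file[r]), dialect)
  write_manifest(man, file.path(dir, "manifest.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(man)
}
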