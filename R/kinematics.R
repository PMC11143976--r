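## Phase detection and impulse-momentum kinematics.
##
## The jump is segmented as: movement onset (force departs from body weight),
## downward COM-velocity minimum, end of braking (upward zero crossing of the
## COM velocity: the eccentric/concentric boundary) and take-off (force falls
## to the flight threshold).  Velocity, displacement and power follow from
## trapezoidal integration of net acceleration a = F/m - g from onset.

#' Detect movement onset
#'
#' The onset is found where force departs from body weight by more than
#' `k` quiet-standing SDs, then backtracked to the first sample of the
#' departure: the sample after the last one within 1 quiet SD of body weight.
#'
#' @param trial a [force_trial()].
#' @param body_weight_N,quiet_sd_N from [compute_body_weight()].
#' @param k detection threshold in quiet SDs (default 5).
#' @param search_from first sample index eligible for detection.
#' @return Onset sample index (1-based).
#' @export
detect_onset <- function(trial, body_weight_N, quiet_sd_N, k = 5,
                         search_from = 1L) {
  stopifnot(inherits(trial, "force_trial"))
  dev <- abs(trial$force - body_weight_N)
  idx <- which(dev > k * quiet_sd_N)
  idx <- idx[idx >= search_from]
  if (!length(idx))
    stop_cmj("no_movement", "no movement detected: force never departs body weight by %g SD", k)
  cross <- idx[1]
  quiet <- which(dev[seq_len(cross - 1L)] <= quiet_sd_N)
  onset <- if (length(quiet)) max(quiet) + 1L else 1L
  onset
}

#' Detect take-off
#'
#' Take-off is the first sample after `onset` at which force drops below
#' `threshold` and stays below it for at least `min_flight` seconds.
#'
#' @param trial a [force_trial()].
#' @param onset sample index from which to search.
#' @param threshold flight force threshold in N (default 10).
#' @param min_flight minimum sustained sub-threshold duration in seconds.
#' @return Take-off sample index.
#' @export
detect_takeoff <- function(trial, onset = 1L, threshold = 10,
                           min_flight = 0.01) {
  stopifnot(inherits(trial, "force_trial"))
  len <- max(1L, round(min_flight * trial$sampling_rate))
  below <- trial$force < threshold
  below[seq_len(min(onset, length(below)))] <- FALSE
  i <- first_run_start(below, len)
  if (is.na(i))
    stop_cmj("no_flight", "no flight detected (force never < %g N for %g s)",
             threshold, min_flight)
  i
}

#' Detect landing after flight
#'
#' First sample after take-off at which force rises above `threshold` and
#' stays above it for `min_contact` seconds; used for the flight-time jump
#' height cross-check.
#'
#' @param trial a [force_trial()].
#' @param takeoff take-off sample index.
#' @param threshold landing force threshold in N.
#' @param min_contact minimum sustained contact duration in seconds.
#' @return Landing sample index.
#' @export
detect_landing <- function(trial, takeoff, threshold = 20, min_contact = 0.01) {
  stopifnot(inherits(trial, "force_trial"))
  len <- max(1L, round(min_contact * trial$sampling_rate))
  above <- trial$force > threshold
  above[seq_len(min(takeoff, length(above)))] <- FALSE
  i <- first_run_start(above, len)
  if (is.na(i)) stop_cmj("no_landing", "no landing detected after take-off")
  i
}

#' Derive COM kinematics from a force trial
#'
#' Net acceleration a = F/m - g over the whole record; velocity is the
#' cumulative trapezoidal integral of a from onset with v(onset) = 0 (zero
#' before onset); displacement integrates velocity likewise; power per kg is
#' (F/m) * v, the total vertical GRF power convention.
#'
#' @param trial a [force_trial()].
#' @param body_mass body mass in kg; defaults to the trial's.
#' @param onset onset sample index (see [detect_onset()]).
#' @param gravity gravitational acceleration (m/s^2).
#' @return A `cmj_kinematics` object aligned to the trial's samples.
#' @export
integrate_motion <- function(trial, body_mass = trial$body_mass, onset,
                             gravity = GRAVITY) {
  stopifnot(inherits(trial, "force_trial"))
  if (is.null(body_mass))
    stop_cmj("invalid_parameter", "body mass unknown; supply `body_mass`")
  n <- length(trial$force)
  if (onset < 1L || onset >= n)
    stop_cmj("invalid_parameter", "onset index outside the record")
  t <- (seq_len(n) - 1) / trial$sampling_rate
  fa <- trial$force / body_mass            # specific force, m/s^2
  a <- fa - gravity
  v <- numeric(n)
  v[onset:n] <- drop(pracma::cumtrapz(t[onset:n], a[onset:n]))
  d <- numeric(n)
  d[onset:n] <- drop(pracma::cumtrapz(t[onset:n], v[onset:n]))
  structure(list(time = t, acceleration = a, velocity = v, displacement = d,
                 power = fa * v, gravity = gravity,
                 sampling_rate = trial$sampling_rate, onset_index = onset,
                 body_mass = body_mass),
            class = "cmj_kinematics")
}

#' Segment a jump into eccentric and concentric phases
#'
#' The minimum-velocity instant is the argmin of velocity between onset and
#' take-off; the end of braking is the first upward zero crossing of the
#' velocity after that minimum (interpolated for the reported time, snapped
#' to the later sample for the index). The eccentric phase runs from onset to
#' end of braking, the concentric phase from end of braking to take-off.
#'
#' @param kin a `cmj_kinematics` object.
#' @param onset onset sample index; defaults to the one stored in `kin`.
#' @param takeoff take-off sample index.
#' @return An object of class `phase_segmentation` with fields `onset_index`,
#'   `min_velocity_index`, `end_of_braking_index`, `takeoff_index`,
#'   `eob_time` (interpolated zero-crossing time) and the two phase windows.
#' @export
segment_phases <- function(kin, onset = kin$onset_index, takeoff) {
  stopifnot(inherits(kin, "cmj_kinematics"))
  if (!(onset < takeoff))
    stop_cmj("invalid_parameter", "onset must precede take-off")
  v <- kin$velocity
  win <- onset:takeoff
  i_min <- win[which.min(v[win])]
  if (v[i_min] >= 0)
    stop_cmj("no_countermovement",
             "no countermovement: velocity never negative before take-off")
  lhs <- i_min:(takeoff - 1L)
  cross <- lhs[v[lhs] <= 0 & v[lhs + 1L] > 0]
  if (!length(cross))
    stop_cmj("no_zero_crossing",
             "aborted jump: velocity never crosses zero upward before take-off")
  i0 <- cross[1]
  eob <- i0 + 1L
  ## interpolated crossing time
  eob_time <- kin$time[i0] +
    (0 - v[i0]) / (v[i0 + 1L] - v[i0]) * (kin$time[i0 + 1L] - kin$time[i0])
  if (!(onset < i_min && i_min < eob && eob <= takeoff))
    stop_cmj("invalid_segmentation", "phase ordering violated")
  structure(list(onset_index = onset, min_velocity_index = i_min,
                 end_of_braking_index = eob, takeoff_index = takeoff,
                 eob_time = eob_time,
                 eccentric = c(onset, eob), concentric = c(eob, takeoff)),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<phase_segmentation> onset %d | v-min %d | ",
                     "end of braking %d | take-off %d\n"),
              x$onset_index, x$min_velocity_index,
              x$end_of_braking_index, x$takeoff_index))
  invisible(x)
}
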