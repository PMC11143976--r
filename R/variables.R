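## Per-trial CMJ performance variables, session averaging, percent change.

#' Compute the CMJ performance variables for one trial
#'
#' Variables (all force/impulse/power quantities normalized to body mass):
#' \describe{
#'   \item{jh_cm}{Jump height from peak concentric velocity, `100 v_peak^2 / (2g)` cm.
#'     `jh_takeoff_cm` (from take-off velocity) and `jh_flight_cm` (from the
#'     ballistic flight time `g t^2 / 8`, when a landing is present) are also
#'     reported.}
#'   \item{pf_nkg}{Peak force over the jump (onset to take-off), N/kg.}
#'   \item{pp_wkg}{Peak power over the jump, W/kg.}
#'   \item{ecci_nskg}{Braking net impulse per kg: the net impulse from the
#'     minimum-velocity instant to the end of braking, equal to the magnitude
#'     of the downward velocity minimum by the impulse-momentum theorem.
#'     (The net impulse over the whole eccentric phase is identically zero,
#'     since velocity starts and ends that phase at zero.)}
#'   \item{coni_nskg}{Concentric net impulse per kg (end of braking to
#'     take-off), equal to the take-off velocity.}
#'   \item{eccmp_wkg}{Mean power magnitude over the eccentric phase (COM power
#'     is negative during descent; the magnitude is reported by default).}
#'   \item{conmp_wkg}{Mean power over the concentric phase.}
#'   \item{eccdur_s, condur_s}{Phase durations.}
#'   \item{duration_ratio}{`condur_s / eccdur_s`, the movement-strategy
#'     indicator; it increases when fatigue lengthens the concentric phase
#'     relative to the eccentric phase.}
#' }
#'
#' @param trial a [force_trial()].
#' @param kin a `cmj_kinematics` from [integrate_motion()].
#' @param seg a `phase_segmentation` from [segment_phases()].
#' @param gravity gravitational acceleration (m/s^2).
#' @param jump_height_from `"peak"` (default) or `"takeoff"`: which velocity
#'   defines the headline `jh_cm`.
#' @param eccentric_power `"magnitude"` (default) or `"signed"` mean power
#'   over the eccentric phase.
#' @return A one-row data frame of class `cmj_variables`.
#' @export
compute_variables <- function(trial, kin, seg, gravity = GRAVITY,
                              jump_height_from = c("peak", "takeoff"),
                              eccentric_power = c("magnitude", "signed")) {
  stopifnot(inherits(trial, "force_trial"), inherits(kin, "cmj_kinematics"),
            inherits(seg, "phase_segmentation"))
  jump_height_from <- match.arg(jump_height_from)
  eccentric_power <- match.arg(eccentric_power)
  on <- seg$onset_index; eob <- seg$end_of_braking_index
  to <- seg$takeoff_index; imin <- seg$min_velocity_index
  rate <- kin$sampling_rate
  v <- kin$velocity; P <- kin$power
  fa <- trial$force / kin$body_mass

  v_takeoff <- v[to]
  v_peak <- max(v[eob:to])
  jh_peak <- 100 * v_peak^2 / (2 * gravity)
  jh_to <- 100 * v_takeoff^2 / (2 * gravity)
  jh_flight <- tryCatch({
    land <- detect_landing(trial, to)
    tf <- (land - to) / rate
    100 * gravity * tf^2 / 8
  }, cmjfatigue_error = function(e) NA_real_)

  ecc <- on:eob; con <- eob:to
  eccmp <- if (eccentric_power == "magnitude") mean(abs(P[ecc])) else mean(P[ecc])
  ## impulse boundaries use the interpolated end-of-braking instant, where
  ## velocity is zero by definition, not the snapped sample
  v_eob <- if (!is.null(seg$eob_time))
    stats::approx(kin$time, v, xout = seg$eob_time)$y else v[eob]
  out <- data.frame(
    participant = trial$participant, condition = trial$condition,
    trial = trial$trial,
    jh_cm = if (jump_height_from == "peak") jh_peak else jh_to,
    jh_takeoff_cm = jh_to, jh_peak_cm = jh_peak, jh_flight_cm = jh_flight,
    pf_nkg = max(fa[on:to]),
    pp_wkg = max(P[on:to]),
    ecci_nskg = v_eob - v[imin],
    coni_nskg = v[to] - v_eob,
    eccmp_wkg = eccmp,
    conmp_wkg = mean(P[con]),
    eccdur_s = (eob - on) / rate,
    condur_s = (to - eob) / rate,
    duration_ratio = (to - eob) / (eob - on),
    v_takeoff = v_takeoff, v_peak = v_peak, v_min = v[imin],
    stringsAsFactors = FALSE)
  class(out) <- c("cmj_variables", "data.frame")
  out
}

#' Names of the session-level analysis variables
#'
#' The eleven variables carried through the session-comparison statistics:
#' RPE plus the ten CMJ variables.
#' @return Character vector of column names.
#' @export
cmj_variable_names <- function() {
  c("rpe", "jh_cm", "pf_nkg", "pp_wkg", "ecci_nskg", "coni_nskg",
    "eccmp_wkg", "conmp_wkg", "eccdur_s", "condur_s", "duration_ratio")
}

#' Average the trials of one testing session
#'
#' Arithmetic mean of every numeric variable over the session's trials,
#' representing the participant's performance for that session.
#'
#' @param vars a `cmj_variables` data frame (one row per trial) for a single
#'   participant and condition, or a list of such one-row frames.
#' @param rpe the session's rating of perceived exertion (Borg 6-20), if any.
#' @return A one-row data frame of class `session_summary`.
#' @export
average_trials <- function(vars, rpe = NA_real_) {
  if (is.list(vars) && !is.data.frame(vars)) vars <- do.call(rbind, vars)
  if (!nrow(vars)) stop_cmj("invalid_parameter", "no trials to average")
  if (!is.na(rpe) && (rpe < 6 || rpe > 20))
    stop_cmj("invalid_parameter", "RPE outside the Borg 6-20 range")
  if (nrow(vars) == 1L)
    warning("session summary based on a single trial", call. = FALSE)
  num <- vapply(vars, is.numeric, logical(1))
  num["trial"] <- FALSE
  means <- colMeans(vars[, num, drop = FALSE], na.rm = TRUE)
  out <- data.frame(participant = vars$participant[1],
                    condition = vars$condition[1],
                    n_trials = nrow(vars), rpe = rpe,
                    as.list(means), stringsAsFactors = FALSE)
  class(out) <- c("session_summary", "data.frame")
  out
}

#' Percent change relative to baseline
#'
#' `100 * (other - baseline) / baseline`; a value X% lower than baseline is
#' reported as -X.
#'
#' @param baseline_value,other_value numeric (vectorized).
#' @return Signed percent change.
#' @export
percent_change <- function(baseline_value, other_value) {
  if (any(baseline_value == 0))
    stop_cmj("zero_baseline", "percent change undefined for zero baseline")
  100 * (other_value - baseline_value) / baseline_value
}

#' Analyze one trial end to end
#'
#' Runs the full per-trial chain: body weight from the quiet-standing window,
#' onset, integration, take-off, phase segmentation, variables, and (if
#' requested) time-normalized force and power curves.
#'
#' @param trial a [force_trial()].
#' @param weighing_window,max_cv see [compute_body_weight()].
#' @param onset_k see [detect_onset()].
#' @param takeoff_threshold see [detect_takeoff()].
#' @param Q normalized-curve resolution; `NULL` to skip curve construction.
#' @param gravity gravitational acceleration (m/s^2).
#' @param body_mass_from `"plate"` (derive from the weighing window; default)
#'   or `"trial"` (use the mass stored on the trial).
#' @return List with `variables`, `segmentation`, `kinematics`, `body_weight`
#'   and, when `Q` is given, `force_curve` and `power_curve`.
#' @export
analyze_trial <- function(trial, weighing_window = 1.0, max_cv = 0.03,
                          onset_k = 5, takeoff_threshold = 10, Q = 100,
                          gravity = GRAVITY,
                          body_mass_from = c("plate", "trial")) {
  body_mass_from <- match.arg(body_mass_from)
  bw <- compute_body_weight(trial, weighing_window, max_cv, gravity)
  mass <- if (body_mass_from == "plate" || is.null(trial$body_mass))
    bw$body_mass_kg else trial$body_mass
  onset <- detect_onset(trial, bw$body_weight_N, bw$quiet_sd_N, k = onset_k,
                        search_from = round(weighing_window * trial$sampling_rate))
  kin <- integrate_motion(trial, body_mass = mass, onset = onset,
                          gravity = gravity)
  takeoff <- detect_takeoff(trial, onset = onset, threshold = takeoff_threshold)
  seg <- segment_phases(kin, onset = onset, takeoff = takeoff)
  vars <- compute_variables(trial, kin, seg, gravity = gravity)
  out <- list(variables = vars, segmentation = seg, kinematics = kin,
              body_weight = bw)
  if (!is.null(Q)) {
    out$force_curve <- normalize_curve(kin, seg, "force", Q = Q, trial = trial)
    out$power_curve <- normalize_curve(kin, seg, "power", Q = Q, trial = trial)
  }
  out
}
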