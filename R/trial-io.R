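## Force-plate trial I/O and body-weight determination.

#' Construct a force-plate trial
#'
#' The canonical in-memory representation of one CMJ trial: a uniformly
#' sampled vertical ground-reaction-force series in newtons. Internal units
#' are newtons and seconds; sample `i` (1-based) occurs at time
#' `(i - 1) / sampling_rate`.
#'
#' @param force numeric vector of vertical GRF in N.
#' @param sampling_rate sampling rate in Hz.
#' @param body_mass body mass in kg, if known (may be derived later from the
#'   quiet-standing segment with [compute_body_weight()]).
#' @param participant,condition,trial identifier labels.
#' @param clamp_negative clamp small negative samples (sensor noise) to 0.
#' @param neg_tolerance largest tolerated negative excursion (N) before the
#'   record is rejected as invalid.
#' @param min_duration minimum record length in seconds (quiet standing plus
#'   movement); relax for synthetic fragments.
#' @return An object of class `force_trial`.
#' @export
force_trial <- function(force, sampling_rate, body_mass = NULL,
                        participant = NA_character_, condition = NA_character_,
                        trial = NA_integer_, clamp_negative = TRUE,
                        neg_tolerance = 50, min_duration = 2) {
  if (!is.numeric(force) || !length(force))
    stop_cmj("invalid_trial", "`force` must be a non-empty numeric vector")
  if (anyNA(force) || any(!is.finite(force)))
    stop_cmj("invalid_trial", "`force` contains non-finite values")
  assert_scalar_pos(sampling_rate, "sampling_rate")
  if (min(force) < -neg_tolerance)
    stop_cmj("invalid_trial", "force contains large negative values (min %.1f N)",
             min(force))
  if (clamp_negative) force[force < 0] <- 0
  if (length(force) < min_duration * sampling_rate)
    stop_cmj("invalid_trial",
             "record too short: %.2f s < required %.2f s",
             length(force) / sampling_rate, min_duration)
  structure(list(force = force, sampling_rate = sampling_rate,
                 body_mass = body_mass, participant = participant,
                 condition = condition, trial = trial),
            class = "force_trial")
}

#' @export
print.force_trial <- function(x, ...) {
  cat(sprintf("<force_trial> %d samples @ %g Hz (%.2f s)",
              length(x$force), x$sampling_rate,
              length(x$force) / x$sampling_rate))
  if (!is.na(x$participant))
    cat(sprintf("  [%s / %s / trial %s]", x$participant, x$condition, x$trial))
  cat(sprintf("\n  force range: %.1f - %.1f N\n",
              min(x$force), max(x$force)))
  invisible(x)
}

#' Trial-file dialect
#'
#' Describes the on-disk format of a force trial: delimiter, header presence,
#' force units, and whether a time column precedes the force column (if not,
#' the sampling rate must be supplied).
#'
#' @param delim field delimiter.
#' @param header whether the file has a header row.
#' @param units force units in the file, `"N"` or `"kN"`.
#' @param time_column whether column 1 is time in seconds.
#' @param rate sampling rate in Hz, required when `time_column = FALSE`.
#' @return An object of class `trial_dialect`.
#' @export
trial_dialect <- function(delim = ",", header = TRUE, units = c("N", "kN"),
                          time_column = TRUE, rate = NULL) {
  units <- match.arg(units)
  if (!time_column && is.null(rate))
    stop_cmj("invalid_parameter", "`rate` is required when the file has no time column")
  structure(list(delim = delim, header = header, units = units,
                 time_column = time_column, rate = rate),
            class = "trial_dialect")
}

#' Read a force-plate trial from delimited text
#'
#' @param path file path.
#' @param dialect a [trial_dialect()].
#' @param ... passed to [force_trial()] (e.g. identifiers, `body_mass`).
#' @param uniformity_tol maximum relative deviation of time steps from their
#'   median before the record is rejected as non-uniformly sampled.
#' @return A [force_trial()].
#' @export
read_force_trial <- function(path, dialect = trial_dialect(), ...,
                             uniformity_tol = 1e-3) {
  if (!file.exists(path)) stop_cmj("io_error", "file not found: %s", path)
  if (file.size(path) == 0) stop_cmj("empty_file", "empty trial file: %s", path)
  dat <- tryCatch(
    utils::read.table(path, sep = dialect$delim, header = dialect$header,
                      colClasses = "numeric"),
    error = function(e) stop_cmj("non_numeric", "non-numeric rows in %s: %s",
                                 path, conditionMessage(e)))
  if (!nrow(dat)) stop_cmj("empty_file", "no data rows in %s", path)
  if (dialect$time_column) {
    if (ncol(dat) < 2)
      stop_cmj("non_numeric", "expected time and force columns in %s", path)
    tm <- dat[[1]]
    dt <- diff(tm)
    med <- stats::median(dt)
    if (med <= 0 || max(abs(dt - med)) > uniformity_tol * med)
      stop_cmj("non_uniform_sampling",
               "non-uniform sampling in %s (max deviation %.3g%% of step)",
               path, 100 * max(abs(dt - med)) / med)
    rate <- 1 / med
    f <- dat[[2]]
  } else {
    rate <- dialect$rate
    f <- dat[[1]]
  }
  if (dialect$units == "kN") f <- f * 1000
  force_trial(f, sampling_rate = rate, ...)
}

#' Write a force-plate trial as delimited text
#'
#' @param trial a [force_trial()].
#' @param path output path.
#' @param dialect a [trial_dialect()]; forces are written in its units.
#' @return Invisibly, `path`.
#' @export
write_force_trial <- function(trial, path, dialect = trial_dialect()) {
  stopifnot(inherits(trial, "force_trial"))
  f <- if (dialect$units == "kN") trial$force / 1000 else trial$force
  tm <- (seq_along(f) - 1) / trial$sampling_rate
  dat <- data.frame(time_s = tm, fz_N = f)
  if (dialect$units == "kN") names(dat)[2] <- "fz_kN"
  if (!dialect$time_column) dat <- dat[, 2, drop = FALSE]
  utils::write.table(format(dat, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = dialect$delim, row.names = FALSE,
                     col.names = dialect$header, quote = FALSE)
  invisible(path)
}

#' Read or write a study manifest
#'
#' A manifest lists every trial of a study: participant, condition, trial
#' index, body mass, per-session RPE and (optionally) the trial file path.
#'
#' @param path CSV path.
#' @param conditions allowed condition labels, in session order.
#' @return `read_manifest()`: a data frame with `condition` as an ordered
#'   factor.
#' @export
read_manifest <- function(path, conditions = cmj_conditions()) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant", "condition", "trial")
  missing <- setdiff(required, names(man))
  if (length(missing))
    stop_cmj("invalid_manifest", "manifest lacks column(s): %s",
             paste(missing, collapse = ", "))
  bad <- setdiff(unique(man$condition), conditions)
  if (length(bad))
    stop_cmj("invalid_manifest", "unknown condition label(s): %s",
             paste(bad, collapse = ", "))
  if (!is.null(man$rpe) && any(!is.na(man$rpe) & (man$rpe < 6 | man$rpe > 20)))
    stop_cmj("invalid_manifest", "RPE outside the Borg 6-20 range")
  man$condition <- factor(man$condition, levels = conditions)
  man
}

#' @rdname read_manifest
#' @param manifest data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Determine body weight from the quiet-standing segment
#'
#' Averages force over an initial weighing window during which the subject
#' must stand still. The window SD doubles as the quiet-noise estimate used
#' for onset thresholding.
#'
#' @param trial a [force_trial()].
#' @param weighing_window window length in seconds from the start of the
#'   record (default 1.0 s).
#' @param max_cv largest tolerated window SD as a fraction of the mean before
#'   the subject is declared not still.
#' @param gravity gravitational acceleration (m/s^2).
#' @return List with `body_weight_N`, `body_mass_kg` and `quiet_sd_N`.
#' @export
compute_body_weight <- function(trial, weighing_window = 1.0, max_cv = 0.03,
                                gravity = GRAVITY) {
  stopifnot(inherits(trial, "force_trial"))
  n <- round(weighing_window * trial$sampling_rate)
  if (n < 2 || n > length(trial$force))
    stop_cmj("invalid_parameter", "weighing window outside the record")
  w <- trial$force[seq_len(n)]
  bw <- mean(w)
  s <- stats::sd(w)
  if (bw <= 0) stop_cmj("not_still", "non-positive mean force in weighing window")
  if (s > max_cv * bw)
    stop_cmj("not_still",
             "subject not still: window SD %.1f N exceeds %.0f%% of body weight",
             s, 100 * max_cv)
  list(body_weight_N = bw, body_mass_kg = bw / gravity, quiet_sd_N = s)
}
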