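## Time-normalized force- and power-time curves.
##
## Each phase is mapped to half of normalized time: eccentric (onset to end
## of braking) to 0-50%, concentric (end of braking to take-off) to 50-100%,
## so the 50% node is the eccentric/concentric boundary on every curve.

#' Build a time-normalized curve for one trial
#'
#' Linearly interpolates the chosen quantity at `Q/2 + 1` equally spaced time
#' fractions within each phase and concatenates the phases at the shared 50%
#' node, giving `Q + 1` nodes on 0-100% of normalized movement time.
#'
#' @param kin a `cmj_kinematics` object.
#' @param seg a `phase_segmentation`.
#' @param quantity `"force"` (N/kg) or `"power"` (W/kg).
#' @param Q number of normalized-time intervals; even, at least 10
#'   (default 100, i.e. 101 nodes).
#' @param trial optional [force_trial()] supplying identifier labels.
#' @return A numeric vector of class `normalized_curve` with attributes
#'   `percent` (node positions), `quantity`, `participant`, `condition`,
#'   `trial`.
#' @export
normalize_curve <- function(kin, seg, quantity = c("force", "power"),
                            Q = 100, trial = NULL) {
  stopifnot(inherits(kin, "cmj_kinematics"), inherits(seg, "phase_segmentation"))
  quantity <- match.arg(quantity)
  if (Q < 10 || Q %% 2 != 0)
    stop_cmj("invalid_parameter", "`Q` must be an even integer >= 10")
  y <- switch(quantity,
              force = kin$acceleration + kin$gravity,  # specific force, N/kg
              power = kin$power)
  t <- kin$time
  t_on <- t[seg$onset_index]
  t_eob <- t[seg$end_of_braking_index]
  t_to <- t[seg$takeoff_index]
  half <- Q / 2
  x_ecc <- seq(t_on, t_eob, length.out = half + 1)
  x_con <- seq(t_eob, t_to, length.out = half + 1)
  vals <- stats::approx(t, y, xout = c(x_ecc, x_con[-1]), rule = 2)$y
  structure(vals,
            percent = seq(0, 100, length.out = Q + 1),
            quantity = quantity,
            participant = if (is.null(trial)) NA_character_ else trial$participant,
            condition = if (is.null(trial)) NA_character_ else trial$condition,
            trial = if (is.null(trial)) NA_integer_ else trial$trial,
            class = "normalized_curve")
}

## Stack a list of normalized_curve objects into a matrix + metadata.
curve_matrix <- function(curves) {
  stopifnot(length(curves) > 0)
  m <- do.call(rbind, lapply(curves, as.numeric))
  meta <- data.frame(
    participant = vapply(curves, function(x) attr(x, "participant"), ""),
    condition = vapply(curves, function(x) attr(x, "condition"), ""),
    trial = vapply(curves, function(x) as.integer(attr(x, "trial")), 1L),
    stringsAsFactors = FALSE)
  list(values = m, meta = meta, percent = attr(curves[[1]], "percent"),
       quantity = attr(curves[[1]], "quantity"))
}

#' Per-participant trial-mean curves for one condition
#'
#' Averages each participant's trial curves node-wise, returning one row per
#' participant. This is the unit of analysis for the curve statistics
#' (sessions are represented by their trial mean).
#'
#' @param curves list of [normalize_curve()] outputs.
#' @param condition condition label to extract.
#' @return Matrix, rows = participants (rownames set), columns = nodes.
#' @export
participant_curves <- function(curves, condition) {
  cm <- curve_matrix(curves)
  keep <- cm$meta$condition == condition
  if (!any(keep)) stop_cmj("invalid_parameter", "no curves for condition '%s'", condition)
  v <- cm$values[keep, , drop = FALSE]
  ids <- cm$meta$participant[keep]
  out <- t(vapply(split(seq_len(nrow(v)), ids),
                  function(i) colMeans(v[i, , drop = FALSE]),
                  numeric(ncol(v))))
  out[order(rownames(out)), , drop = FALSE]
}

#' Condition mean and SD curves
#'
#' Computes, for each condition, the across-participant mean and SD at every
#' node, after first averaging each participant's trials.
#'
#' @param curves list of [normalize_curve()] outputs (any mix of conditions).
#' @return A long data frame: `condition`, `percent`, `mean`, `sd`, `n`, plus
#'   a `quantity` attribute.
#' @export
average_curves <- function(curves) {
  cm <- curve_matrix(curves)
  conds <- unique(cm$meta$condition)
  out <- do.call(rbind, lapply(conds, function(cn) {
    pm <- participant_curves(curves, cn)
    data.frame(condition = cn, percent = cm$percent,
               mean = colMeans(pm),
               sd = apply(pm, 2, stats::sd),
               n = nrow(pm), stringsAsFactors = FALSE)
  }))
  attr(out, "quantity") <- cm$quantity
  out
}
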