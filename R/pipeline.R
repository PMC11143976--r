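## End-to-end study orchestration: trials -> per-trial variables -> session
## summaries -> repeated-measures statistics and percent changes -> normalized
## curves -> SPM comparisons of every fatigue condition against baseline.

#' Study configuration
#'
#' Collects every tunable of the pipeline in one validated object. In
#' `"synthetic"` mode the study is simulated from `cohort`/`baseline_params`/
#' `effects`; in `"manifest"` mode trials are read from disk via `manifest`
#' (which must contain a `file` column) and `data_dir`.
#'
#' @param mode `"synthetic"` or `"manifest"`.
#' @param cohort a [cohort_spec()] (synthetic mode).
#' @param baseline_params a [jump_profile_params()] (synthetic mode).
#' @param effects named list of [fatigue_effect()] per condition; default
#'   [default_fatigue_effects()].
#' @param manifest manifest data frame or CSV path (manifest mode).
#' @param data_dir directory containing the trial files (manifest mode).
#' @param dialect a [trial_dialect()] for reading trial files.
#' @param Q normalized-curve resolution (number of intervals; 101 nodes for
#'   the default 100).
#' @param alpha significance level for ANOVA, post hoc tests and SPM.
#' @param onset_k onset threshold in quiet SDs.
#' @param takeoff_threshold take-off force threshold (N).
#' @param weighing_window quiet-standing weighing window (s).
#' @param gravity gravitational acceleration (m/s^2).
#' @param seed integer seed for synthetic mode (overrides `cohort$seed` when
#'   not `NULL`).
#' @param output_dir if given, report tables and a run log are written there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "manifest"),
                         cohort = cohort_spec(),
                         baseline_params = jump_profile_params(),
                         effects = NULL,
                         manifest = NULL, data_dir = NULL,
                         dialect = trial_dialect(),
                         Q = 100, alpha = 0.05, onset_k = 5,
                         takeoff_threshold = 10, weighing_window = 1.0,
                         gravity = GRAVITY, seed = NULL, output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "manifest" && is.null(manifest))
    stop_cmj("invalid_parameter", "manifest mode requires `manifest`")
  if (!is.null(seed)) cohort$seed <- seed
  structure(list(mode = mode, cohort = cohort,
                 baseline_params = baseline_params,
                 effects = effects, manifest = manifest, data_dir = data_dir,
                 dialect = dialect, Q = Q, alpha = alpha, onset_k = onset_k,
                 takeoff_threshold = takeoff_threshold,
                 weighing_window = weighing_window, gravity = gravity,
                 seed = cohort$seed, output_dir = output_dir),
            class = "study_config")
}

#' Run a whole study
#'
#' Executes the full chain on a simulated cohort or a manifest of recorded
#' trials: per-trial analysis, session summaries (trial averages plus RPE),
#' repeated-measures ANOVA with Bonferroni post hoc tests for each analysis
#' variable, percent changes of the condition means against baseline,
#' condition mean and SD normalized curves, and an SPM paired comparison of
#' every non-baseline condition against baseline for both the force- and the
#' power-time curve.
#'
#' @param config a [study_config()].
#' @return An object of class `study_report`: `manifest`, `trial_variables`,
#'   `summaries`, `anova` (named list per variable), `posthoc`,
#'   `percent_change`, `curves` (long mean and SD per condition, per
#'   quantity), `participant_curves`, `spm` (named list `quantity.condition`),
#'   `truth` (synthetic mode), `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  conds <- if (config$mode == "synthetic") config$cohort$conditions
           else cmj_conditions()

  ## ---- stage: input ----
  if (config$mode == "synthetic") {
    effects <- config$effects %||% default_fatigue_effects(config$cohort$conditions)
    cohort <- simulate_cohort(config$cohort, config$baseline_params, effects)
    trials <- cohort$trials
    manifest <- cohort$manifest
    truth <- cohort$truth
  } else {
    manifest <- if (is.character(config$manifest))
      read_manifest(config$manifest) else config$manifest
    if (is.null(manifest$file))
      stop_cmj("invalid_manifest", "manifest mode requires a `file` column")
    trials <- lapply(seq_len(nrow(manifest)), function(r) {
      path <- if (is.null(config$data_dir)) manifest$file[r]
              else file.path(config$data_dir, manifest$file[r])
      read_force_trial(path, config$dialect,
                       body_mass = manifest$body_mass[r],
                       participant = manifest$participant[r],
                       condition = as.character(manifest$condition[r]),
                       trial = manifest$trial[r])
    })
    truth <- NULL
    conds <- intersect(conds, unique(as.character(manifest$condition)))
  }

  ## ---- stage: per-trial analysis ----
  analyses <- lapply(trials, function(tr)
    analyze_trial(tr, weighing_window = config$weighing_window,
                  onset_k = config$onset_k,
                  takeoff_threshold = config$takeoff_threshold,
                  Q = config$Q, gravity = config$gravity))
  trial_vars <- do.call(rbind, lapply(analyses, `[[`, "variables"))
  force_curves <- lapply(analyses, `[[`, "force_curve")
  power_curves <- lapply(analyses, `[[`, "power_curve")

  ## ---- stage: session summaries ----
  key <- interaction(trial_vars$participant, trial_vars$condition, drop = TRUE)
  summaries <- do.call(rbind, lapply(split(seq_len(nrow(trial_vars)), key),
    function(i) {
      rpe <- manifest$rpe[match(paste(trial_vars$participant[i[1]],
                                      trial_vars$condition[i[1]]),
                                paste(manifest$participant, manifest$condition))]
      suppressWarnings(average_trials(trial_vars[i, ], rpe = rpe %||% NA_real_))
    }))
  rownames(summaries) <- NULL

  ## ---- stage: repeated-measures statistics ----
  vars <- intersect(cmj_variable_names(), names(summaries))
  anova <- list(); posthoc <- list()
  for (v in vars) {
    m <- condition_matrix(summaries, v, conditions = conds)
    anova[[v]] <- rm_anova(m, sphericity_alpha = config$alpha)
    posthoc[[v]] <- bonferroni_posthoc(m, alpha = config$alpha)
  }

  ## ---- stage: percent changes vs baseline ----
  base_cond <- conds[1]
  pc <- do.call(rbind, lapply(vars, function(v) {
    m <- condition_matrix(summaries, v, conditions = conds)
    mu <- colMeans(m)
    data.frame(variable = v, condition = conds[-1],
               baseline_mean = mu[[base_cond]], condition_mean = mu[conds[-1]],
               percent_change = percent_change(mu[[base_cond]], mu[conds[-1]]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  ## ---- stage: curves and SPM ----
  curves <- list(force = average_curves(force_curves),
                 power = average_curves(power_curves))
  pcurves <- list(
    force = lapply(conds, function(cn) participant_curves(force_curves, cn)),
    power = lapply(conds, function(cn) participant_curves(power_curves, cn)))
  names(pcurves$force) <- names(pcurves$power) <- conds
  spm <- list()
  for (qty in c("force", "power")) {
    for (cn in conds[-1]) {
      spm[[paste(qty, cn, sep = ".")]] <-
        spm_paired_test(pcurves[[qty]][[cn]], pcurves[[qty]][[base_cond]],
                        alpha = config$alpha)
    }
  }

  report <- structure(list(
    manifest = manifest, trial_variables = trial_vars, summaries = summaries,
    anova = anova, posthoc = posthoc, percent_change = pc, curves = curves,
    participant_curves = pcurves, spm = spm, truth = truth,
    conditions = conds, config = config
  ), class = "study_report")

  if (!is.null(config$output_dir)) {
    make_report_tables(report, config$output_dir)
    write_run_log(report, config$output_dir)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d participants x %d conditions, %d trials\n",
              length(unique(x$manifest$participant)), length(x$conditions),
              nrow(x$manifest)))
  cat("Main effects (repeated-measures ANOVA):\n")
  for (v in names(x$anova)) {
    a <- x$anova[[v]]
    cat(sprintf("  %-15s F(%.2f, %.2f) = %6.2f  p = %-8.3g eta2 = %.2f (%s)\n",
                v, a$df_effect, a$df_error, a$F, a$p, a$partial_eta_sq,
                a$effect_label))
  }
  nsig <- sum(vapply(x$spm, function(s) nrow(s$clusters) > 0, logical(1)))
  cat(sprintf("SPM: %d of %d comparisons with supra-threshold clusters\n",
              nsig, length(x$spm)))
  invisible(x)
}

## Letter codes for the pairwise footnote scheme: pairs in column order
## (baseline-3min = a, baseline-10min = b, ..., 1hr-24hr = j), marked on the
## earlier condition's column.
posthoc_letters <- function(ph, conds) {
  pairs <- utils::combn(length(conds), 2)
  letters_by_pair <- letters[seq_len(ncol(pairs))]
  marks <- stats::setNames(rep("", length(conds)), conds)
  for (j in seq_len(ncol(pairs))) {
    c1 <- conds[pairs[1, j]]; c2 <- conds[pairs[2, j]]
    hit <- ph$significant[(ph$cond1 == c1 & ph$cond2 == c2) |
                            (ph$cond1 == c2 & ph$cond2 == c1)]
    if (length(hit) && any(hit))
      marks[c1] <- paste0(marks[c1], letters_by_pair[j])
  }
  marks
}

#' Write the report tables
#'
#' Writes a session-comparison table (one row per variable: per-condition
#' mean and SD, F, partial eta-squared, effect label and pairwise
#' significance letters), the percent-change table, the SPM cluster table
#' and the session summaries, as CSV files.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
make_report_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conds <- report$conditions
  rows <- lapply(names(report$anova), function(v) {
    m <- condition_matrix(report$summaries, v, conditions = conds)
    a <- report$anova[[v]]
    marks <- posthoc_letters(report$posthoc[[v]], conds)
    cells <- sprintf("%.2f ± %.2f%s", colMeans(m), apply(m, 2, stats::sd),
                     ifelse(marks == "", "", paste0(" ", marks)))
    names(cells) <- conds
    data.frame(variable = v, t(cells),
               F = sprintf("%.2f", a$F),
               df = sprintf("(%.2f, %.2f)", a$df_effect, a$df_error),
               p = sprintf("%.4g", a$p),
               partial_eta_sq = sprintf("%.2f", a$partial_eta_sq),
               effect = a$effect_label,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  paths <- character()
  p1 <- file.path(dir, "variables_table.csv")
  utils::write.csv(tab, p1, row.names = FALSE)
  pc <- report$percent_change
  pc$percent_change <- round(pc$percent_change, 1)
  p2 <- file.path(dir, "percent_change.csv")
  utils::write.csv(pc, p2, row.names = FALSE)
  cl <- do.call(rbind, lapply(names(report$spm), function(nm) {
    s <- report$spm[[nm]]
    if (!nrow(s$clusters)) return(NULL)
    qc <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(quantity = qc[1], condition = qc[2],
               start_pct = round(s$clusters$start_pct, 1),
               end_pct = round(s$clusters$end_pct, 1),
               peak_t = round(s$clusters$peak_t, 2),
               t_star = round(s$t_star, 3),
               p = signif(s$clusters$p, 4), stringsAsFactors = FALSE)
  }))
  p3 <- file.path(dir, "spm_clusters.csv")
  utils::write.csv(cl %||% data.frame(), p3, row.names = FALSE)
  p4 <- file.path(dir, "session_summaries.csv")
  utils::write.csv(report$summaries, p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}

write_run_log <- function(report, dir) {
  cfg <- report$config
  log <- list(
    package_version = as.character(utils::packageVersion("cmjfatigue")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    mode = cfg$mode, seed = cfg$seed, Q = cfg$Q, alpha = cfg$alpha,
    onset_k = cfg$onset_k, takeoff_threshold = cfg$takeoff_threshold,
    weighing_window = cfg$weighing_window, gravity = cfg$gravity,
    conditions = report$conditions,
    n_participants = length(unique(report$manifest$participant)),
    n_trials = nrow(report$manifest))
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "run_log.json"))
}
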