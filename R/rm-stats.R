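## One-way repeated-measures ANOVA across sessions, with Mauchly's sphericity
## test, the Greenhouse-Geisser correction, Bonferroni post hoc paired tests,
## and partial eta-squared effect sizes.

#' Build a participant x condition matrix for one variable
#'
#' @param summaries data frame with columns `participant`, `condition` and the
#'   variable of interest (e.g. from session summaries).
#' @param variable column name to extract.
#' @param conditions column order of the result.
#' @return Numeric matrix, rows = participants, columns = conditions.
#' @export
condition_matrix <- function(summaries, variable,
                             conditions = cmj_conditions()) {
  conditions <- intersect(conditions, unique(as.character(summaries$condition)))
  ids <- sort(unique(summaries$participant))
  m <- matrix(NA_real_, length(ids), length(conditions),
              dimnames = list(ids, conditions))
  for (r in seq_len(nrow(summaries)))
    m[summaries$participant[r], as.character(summaries$condition[r])] <-
      summaries[[variable]][r]
  if (anyNA(m))
    stop_cmj("incomplete_design", "missing participant x condition cell(s) for '%s'",
             variable)
  m
}

## Orthonormal within-subject contrast matrix (k x k-1).
ortho_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C %*% diag(1 / sqrt(colSums(C^2)), ncol(C), ncol(C))
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-departure index estimated from the sample covariance of the
#' condition columns; 1 under perfect sphericity, bounded below by
#' `1/(k - 1)`.
#'
#' @param m participant x condition matrix.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(m) {
  k <- ncol(m)
  if (k < 3) return(1)
  S <- stats::cov(m)
  C <- ortho_contrasts(k)
  Sc <- t(C) %*% S %*% C
  tr <- sum(diag(Sc))
  eps <- tr^2 / ((k - 1) * sum(Sc^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' Mauchly's test of sphericity
#'
#' Tests whether the covariance matrix of the orthonormalized within-subject
#' contrasts is proportional to the identity, using the chi-squared
#' approximation with the second-order Box series term.
#'
#' @param m participant x condition matrix.
#' @return List with `W`, `chisq`, `df` and `p` (all `NA`/degenerate when
#'   `k = 2`, for which sphericity holds trivially).
#' @export
mauchly_test <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (k < 3) return(list(W = 1, chisq = NA_real_, df = 0L, p = NA_real_))
  S <- stats::cov(m)
  C <- ortho_contrasts(k)
  Sc <- t(C) %*% S %*% C
  pp <- k - 1
  W <- det(Sc) / (sum(diag(Sc)) / pp)^pp
  df <- pp * (pp + 1) / 2 - 1
  if (!is.finite(W) || W <= 0)
    return(list(W = W, chisq = Inf, df = as.integer(df), p = 0))
  nd <- n - 1                                    # error degrees of freedom
  rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * nd)
  w2 <- (pp + 2) * (pp - 1) * (pp - 2) * (2 * pp^3 + 6 * pp^2 + 3 * k + 2) /
    (288 * (nd * pp * rho)^2)
  chisq <- -nd * rho * log(W)
  pr1 <- stats::pchisq(chisq, df, lower.tail = FALSE)
  pr2 <- stats::pchisq(chisq, df + 4, lower.tail = FALSE)
  list(W = W, chisq = chisq, df = as.integer(df),
       p = pr1 + w2 * (pr2 - pr1))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition of a complete participant x condition matrix:
#' F = MS_condition / MS_error with df `(k-1, (k-1)(n-1))`. When Mauchly's
#' test rejects sphericity at `sphericity_alpha`, both degrees of freedom are
#' multiplied by the Greenhouse-Geisser epsilon. Partial eta-squared is
#' `SS_condition / (SS_condition + SS_error)`.
#'
#' @param m participant x condition matrix (no missing cells).
#' @param sphericity_alpha alpha for Mauchly's test gate (default 0.05).
#' @param correction `"auto"` (apply GG when Mauchly rejects), `"none"`, or
#'   `"gg"` (always apply).
#' @return An object of class `rm_anova_result`.
#' @export
rm_anova <- function(m, sphericity_alpha = 0.05,
                     correction = c("auto", "none", "gg")) {
  correction <- match.arg(correction)
  m <- as.matrix(m)
  if (anyNA(m)) stop_cmj("incomplete_design", "matrix contains missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop_cmj("invalid_parameter", "need at least 2 participants and 2 conditions")
  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0)
    stop_cmj("degenerate_matrix", "zero-variance matrix")
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  if (ms_err <= 0)
    stop_cmj("degenerate_matrix", "zero error variance")
  F <- ms_cond / ms_err
  mau <- mauchly_test(m)
  eps <- gg_epsilon(m)
  corrected <- switch(correction,
                      none = FALSE,
                      gg = k > 2,
                      auto = k > 2 && !is.na(mau$p) && mau$p < sphericity_alpha)
  df1_eff <- if (corrected) eps * df1 else df1
  df2_eff <- if (corrected) eps * df2 else df2
  eta <- ss_cond / (ss_cond + ss_err)
  structure(list(
    F = F, df_effect = df1_eff, df_error = df2_eff,
    p = stats::pf(F, df1_eff, df2_eff, lower.tail = FALSE),
    mauchly_w = mau$W, mauchly_p = mau$p, gg_epsilon = eps,
    gg_applied = corrected,
    partial_eta_sq = eta, effect_label = classify_effect_size(eta),
    ss = c(condition = ss_cond, subjects = ss_subj, error = ss_err),
    n = n, k = k
  ), class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%.2f, %.2f) = %.2f, p = %.4g\n",
              x$df_effect, x$df_error, x$F, x$p))
  cat(sprintf("  Mauchly W = %.3f (p = %.3g); GG epsilon = %.3f%s\n",
              x$mauchly_w, x$mauchly_p, x$gg_epsilon,
              if (x$gg_applied) " [applied]" else ""))
  cat(sprintf("  partial eta^2 = %.3f (%s effect)\n",
              x$partial_eta_sq, x$effect_label))
  invisible(x)
}

#' Bonferroni-corrected post hoc paired comparisons
#'
#' Paired t-tests for all `k(k-1)/2` condition pairs; each p-value is
#' multiplied by the number of pairs (capped at 1).
#'
#' @param m participant x condition matrix.
#' @param alpha flagging threshold for the adjusted p-values.
#' @return Data frame: `cond1`, `cond2`, `mean_diff` (cond2 - cond1), `t`,
#'   `df`, `p_raw`, `p_adj`, `significant`.
#' @export
bonferroni_posthoc <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  k <- ncol(m)
  cn <- colnames(m) %||% paste0("C", seq_len(k))
  pairs <- utils::combn(k, 2)
  npairs <- ncol(pairs)
  rows <- lapply(seq_len(npairs), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- m[, i2] - m[, i1]
    if (stats::sd(d) == 0) {
      data.frame(cond1 = cn[i1], cond2 = cn[i2], mean_diff = mean(d),
                 t = if (mean(d) == 0) 0 else Inf, df = length(d) - 1,
                 p_raw = if (mean(d) == 0) 1 else 0, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(m[, i2], m[, i1], paired = TRUE)
      data.frame(cond1 = cn[i1], cond2 = cn[i2],
                 mean_diff = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * npairs)
  out$significant <- out$p_adj < alpha
  out
}

#' Classify a partial eta-squared effect size
#'
#' Thresholds: below 0.04 negligible; 0.04 to 0.25 small; 0.25 to 0.64
#' moderate; 0.64 and above large (lower bounds inclusive).
#'
#' @param eta_sq partial eta-squared value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @export
classify_effect_size <- function(eta_sq) {
  if (any(eta_sq < 0 | eta_sq > 1, na.rm = TRUE))
    stop_cmj("invalid_parameter", "partial eta-squared must lie in [0, 1]")
  as.character(cut(eta_sq, breaks = c(-Inf, 0.04, 0.25, 0.64, Inf),
                   labels = c("negligible", "small", "moderate", "large"),
                   right = FALSE))
}
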