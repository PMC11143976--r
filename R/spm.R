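## One-dimensional statistical parametric mapping (SPM) for paired
## comparisons of time-normalized curves.
##
## A paired t-statistic is computed at every node, the smoothness (FWHM) of
## the residual difference fields is estimated from their gradients, and the
## critical threshold controlling the family-wise error over the whole curve
## is obtained from random field theory (RFT): the expected Euler
## characteristic of the excursion set of a smooth t-field. Supra-threshold
## clusters receive extent-based p-values from the standard cluster-size
## approximation for smooth fields.

#' Node-wise paired t-statistic curve
#'
#' @param A,B participant x node matrices for the two conditions, with the
#'   same participants in the same row order (rownames are checked when
#'   present).
#' @return List with `t` (t-statistic per node, `NA` at zero-variance nodes),
#'   `df` (n - 1), `residuals` (centred difference fields, one row per
#'   participant) and `masked` (logical, zero-variance nodes).
#' @export
paired_t_curve <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)))
    stop_cmj("invalid_parameter", "condition matrices must have identical dimensions")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop_cmj("invalid_parameter", "participants differ between conditions")
  n <- nrow(A)
  if (n < 2) stop_cmj("invalid_parameter", "need at least 2 participants")
  d <- A - B
  mu <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  zero_var <- s <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  ## zero variance with zero mean (e.g. identical conditions) is a genuine
  ## null, t = 0; zero variance with nonzero mean leaves t undefined
  masked <- zero_var & abs(mu) > .Machine$double.eps^0.5
  t <- ifelse(masked, NA_real_, ifelse(zero_var, 0, mu / (s / sqrt(n))))
  res <- sweep(d, 2, mu)
  list(t = t, df = as.integer(n - 1), residuals = res, masked = masked)
}

#' Estimate residual-field smoothness (FWHM)
#'
#' Gradient-based estimator: at each node the squared gradients of the
#' residual fields are summed and normalized by the fields' sum of squares;
#' the per-node resel density is `sqrt(v / (4 log 2))` and the FWHM is the
#' reciprocal of its mean over valid nodes. Gradients use central differences
#' in the interior and one-sided differences at the ends.
#'
#' @param residuals fields x nodes matrix (e.g. from [paired_t_curve()]).
#' @param masked optional logical vector of nodes to exclude.
#' @return FWHM in node units.
#' @export
estimate_fwhm <- function(residuals, masked = NULL) {
  R <- as.matrix(residuals)
  grad <- t(apply(R, 1, node_gradient))
  ssq <- colSums(R^2)
  v <- colSums(grad^2) / ssq
  drop <- !is.finite(v)
  if (!is.null(masked)) drop <- drop | masked
  v <- v[!drop]
  if (!length(v)) stop_cmj("degenerate_field", "no valid nodes for smoothness estimation")
  rpn <- sqrt(v / (4 * log(2)))          # resels per node
  1 / mean(rpn)
}

node_gradient <- function(x) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  g
}

## Expected Euler characteristic of the excursion set of a smooth 1D t-field
## above u: EC-density sum of the point-probability term and the resel term.
expected_ec_t <- function(u, df, resels) {
  stats::pt(u, df, lower.tail = FALSE) +
    resels * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

#' Random-field-theory critical threshold for a 1D t-field
#'
#' Solves for the threshold `t*` at which the family-wise probability of the
#' field maximum exceeding `t*` equals `alpha`, using the expected-Euler-
#' characteristic approximation (point-probability term plus resel term).
#' Two-tailed inference splits alpha between the tails. As the resel count
#' approaches zero the threshold reduces to the uncorrected t quantile.
#'
#' @param df degrees of freedom.
#' @param resels resel count (field length in nodes divided by the FWHM).
#' @param alpha family-wise error rate, in (0, 1).
#' @param two_tailed logical (default `TRUE`).
#' @return Critical threshold `t*`.
#' @export
rft_threshold <- function(df, resels, alpha = 0.05, two_tailed = TRUE) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_cmj("invalid_parameter", "`alpha` must lie in (0, 1)")
  if (df < 1) stop_cmj("invalid_parameter", "`df` must be >= 1")
  if (resels < 0) stop_cmj("invalid_parameter", "`resels` must be >= 0")
  target <- if (two_tailed) alpha / 2 else alpha
  f <- function(u) expected_ec_t(u, df, resels) - target
  upper <- 10
  while (f(upper) > 0 && upper < 1e6) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

## Cluster-extent p-value for a smooth 1D t-field: standard cluster-size
## approximation (exponential-form extent distribution calibrated to the
## expected number and total size of excursion clusters).
cluster_p_value <- function(extent_resels, u, df, resels, two_tailed = TRUE) {
  Em <- expected_ec_t(u, df, resels)          # expected number of clusters
  EN <- resels * stats::pt(u, df, lower.tail = FALSE)  # expected excursion size
  if (Em <= 0 || EN <= 0) return(NA_real_)
  beta <- (gamma(1.5) * Em / EN)^2
  p_ge <- exp(-beta * extent_resels^2)
  tails <- if (two_tailed) 2 else 1
  -expm1(-tails * Em * p_ge)   # stays strictly positive for large extents
}

#' Identify supra-threshold clusters of a t-curve
#'
#' Maximal contiguous runs of nodes where the (absolute, if two-tailed)
#' t-curve exceeds the threshold. Cluster endpoints are refined to fractional
#' normalized time by linear interpolation of the threshold crossings; each
#' cluster receives an RFT extent p-value.
#'
#' @param t_curve t-statistic per node (`NA` allowed at masked nodes).
#' @param t_star critical threshold from [rft_threshold()].
#' @param fwhm smoothness in nodes.
#' @param df degrees of freedom.
#' @param percent node positions on 0-100% (defaults to evenly spaced).
#' @param resels resel count used for the p-values (defaults to
#'   `(nodes - 1)/fwhm`).
#' @param two_tailed logical.
#' @return Data frame: `start_pct`, `end_pct`, `extent_resels`, `peak_t`,
#'   `sign`, `p`; zero rows when nothing exceeds the threshold.
#' @export
find_clusters <- function(t_curve, t_star, fwhm, df,
                          percent = seq(0, 100, length.out = length(t_curve)),
                          resels = (length(t_curve) - 1) / fwhm,
                          two_tailed = TRUE) {
  z <- if (two_tailed) abs(t_curve) else t_curve
  above <- !is.na(z) & z > t_star
  empty <- data.frame(start_pct = numeric(), end_pct = numeric(),
                      extent_resels = numeric(), peak_t = numeric(),
                      sign = numeric(), p = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  node_w <- mean(diff(percent))
  rows <- lapply(keep, function(j) {
    i1 <- starts[j]; i2 <- ends[j]
    x1 <- percent[i1]
    if (i1 > 1 && !is.na(z[i1 - 1])) {
      frac <- (t_star - z[i1 - 1]) / (z[i1] - z[i1 - 1])
      x1 <- percent[i1 - 1] + frac * (percent[i1] - percent[i1 - 1])
    }
    x2 <- percent[i2]
    if (i2 < length(z) && !is.na(z[i2 + 1])) {
      frac <- (z[i2] - t_star) / (z[i2] - z[i2 + 1])
      x2 <- percent[i2] + frac * (percent[i2 + 1] - percent[i2])
    }
    ext_resels <- (x2 - x1) / node_w / fwhm
    ipk <- (i1:i2)[which.max(z[i1:i2])]
    data.frame(start_pct = x1, end_pct = x2, extent_resels = ext_resels,
               peak_t = t_curve[ipk], sign = sign(t_curve[ipk]),
               p = cluster_p_value(ext_resels, t_star, df, resels, two_tailed))
  })
  do.call(rbind, rows)
}

#' Paired SPM test on two sets of normalized curves
#'
#' Full inference chain: paired t-curve, residual smoothness, RFT threshold
#' at the chosen alpha, supra-threshold clusters with extent p-values.
#' Masked (zero-variance) nodes are excluded from the resel count.
#'
#' @param A,B participant x node matrices (same participants, same order);
#'   `A` is the condition of interest, `B` the reference, so positive t means
#'   `A` above `B`.
#' @param alpha family-wise error rate (default 0.05).
#' @param two_tailed logical (default `TRUE`).
#' @param percent node positions on 0-100%.
#' @return An object of class `spm_result`: `t`, `percent`, `df`, `fwhm`,
#'   `resels`, `t_star`, `clusters`, `alpha`, `two_tailed`, `masked`.
#' @export
spm_paired_test <- function(A, B, alpha = 0.05, two_tailed = TRUE,
                            percent = seq(0, 100, length.out = ncol(A))) {
  tt <- paired_t_curve(A, B)
  fwhm <- estimate_fwhm(tt$residuals, masked = tt$masked)
  resels <- (sum(!tt$masked) - 1) / fwhm
  t_star <- rft_threshold(tt$df, resels, alpha, two_tailed)
  clusters <- find_clusters(tt$t, t_star, fwhm, tt$df, percent = percent,
                            resels = resels, two_tailed = two_tailed)
  structure(list(t = tt$t, percent = percent, df = tt$df, fwhm = fwhm,
                 resels = resels, t_star = t_star, clusters = clusters,
                 alpha = alpha, two_tailed = two_tailed, masked = tt$masked),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("SPM paired t-test: df = %d, FWHM = %.1f nodes, resels = %.2f\n",
              x$df, x$fwhm, x$resels))
  cat(sprintf("  t* = %.3f (alpha = %g, %s)\n", x$t_star, x$alpha,
              if (x$two_tailed) "two-tailed" else "one-tailed"))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %.1f-%.1f%% (peak t = %.2f, p = %.4f)\n",
                  i, x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$peak_t[i], x$clusters$p[i]))
  }
  invisible(x)
}

#' Plot an SPM result
#'
#' Draws the t-curve over normalized time with the critical threshold
#' (dotted) and supra-threshold clusters shaded.
#'
#' @param x an `spm_result`.
#' @param ... passed to [plot()].
#' @export
plot.spm_result <- function(x, ...) {
  ylim <- range(c(x$t, x$t_star, -x$t_star), na.rm = TRUE)
  graphics::plot(x$percent, x$t, type = "l", xlab = "normalized time (%)",
                 ylab = "SPM{t}", ylim = ylim, ...)
  graphics::abline(h = c(-1, 1) * x$t_star, lty = 3)
  graphics::abline(h = 0, col = "grey")
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      sel <- x$percent >= x$clusters$start_pct[i] &
        x$percent <= x$clusters$end_pct[i]
      graphics::polygon(c(x$percent[sel], rev(x$percent[sel])),
                        c(x$t[sel], rep(0, sum(sel))),
                        col = grDevices::adjustcolor("grey", 0.5), border = NA)
    }
  }
  invisible(x)
}
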