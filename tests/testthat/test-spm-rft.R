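test_that("identical conditions give a null t-curve", {
  set.seed(20)
  A <- matrix(rnorm(50), 5, 10)
  tt <- paired_t_curve(A, A)
  expect_equal(tt$t, rep(0, 10))
  expect_false(any(tt$masked))
  expect_identical(tt$df, 4L)
})

test_that("each node reproduces the scalar paired t-test", {
  set.seed(21)
  A <- matrix(rnorm(80), 8, 10)
  B <- matrix(rnorm(80), 8, 10)
  tt <- paired_t_curve(A, B)
  for (q in c(1, 5, 10)) {
    sc <- stats::t.test(A[, q], B[, q], paired = TRUE)
    expect_equal(tt$t[q], unname(sc$statistic), tolerance = 1e-12)
  }
})

test_that("constant nonzero differences mask the node", {
  set.seed(22)
  A <- matrix(rnorm(40), 4, 10)
  B <- A
  B[, 3] <- A[, 3] - 2   # same shift for every participant
  tt <- paired_t_curve(A, B)
  expect_true(tt$masked[3])
  expect_true(is.na(tt$t[3]))
  expect_false(any(tt$masked[-3]))
})

test_that("A/B swap negates the t-curve and preserves clusters", {
  set.seed(23)
  gen <- smooth_field_sampler(101, 12)
  A <- gen(10) + 2 * sin(seq(0, pi, length.out = 101))
  B <- gen(10)
  s1 <- spm_paired_test(A, B)
  s2 <- spm_paired_test(B, A)
  expect_equal(s1$t, -s2$t, tolerance = 1e-12)
  expect_equal(s1$t_star, s2$t_star, tolerance = 1e-12)
  expect_equal(s1$clusters$start_pct, s2$clusters$start_pct, tolerance = 1e-9)
  expect_equal(s1$clusters$p, s2$clusters$p, tolerance = 1e-12)
  expect_equal(s1$clusters$sign, -s2$clusters$sign)
})

test_that("smoothness estimator recovers a known field FWHM", {
  set.seed(24)
  gen <- smooth_field_sampler(101, 12)
  ests <- replicate(200, {
    R <- gen(10)
    estimate_fwhm(sweep(R, 2, colMeans(R)))
  })
  expect_lt(abs(mean(ests) - 12) / 12, 0.15)
})

test_that("nearly constant fields give a huge FWHM and the uncorrected threshold", {
  a <- rnorm(8)
  a <- a - mean(a)
  R <- outer(a, 100 + seq(0, 1, length.out = 101))
  fwhm <- estimate_fwhm(R)
  expect_gt(fwhm, 1e3)
  t_unc <- stats::qt(0.975, 9)
  expect_lt(abs(rft_threshold(9, 100 / fwhm, 0.05) - t_unc), 0.02)
  ## exact zero-resel limit: the uncorrected two-tailed quantile
  expect_equal(rft_threshold(9, 0, 0.05), t_unc, tolerance = 1e-9)
})

test_that("the RFT threshold is monotone in its arguments", {
  t_ref <- rft_threshold(9, 10, 0.05)
  expect_gt(t_ref, rft_threshold(9, 5, 0.05))       # fewer resels, lower t*
  expect_gt(t_ref, rft_threshold(9, 10, 0.10))      # larger alpha, lower t*
  expect_gt(t_ref, rft_threshold(30, 10, 0.05))     # more df, lower t*
  expect_gt(t_ref, stats::qt(0.975, 9))             # above uncorrected
  expect_error(rft_threshold(9, 10, 1.5), class = "invalid_parameter")
  expect_error(rft_threshold(0.5, 10, 0.05), class = "invalid_parameter")
})

test_that("clusters are detected with interpolated endpoints", {
  Q <- 100
  t_curve <- rep(0, Q + 1)
  ## triangular excursion peaking at node 62 (q = 61%)
  ramp <- seq(0, 1, length.out = 14)
  t_curve[49:62] <- ramp * 6
  t_curve[62:75] <- rev(ramp) * 6
  t_star <- 3
  cl <- find_clusters(t_curve, t_star, fwhm = 12, df = 9)
  expect_identical(nrow(cl), 1L)
  ## analytic crossings of the two ramps
  up <- 48 + 13 * (3 / 6)
  down <- 61 + 13 * (1 - 3 / 6)
  expect_equal(cl$start_pct, up, tolerance = 1e-9)
  expect_equal(cl$end_pct, down, tolerance = 1e-9)
  expect_equal(cl$peak_t, 6)
  expect_true(cl$p > 0 && cl$p < 0.05)
  ## sub-threshold curve yields no clusters
  expect_identical(nrow(find_clusters(t_curve, 7, 12, 9)), 0L)
})

test_that("cluster p-values decrease with extent and stay within (0, alpha]", {
  Q <- 100
  narrow <- rep(0, Q + 1); narrow[50:55] <- 5
  wide <- rep(0, Q + 1); wide[30:75] <- 5
  cn <- find_clusters(narrow, 3.5, 12, 9)
  cw <- find_clusters(wide, 3.5, 12, 9)
  expect_lt(cw$p, cn$p)
  t_star <- rft_threshold(9, 100 / 12, 0.05)
  for (width in c(3, 10, 25, 60)) {
    tc <- rep(0, Q + 1); tc[50:(50 + width)] <- t_star + 0.4
    cl <- find_clusters(tc, t_star, 12, 9, resels = 100 / 12)
    expect_true(cl$p > 0 && cl$p <= 0.05 + 1e-9)
  }
})

test_that("negative excursions are detected two-tailed", {
  Q <- 100
  tc <- rep(0, Q + 1)
  tc[40:60] <- -6
  cl <- find_clusters(tc, 3, 12, 9)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$sign, -1)
  expect_equal(cl$peak_t, -6)
})

test_that("the full paired test is internally consistent", {
  set.seed(26)
  gen <- smooth_field_sampler(101, 15)
  A <- gen(10) - 1.5 * exp(-((0:100) - 60)^2 / 50)
  B <- gen(10)
  s <- spm_paired_test(A, B)
  expect_identical(s$df, 9L)
  expect_equal(s$resels, 100 / s$fwhm, tolerance = 1e-12)
  expect_equal(s$t_star, rft_threshold(9, s$resels, 0.05, TRUE),
               tolerance = 1e-12)
  ## deterministic given inputs
  s2 <- spm_paired_test(A, B)
  expect_identical(s$t, s2$t)
  expect_identical(s$clusters, s2$clusters)
})
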