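## Shared fixtures: built in code at test time.

quiet_params <- function(...) {
  args <- list(...)
  if (is.null(args$noise_sd)) args$noise_sd <- 0
  do.call(jump_profile_params, args)
}

## A cmj_kinematics object from explicit velocity samples (for analytic
## segmentation/curve tests that bypass the generator).
manual_kinematics <- function(velocity, rate = 1000, gravity = 9.81,
                              acceleration = NULL, body_mass = 70) {
  n <- length(velocity)
  t <- (seq_len(n) - 1) / rate
  a <- acceleration %||% c(diff(velocity) * rate, 0)
  structure(list(time = t, acceleration = a, velocity = velocity,
                 displacement = drop(pracma::cumtrapz(t, velocity)),
                 power = (a + gravity) * velocity, gravity = gravity,
                 sampling_rate = rate, onset_index = 1L,
                 body_mass = body_mass),
            class = "cmj_kinematics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Smooth Gaussian 1D fields with known smoothness: white noise convolved
## with a Gaussian kernel of the stated FWHM (in nodes), unit variance.
smooth_field_sampler <- function(nodes = 101, fwhm = 12) {
  sdk <- fwhm / sqrt(8 * log(2))
  pad <- ceiling(4 * sdk)
  kx <- dnorm(seq(-pad, pad), 0, sdk)
  npre <- nodes + 2 * pad
  K <- matrix(0, nodes, npre)
  for (i in seq_len(nodes)) K[i, i:(i + 2 * pad)] <- rev(kx)
  K <- K / sqrt(sum(kx^2))
  function(n) matrix(rnorm(n * npre), n, npre) %*% t(K)
}

## Wrap a raw force vector in a force_trial without the 2 s length guard.
short_trial <- function(force, rate = 1000, ...) {
  force_trial(force, sampling_rate = rate, min_duration = 0, ...)
}
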