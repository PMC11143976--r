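#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cumsum median pchisq pf pt qt rnorm runif sd t.test uniroot var
#' @importFrom utils read.table write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard gravitational acceleration (m/s^2)
#'
#' Constant used throughout the package to convert between force and
#' centre-of-mass acceleration. Every user-facing function that depends on it
#' exposes a `gravity` argument so the value can be overridden.
#' @export
GRAVITY <- 9.81

stop_cmj <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cmjfatigue_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_cmj("invalid_parameter", "`%s` must be a single positive finite number", name)
  invisible(x)
}

assert_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x < 1)
  if (!ok) stop_cmj("invalid_parameter", "`%s` must be a fraction in %s", name,
                    if (open) "(0, 1)" else "[0, 1)")
  invisible(x)
}

## Evaluate an expression with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## First index of a run of at least `len` consecutive TRUEs, or NA.
first_run_start <- function(x, len) {
  if (!any(x)) return(NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= len
  if (!any(ok)) return(NA_integer_)
  starts[which(ok)[1L]]
}
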