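# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so package functions never disturb user simulations.
#' A `NULL` seed evaluates the code against the current RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(x) atan2(sin(x), cos(x))

# nearest sample index of each time in a time axis (constant fs assumed)
time_index <- function(time_s, at_s) {
  fs <- 1 / (time_s[2] - time_s[1])
  idx <- round((at_s - time_s[1]) * fs) + 1L
  if (any(idx < 1L | idx > length(time_s))) {
    stopf("requested time outside the sampled axis [%.3f, %.3f]",
          time_s[1], time_s[length(time_s)])
  }
  idx
}

# logical column selector for a half-open interval [lo, hi) on a time axis
time_window <- function(time_s, interval_s) {
  if (length(interval_s) != 2L || interval_s[2] <= interval_s[1]) {
    stopf("interval must be c(lo, hi) with hi > lo")
  }
  sel <- time_s >= interval_s[1] & time_s < interval_s[2]
  if (!any(sel)) stopf("interval [%g, %g) contains no samples",
                       interval_s[1], interval_s[2])
  sel
}
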