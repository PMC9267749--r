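# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulators do not perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive n child seeds (< 2^31) from one master seed. Single declared
# splitting rule used everywhere randomness fans out.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Uniform-grid check: all steps equal the median step within rel. tolerance.
is_uniform_grid <- function(time, rel_tol = 1e-6) {
  if (length(time) < 2L) return(TRUE)
  dt <- diff(time)
  h <- stats::median(dt)
  h > 0 && all(abs(dt - h) <= rel_tol * h)
}

grid_step <- function(time) stats::median(diff(time))

# Linear resampling of (t, x) onto new times; constant extrapolation at ends.
resample_linear <- function(time, x, new_time) {
  stats::approx(time, x, xout = new_time, method = "linear", rule = 2)$y
}

# First-order low-pass (unit DC gain) on a uniform grid: discrete form of
# convolution with (1/tau) * exp(-t/tau).
exp_smooth <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
}

# Sample standard deviation that tolerates n = 1 (returns NA).
sd_or_na <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits = 12L) formatC(x, digits = digits, format = "g")
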