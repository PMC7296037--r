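#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

#' Trapezoidal integral of y over x restricted to an interval
#'
#' Integrates a sampled function over `[a, b]`, linearly interpolating the
#' integrand at the interval endpoints so band edges that fall between grid
#' points are handled exactly for piecewise-linear integrands.
#'
#' @keywords internal
trapz_interval <- function(x, y, a, b) {
  if (a < min(x) - 1e-12 || b > max(x) + 1e-12) {
    stop("integration interval outside the frequency grid", call. = FALSE)
  }
  ya <- approx(x, y, xout = a)$y
  yb <- approx(x, y, xout = b)$y
  inside <- x > a & x < b
  xs <- c(a, x[inside], b)
  ys <- c(ya, y[inside], yb)
  pracma::trapz(xs, ys)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
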