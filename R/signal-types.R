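#' Construct a uniformly sampled voltage signal
#'
#' The basic container for local field potential traces and evoked sweeps:
#' a numeric sample vector plus its sampling rate and start time.
#'
#' @param samples numeric vector of voltage samples (arbitrary units,
#'   nominally microvolts for LFP).
#' @param fs sampling rate in Hz. In-vivo LFP is nominally sampled at
#'   1000 Hz through a 0.5--300 Hz acquisition band-pass.
#' @param t0 start time in seconds (default 0).
#' @return An object of class `lfp_signal` with fields `samples`, `fs`, `t0`.
#' @examples
#' sig <- lfp_signal(sin(2 * pi * 8 * seq(0, 2, by = 1e-3)), fs = 1000)
#' duration(sig)
#' @export
lfp_signal <- function(samples, fs, t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("`samples` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (anyNA(samples)) stop("`samples` must not contain missing values", call. = FALSE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(t0, "t0")
  structure(
    list(samples = as.numeric(samples), fs = fs, t0 = t0),
    class = "lfp_signal"
  )
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat(sprintf("<lfp_signal> %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @rdname lfp_signal
#' @param x an `lfp_signal`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "lfp_signal"))
  length(x$samples) / x$fs
}

#' Sample times of a signal
#' @param x an `lfp_signal`.
#' @return numeric vector of times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "lfp_signal"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

#' Define a frequency band
#'
#' @param name band label.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi`.
#' @return An object of class `frequency_band`.
#' @seealso [band_preset()] for the hippocampal presets.
#' @export
frequency_band <- function(name, f_lo, f_hi) {
  stopifnot(is_string(name))
  stopifnot_scalar_number(f_lo, "f_lo")
  stopifnot_scalar_number(f_hi, "f_hi")
  if (f_lo < 0 || f_lo >= f_hi) {
    stop("require 0 <= f_lo < f_hi", call. = FALSE)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "frequency_band")
}

#' Hippocampal oscillation band presets
#'
#' Standard bands for CA1 local field potentials: theta 4--12 Hz,
#' low gamma 30--50 Hz, high gamma 80--120 Hz.
#'
#' @param name one of `"theta"`, `"low_gamma"`, `"high_gamma"`.
#' @return A [frequency_band()].
#' @examples
#' band_preset("low_gamma")
#' @export
band_preset <- function(name = c("theta", "low_gamma", "high_gamma")) {
  name <- match.arg(name)
  switch(name,
    theta      = frequency_band("theta", 4, 12),
    low_gamma  = frequency_band("low_gamma", 30, 50),
    high_gamma = frequency_band("high_gamma", 80, 120)
  )
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "frequency_band")) return(band)
  if (is.character(band) && length(band) == 1L) return(band_preset(band))
  if (is.numeric(band) && length(band) == 2L) {
    return(frequency_band("custom", band[1], band[2]))
  }
  stop("`band` must be a frequency_band, preset name, or length-2 numeric",
       call. = FALSE)
}
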