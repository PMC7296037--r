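#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion -- the emulation used
#' for both the 0.5--300 Hz acquisition band-pass and the 0--120 Hz
#' digital filter, and the band-pass underlying analytic-signal
#' extraction.
#'
#' @param sig an [lfp_signal()].
#' @param f_lo,f_hi band edges in Hz; `f_lo = 0` gives a low-pass.
#' @param order filter order (default 4).
#' @return a filtered [lfp_signal()].
#' @export
bandpass_filter <- function(sig, f_lo, f_hi, order = 4) {
  stopifnot(inherits(sig, "lfp_signal"))
  nyq <- sig$fs / 2
  if (f_hi >= nyq) {
    stop(sprintf("upper band edge %g Hz is at or above Nyquist (%g Hz)",
                 f_hi, nyq), call. = FALSE)
  }
  if (f_lo < 0 || f_lo >= f_hi) stop("require 0 <= f_lo < f_hi", call. = FALSE)
  run <- function(ord) {
    bf <- if (f_lo <= 0) {
      signal::butter(ord, f_hi / nyq, type = "low")
    } else {
      signal::butter(ord, c(f_lo, f_hi) / nyq, type = "pass")
    }
    signal::filtfilt(bf, sig$samples)
  }
  y <- run(order)
  # very narrow normalized bands can make the IIR recursion blow up in
  # double precision; retry at order 2 (filtfilt doubles it anyway)
  if (anyNA(y) || max(abs(y)) > 1e3 * max(abs(sig$samples), 1e-300)) {
    y <- run(2)
    if (anyNA(y)) {
      stop(sprintf("band-pass %g-%g Hz unstable at fs = %g Hz", f_lo, f_hi,
                   sig$fs), call. = FALSE)
    }
  }
  lfp_signal(y, fs = sig$fs, t0 = sig$t0)
}

# analytic extension of a real series via the one-sided FFT spectrum
analytic_extend <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Band-limited analytic signal (instantaneous phase and amplitude)
#'
#' Band-pass filters the signal (zero-phase Butterworth) and forms the
#' analytic extension by the Hilbert transform; phase is the complex
#' argument and amplitude the modulus. The theta default band is 4--12 Hz.
#'
#' @param sig an [lfp_signal()].
#' @param band a [frequency_band()], preset name, or `c(f_lo, f_hi)`;
#'   default the 4--12 Hz theta band.
#' @return An object of class `analytic_signal`: `phase` (radians,
#'   (-pi, pi]), `amplitude` (envelope, >= 0), `band`, `fs`, `n_samples`.
#' @examples
#' t <- seq(1e-3, 10, by = 1e-3)
#' as8 <- analytic_signal(lfp_signal(sin(2 * pi * 8 * t), 1000), "theta")
#' sd(as8$amplitude[1000:9000])   # ~0: constant envelope
#' @export
analytic_signal <- function(sig, band = band_preset("theta")) {
  stopifnot(inherits(sig, "lfp_signal"))
  band <- as_band(band)
  nyq <- sig$fs / 2
  if (band$f_hi >= nyq) {
    stop(sprintf("band %g-%g Hz reaches Nyquist (%g Hz)", band$f_lo,
                 band$f_hi, nyq), call. = FALSE)
  }
  if (band$f_lo > 0 && length(sig$samples) < 10 * sig$fs / band$f_lo) {
    stop("signal shorter than 10 cycles of the band's lower edge",
         call. = FALSE)
  }
  filtered <- bandpass_filter(sig, band$f_lo, band$f_hi)
  z <- analytic_extend(filtered$samples)
  structure(
    list(phase = Arg(z), amplitude = Mod(z), band = band, fs = sig$fs,
         n_samples = length(sig$samples)),
    class = "analytic_signal"
  )
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal> %d samples @ %g Hz, band %s %g-%g Hz\n",
              x$n_samples, x$fs, x$band$name, x$band$f_lo, x$band$f_hi))
  invisible(x)
}
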