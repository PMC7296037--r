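#' Single-taper Hann spectrogram
#'
#' Short-time power spectra on overlapping windows with a single Hann
#' taper, the settings used for LFP time-frequency displays (window shift
#' 0.1 s, frequencies clipped to 0--120 Hz). Window k starts at
#' `(k-1) * shift_s`; a signal of duration `T` with window `w` yields
#' `floor((T - w) / shift) + 1` time bins. Reported times are window
#' centers (relative to `t0`).
#'
#' @param sig an [lfp_signal()].
#' @param window_s window length in seconds (default 1).
#' @param shift_s window shift in seconds (default 0.1).
#' @param f_max highest retained frequency in Hz (default 120).
#' @param nfft FFT length; default next power of two >= window length.
#' @return An object of class `spectrogram_tf`: `times` (s, window
#'   centers), `freqs` (Hz), `power` (time x frequency matrix, >= 0),
#'   `window_s`, `shift_s`, `window_fn = "hann"`.
#' @examples
#' t <- seq(1e-3, 10, by = 1e-3)
#' sg <- spectrogram(lfp_signal(sin(2 * pi * 40 * t), 1000))
#' nrow(sg$power)   # 91 bins: (10 - 1)/0.1 + 1
#' @export
spectrogram <- function(sig, window_s = 1.0, shift_s = 0.1, f_max = 120,
                        nfft = NULL) {
  stopifnot(inherits(sig, "lfp_signal"))
  stopifnot_scalar_number(window_s, "window_s", positive = TRUE)
  stopifnot_scalar_number(shift_s, "shift_s", positive = TRUE)
  if (window_s < shift_s) stop("require window_s >= shift_s", call. = FALSE)
  x <- sig$samples
  wl <- as.integer(round(window_s * sig$fs))
  sh <- as.integer(round(shift_s * sig$fs))
  if (wl > length(x)) stop("window longer than the signal", call. = FALSE)
  if (sh < 1L) stop("`shift_s` shorter than one sample", call. = FALSE)

  if (is.null(nfft)) nfft <- next_pow2(wl)
  win <- as.numeric(signal::hanning(wl))
  wnorm <- sum(win^2)
  starts <- seq(1L, length(x) - wl + 1L, by = sh)

  freqs_all <- (0:(nfft %/% 2)) * (sig$fs / nfft)
  keep <- freqs_all <= f_max + 1e-9
  P <- matrix(0, nrow = length(starts), ncol = sum(keep))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + wl - 1L)] * win
    J <- fft(c(seg, numeric(nfft - wl)))
    p <- Mod(J[1:(nfft %/% 2 + 1L)])^2 / (wnorm * sig$fs)
    half <- nfft %/% 2
    if (half > 1L) p[2:half] <- 2 * p[2:half]
    P[i, ] <- p[keep]
  }
  structure(
    list(times = sig$t0 + (starts - 1L) / sig$fs + window_s / 2,
         freqs = freqs_all[keep], power = P,
         window_s = window_s, shift_s = shift_s, window_fn = "hann"),
    class = "spectrogram_tf"
  )
}

#' @export
print.spectrogram_tf <- function(x, ...) {
  cat(sprintf(
    "<spectrogram_tf> %d time bins x %d frequencies (0-%g Hz), %g s %s window, %g s shift\n",
    nrow(x$power), ncol(x$power), max(x$freqs), x$window_s, x$window_fn,
    x$shift_s))
  invisible(x)
}

#' Perievent (event-triggered average) spectrogram
#'
#' Cuts a `[-pre_s, +post_s]` slice around each event time, computes the
#' Hann spectrogram of each slice, and averages the power matrices across
#' events; the time axis is re-expressed relative to the event (negative =
#' pre-event). Events whose slice would extend beyond the recording are
#' skipped and counted.
#'
#' @param sig an [lfp_signal()].
#' @param event_times event times in seconds (same clock as `t0`).
#' @param pre_s,post_s seconds of signal before/after each event
#'   (default 2 each).
#' @param window_s,shift_s,f_max,nfft passed to [spectrogram()].
#' @return a `spectrogram_tf` with times relative to the event, plus
#'   fields `n_events` (averaged) and `n_skipped`.
#' @export
perievent_spectrogram <- function(sig, event_times, pre_s = 2, post_s = 2,
                                  window_s = 1.0, shift_s = 0.1, f_max = 120,
                                  nfft = NULL) {
  stopifnot(inherits(sig, "lfp_signal"))
  if (length(event_times) < 1L) stop("no events supplied", call. = FALSE)
  t_end <- sig$t0 + (length(sig$samples) - 1L) / sig$fs

  acc <- NULL
  template <- NULL
  n_used <- 0L
  n_skipped <- 0L
  for (ev in sort(event_times)) {
    a <- ev - pre_s
    b <- ev + post_s
    if (a < sig$t0 - 1e-9 || b > t_end + 1e-9) {
      n_skipped <- n_skipped + 1L
      next
    }
    i0 <- as.integer(round((a - sig$t0) * sig$fs)) + 1L
    i1 <- i0 + as.integer(round((pre_s + post_s) * sig$fs)) - 1L
    slice <- lfp_signal(sig$samples[i0:i1], fs = sig$fs, t0 = -pre_s)
    sg <- spectrogram(slice, window_s = window_s, shift_s = shift_s,
                      f_max = f_max, nfft = nfft)
    if (is.null(acc)) {
      acc <- sg$power
      template <- sg
    } else {
      acc <- acc + sg$power
    }
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    stop("every event was too close to a recording edge", call. = FALSE)
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d event(s) skipped: slice outside the recording",
                    n_skipped))
  }
  template$power <- acc / n_used
  template$n_events <- n_used
  template$n_skipped <- n_skipped
  template
}
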