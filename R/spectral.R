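#' Multitaper power spectral density
#'
#' Estimates the one-sided power spectrum of a signal by averaging tapered
#' periodograms over a Slepian taper ensemble:
#' \deqn{S(f) = \frac{1}{K} \sum_{k=1}^{K} \left| \frac{1}{N}
#'   \sum_{n=1}^{N} e^{2\pi i f n} u_n^k X_n \right|^2}
#' where \eqn{u^k} is the k-th taper. Two output scalings are provided:
#' `"eq"` returns the raw estimator value above (arbitrary units, as
#' conventionally plotted for LFP spectra), while the default `"density"`
#' rescales to a physical one-sided density in units^2/Hz
#' (`raw * N^2 / fs`, doubled off DC/Nyquist) so that the integral of the
#' density over `[0, fs/2]` equals the signal mean square (Parseval).
#'
#' If the signal is longer than the tapers and `segmented = TRUE`, the
#' signal is cut into `floor(length / n_samples)` non-overlapping segments
#' of taper length and the segment estimates are averaged; any remainder
#' samples are dropped. Otherwise a length mismatch is an error.
#'
#' @param sig an [lfp_signal()].
#' @param tapers a [taper_set()]; default Slepian tapers of the signal
#'   length with `nw` and `k`.
#' @param nw,k taper parameters used only when `tapers` is `NULL`
#'   (default NW = 3, K = 2 NW - 1 = 5).
#' @param nfft FFT length; default next power of two >= taper length
#'   (zero-padded, giving <= 0.5 Hz resolution for 2-s epochs at 1000 Hz).
#' @param scaling `"density"` (units^2/Hz, Parseval-consistent) or `"eq"`
#'   (raw estimator value).
#' @param demean subtract the (per-segment) mean before tapering
#'   (default `FALSE`: the estimator is applied verbatim).
#' @param segmented average over taper-length segments when the signal is
#'   longer than the tapers.
#' @return An object of class `psd_estimate`: fields `freqs` (Hz, 0 to
#'   fs/2), `power`, `n_tapers`, `n_samples`, `fs`, `scaling`,
#'   `n_segments`.
#' @examples
#' t <- seq(0, 2, by = 1e-3)[-1]
#' sig <- lfp_signal(sin(2 * pi * 40 * t), fs = 1000)
#' psd <- multitaper_psd(sig)
#' psd$freqs[which.max(psd$power)]   # ~40 Hz
#' @export
multitaper_psd <- function(sig, tapers = NULL, nw = 3, k = NULL, nfft = NULL,
                           scaling = c("density", "eq"), demean = FALSE,
                           segmented = FALSE) {
  stopifnot(inherits(sig, "lfp_signal"))
  scaling <- match.arg(scaling)
  x <- sig$samples
  if (is.null(tapers)) {
    n_tap <- if (segmented) {
      stop("`segmented = TRUE` requires an explicit taper set", call. = FALSE)
    } else {
      length(x)
    }
    tapers <- make_slepian_tapers(n_tap, nw, k)
  }
  stopifnot(inherits(tapers, "taper_set"))
  n <- tapers$n_samples

  if (length(x) != n) {
    if (!segmented) {
      stop(sprintf(
        "signal length (%d) != taper length (%d); set `segmented = TRUE` to average over segments",
        length(x), n), call. = FALSE)
    }
    if (length(x) < n) {
      stop("signal shorter than the tapers", call. = FALSE)
    }
    n_seg <- length(x) %/% n
    segs <- lapply(seq_len(n_seg), function(i) x[((i - 1L) * n + 1L):(i * n)])
  } else {
    n_seg <- 1L
    segs <- list(x)
  }

  if (is.null(nfft)) nfft <- next_pow2(n)
  if (nfft < n) stop("`nfft` must be >= taper length", call. = FALSE)

  acc <- 0
  for (seg in segs) {
    if (demean) seg <- seg - mean(seg)
    tx <- tapers$tapers * seg                   # n x K
    padded <- rbind(tx, matrix(0, nfft - n, tapers$k))
    J <- mvfft(padded)                          # nfft x K
    acc <- acc + rowMeans(Mod(J)^2) / n^2       # Eq-style raw value, two-sided
  }
  raw <- acc / n_seg

  half <- nfft %/% 2
  freqs <- (0:half) * (sig$fs / nfft)
  p <- raw[1:(half + 1L)]
  if (scaling == "density") {
    p <- p * n^2 / sig$fs
    if (half > 1L) p[2:half] <- 2 * p[2:half]   # fold negative frequencies
  }

  structure(
    list(freqs = freqs, power = p, n_tapers = tapers$k, n_samples = n,
         fs = sig$fs, scaling = scaling, n_segments = n_seg,
         nfft = nfft),
    class = "psd_estimate"
  )
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf(
    "<psd_estimate> %d frequencies 0-%g Hz, K = %d tapers, N = %d, %s scaling%s\n",
    length(x$freqs), max(x$freqs), x$n_tapers, x$n_samples, x$scaling,
    if (x$n_segments > 1L) sprintf(", %d segments", x$n_segments) else ""))
  invisible(x)
}

#' Integrated band power of a PSD estimate
#'
#' Trapezoidal integral of the spectral density over `[f_lo, f_hi]`, with
#' linear interpolation at band edges that fall between grid points.
#'
#' @param psd a `psd_estimate` (density scaling recommended; units^2).
#' @param band a [frequency_band()], preset name, or `c(f_lo, f_hi)`.
#' @return scalar band power.
#' @examples
#' t <- seq(1e-3, 2, by = 1e-3)
#' psd <- multitaper_psd(lfp_signal(sin(2 * pi * 40 * t), fs = 1000))
#' band_power(psd, "low_gamma") > band_power(psd, "theta")
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_estimate"))
  band <- as_band(band)
  if (band$f_lo < min(psd$freqs) || band$f_hi > max(psd$freqs)) {
    stop(sprintf("band %g-%g Hz outside the frequency grid 0-%g Hz",
                 band$f_lo, band$f_hi, max(psd$freqs)), call. = FALSE)
  }
  trapz_interval(psd$freqs, psd$power, band$f_lo, band$f_hi)
}

#' Ratio of band power between two PSD estimates
#'
#' The exploration/approach statistic: band power of the numerator PSD
#' divided by band power of the denominator PSD, computed on identical
#' frequency grids.
#'
#' @param psd_num,psd_den `psd_estimate` objects on the same grid.
#' @param band band over which to integrate.
#' @return scalar ratio.
#' @export
psd_band_ratio <- function(psd_num, psd_den, band) {
  stopifnot(inherits(psd_num, "psd_estimate"), inherits(psd_den, "psd_estimate"))
  if (length(psd_num$freqs) != length(psd_den$freqs) ||
      max(abs(psd_num$freqs - psd_den$freqs)) > 1e-9) {
    stop("the two PSD estimates must share an identical frequency grid",
         call. = FALSE)
  }
  den <- band_power(psd_den, band)
  if (den <= 0) {
    band <- as_band(band)
    stop(sprintf("zero denominator band power in %g-%g Hz", band$f_lo,
                 band$f_hi), call. = FALSE)
  }
  band_power(psd_num, band) / den
}

#' Randomly select artifact-free epochs from a recording
#'
#' Emulates the manual selection of representative artifact-free epochs:
#' the recording is tiled into non-overlapping windows of `epoch_s`
#' seconds, windows whose peak absolute robust z-score (relative to the
#' whole-recording median and MAD) reaches `artifact_z` are excluded, and
#' `n_epochs` of the remaining windows are sampled without replacement
#' under `seed`. Deterministic for a fixed seed.
#'
#' @param sig an [lfp_signal()].
#' @param n_epochs number of epochs (default 10).
#' @param epoch_s epoch duration in seconds (default 2).
#' @param artifact_z robust z-score threshold marking a window as
#'   artifact-contaminated (default 6).
#' @param seed integer RNG seed.
#' @return An object of class `epoch_set`: `epochs` (list of
#'   [lfp_signal()]s), `indices` (1-based start samples, sorted),
#'   `epoch_s`, `seed`, `n_available`.
#' @export
select_epochs <- function(sig, n_epochs = 10, epoch_s = 2.0, artifact_z = 6,
                          seed = 1L) {
  stopifnot(inherits(sig, "lfp_signal"))
  stopifnot_scalar_number(n_epochs, "n_epochs", positive = TRUE)
  stopifnot_scalar_number(epoch_s, "epoch_s", positive = TRUE)
  stopifnot_scalar_number(artifact_z, "artifact_z", positive = TRUE)
  x <- sig$samples
  len <- as.integer(round(epoch_s * sig$fs))
  if (len < 2L) stop("`epoch_s` too short for the sampling rate", call. = FALSE)
  n_win <- length(x) %/% len
  if (n_win < 1L) stop("signal shorter than one epoch", call. = FALSE)

  ctr <- median(x)
  scl <- mad(x)
  if (scl <= 0) scl <- sd(x)
  if (scl <= 0) scl <- 1
  starts <- (seq_len(n_win) - 1L) * len + 1L
  peak_z <- vapply(starts, function(s) {
    max(abs((x[s:(s + len - 1L)] - ctr) / scl))
  }, numeric(1))
  clean <- starts[peak_z < artifact_z]

  if (length(clean) < n_epochs) {
    stop(sprintf(
      "only %d artifact-free windows available (requested %d)",
      length(clean), n_epochs), call. = FALSE)
  }
  picked <- sort(with_seed(seed, sample(clean, n_epochs)))
  epochs <- lapply(picked, function(s) {
    lfp_signal(x[s:(s + len - 1L)], fs = sig$fs,
               t0 = sig$t0 + (s - 1L) / sig$fs)
  })
  structure(
    list(epochs = epochs, indices = picked, epoch_s = epoch_s, seed = seed,
         n_available = length(clean)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s (of %d clean windows), seed %s\n",
              length(x$epochs), x$epoch_s, x$n_available, format(x$seed)))
  invisible(x)
}

#' Average multitaper PSD over an epoch set
#'
#' Convenience wrapper: multitaper PSD of every epoch, averaged on the
#' common grid. Used for the per-epoch-then-average band statistics.
#'
#' @param ep an `epoch_set`.
#' @param ... passed to [multitaper_psd()].
#' @return a `psd_estimate`.
#' @export
epoch_psd <- function(ep, ...) {
  stopifnot(inherits(ep, "epoch_set"))
  psds <- lapply(ep$epochs, multitaper_psd, ...)
  out <- psds[[1]]
  if (length(psds) > 1L) {
    out$power <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
  }
  out$n_segments <- length(psds)
  out
}
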