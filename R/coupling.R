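#' Phase-binned amplitude distribution
#'
#' Bins the envelope of a fast oscillation by the instantaneous phase of a
#' slow oscillation into `n_bins` equal phase bins on (-pi, pi], and
#' normalizes the per-bin mean amplitudes to a probability distribution.
#' One second is trimmed from each end of both series before binning to
#' discard filter edge transients (`edge_trim_s`).
#'
#' Empty phase bins (possible only for very short or degenerate inputs)
#' are dropped with a warning in the default lenient mode, reducing the
#' effective bin count; `strict = TRUE` raises an error instead.
#'
#' @param phase an [analytic_signal()] providing the phase series.
#' @param amplitude an [analytic_signal()] providing the envelope.
#' @param n_bins number of phase bins (default 18, i.e. 20 degrees).
#' @param edge_trim_s seconds trimmed from each end (default 1).
#' @param strict error on empty bins instead of dropping them.
#' @return An object of class `phase_amplitude_distribution`:
#'   `bin_edges` (radians, length `n_bins + 1`), `bin_centers`,
#'   `mean_amplitude`, `normalized` (sums to 1), `n_bins` (effective),
#'   `n_samples`.
#' @export
phase_amplitude_distribution <- function(phase, amplitude, n_bins = 18,
                                         edge_trim_s = 1, strict = FALSE) {
  stopifnot(inherits(phase, "analytic_signal"),
            inherits(amplitude, "analytic_signal"))
  if (phase$n_samples != amplitude$n_samples) {
    stop("phase and amplitude series must have equal length", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 4L) stop("`n_bins` must be >= 4", call. = FALSE)

  trim <- as.integer(round(edge_trim_s * phase$fs))
  n <- phase$n_samples
  if (n - 2L * trim < n_bins * 4L) {
    stop("series too short after edge trimming", call. = FALSE)
  }
  idx <- (trim + 1L):(n - trim)
  ph <- phase$phase[idx]
  am <- amplitude$amplitude[idx]

  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  bin <- findInterval(ph, edges, rightmost.closed = TRUE, all.inside = TRUE)
  sums <- tabulate(bin, nbins = n_bins)
  mean_amp <- vapply(seq_len(n_bins), function(b) {
    if (sums[b] == 0L) NA_real_ else mean(am[bin == b])
  }, numeric(1))

  if (anyNA(mean_amp)) {
    if (strict) stop("empty phase bin(s) with strict = TRUE", call. = FALSE)
    keep <- !is.na(mean_amp)
    warning(sprintf("dropping %d empty phase bin(s); effective bins = %d",
                    sum(!keep), sum(keep)))
    mean_amp <- mean_amp[keep]
    centers <- (edges[-1] + edges[-length(edges)])[keep] / 2
    n_eff <- sum(keep)
  } else {
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    n_eff <- n_bins
  }
  total <- sum(mean_amp)
  if (total <= 0) stop("degenerate amplitude series (all zero)", call. = FALSE)
  structure(
    list(bin_edges = edges, bin_centers = centers, mean_amplitude = mean_amp,
         normalized = mean_amp / total, n_bins = n_eff,
         n_samples = length(idx)),
    class = "phase_amplitude_distribution"
  )
}

#' Phase-amplitude coupling modulation index
#'
#' Kullback-Leibler modulation index: the envelope of the fast band is
#' binned by the phase of the slow band, the per-bin mean amplitudes are
#' normalized to a distribution P, and
#' `MI = KL(P || uniform) / log(n_bins)`, which lies in [0, 1]; 0 means
#' the envelope is independent of phase, 1 means all envelope is
#' concentrated in a single phase bin.
#'
#' @inheritParams phase_amplitude_distribution
#' @return An object of class `modulation_index_result`: `mi`, `n_bins`
#'   (effective), `phase_band`, `amp_band`, `n_samples`, `distribution`
#'   (the underlying [phase_amplitude_distribution()]).
#' @examples
#' sim <- simulate_lfp(lfp_sim_config(duration_s = 30, coupling_depth = 1,
#'                                    noise_amp = 0, seed = 1))
#' mi <- modulation_index(analytic_signal(sim$lfp, "theta"),
#'                        analytic_signal(sim$lfp, "low_gamma"))
#' mi$mi > 0.01
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18, edge_trim_s = 1,
                             strict = FALSE) {
  pad <- phase_amplitude_distribution(phase, amplitude, n_bins = n_bins,
                                      edge_trim_s = edge_trim_s,
                                      strict = strict)
  p <- pad$normalized
  m <- pad$n_bins
  kl <- sum(p[p > 0] * log(p[p > 0] * m))
  structure(
    list(mi = kl / log(m), n_bins = m, phase_band = phase$band,
         amp_band = amplitude$band, n_samples = pad$n_samples,
         distribution = pad),
    class = "modulation_index_result"
  )
}

#' @export
print.modulation_index_result <- function(x, ...) {
  cat(sprintf(
    "<modulation_index> MI = %.5g (%s %g-%g Hz phase, %s %g-%g Hz amplitude, %d bins, n = %d)\n",
    x$mi, x$phase_band$name, x$phase_band$f_lo, x$phase_band$f_hi,
    x$amp_band$name, x$amp_band$f_lo, x$amp_band$f_hi, x$n_bins,
    x$n_samples))
  invisible(x)
}

#' Phase-amplitude comodulogram
#'
#' Scans a grid of (phase frequency, amplitude frequency) pairs and
#' computes the modulation index for each, searching for cross-frequency
#' coupling. Default grids: phase centers 2--12 Hz in 1 Hz steps with 2 Hz
#' bandwidth (spanning the 4--12 Hz theta band), amplitude centers
#' 20--120 Hz in 5 Hz steps with 20 Hz bandwidth.
#'
#' @param sig an [lfp_signal()].
#' @param phase_freqs,amp_freqs center-frequency grids in Hz.
#' @param phase_bw,amp_bw full bandwidths (Hz) around each center.
#' @param n_bins phase bins for the modulation index.
#' @param edge_trim_s seconds trimmed from each end before binning.
#' @return An object of class `comodulogram`: `phase_freqs`, `amp_freqs`,
#'   `mi` (|phase_freqs| x |amp_freqs| matrix), bandwidths, and
#'   `peak = c(phase_hz, amp_hz)` at the MI argmax.
#' @export
comodulogram <- function(sig, phase_freqs = seq(2, 12, by = 1),
                         amp_freqs = seq(20, 120, by = 5),
                         phase_bw = 2, amp_bw = 20, n_bins = 18,
                         edge_trim_s = 1) {
  stopifnot(inherits(sig, "lfp_signal"))
  if (length(phase_freqs) < 1L || length(amp_freqs) < 1L) {
    stop("frequency grids must be nonempty", call. = FALSE)
  }
  nyq <- sig$fs / 2
  if (max(amp_freqs) + amp_bw / 2 >= nyq) {
    stop("amplitude grid reaches Nyquist", call. = FALSE)
  }
  amp_as <- lapply(amp_freqs, function(fc) {
    analytic_signal(sig, c(fc - amp_bw / 2, fc + amp_bw / 2))
  })
  mi <- matrix(0, nrow = length(phase_freqs), ncol = length(amp_freqs),
               dimnames = list(phase_freqs, amp_freqs))
  for (i in seq_along(phase_freqs)) {
    fp <- phase_freqs[i]
    ph <- analytic_signal(sig, c(max(fp - phase_bw / 2, 0.5), fp + phase_bw / 2))
    for (j in seq_along(amp_freqs)) {
      mi[i, j] <- modulation_index(ph, amp_as[[j]], n_bins = n_bins,
                                   edge_trim_s = edge_trim_s)$mi
    }
  }
  pk <- which(mi == max(mi), arr.ind = TRUE)[1, ]
  structure(
    list(phase_freqs = phase_freqs, amp_freqs = amp_freqs, mi = mi,
         phase_bandwidth = phase_bw, amp_bandwidth = amp_bw,
         n_bins = n_bins,
         peak = c(phase_hz = phase_freqs[pk[1]], amp_hz = amp_freqs[pk[2]])),
    class = "comodulogram"
  )
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf(
    "<comodulogram> %d x %d grid, peak MI = %.4g at (%g Hz phase, %g Hz amplitude)\n",
    length(x$phase_freqs), length(x$amp_freqs), max(x$mi),
    x$peak["phase_hz"], x$peak["amp_hz"]))
  invisible(x)
}

#' Surrogate null distribution for the modulation index
#'
#' Recomputes the modulation index after circularly time-shifting the
#' amplitude series by seeded uniform random offsets of at least
#' `min_shift_s` seconds, destroying phase-amplitude alignment while
#' preserving both marginals. Provides an empirical null against which an
#' observed MI can be compared.
#'
#' @inheritParams phase_amplitude_distribution
#' @param n_surrogates number of shifted recomputations (>= 1).
#' @param seed integer RNG seed.
#' @param min_shift_s minimum circular shift in seconds (default 1).
#' @return An object of class `surrogate_null`: `mi` (length
#'   `n_surrogates`), `observed`, `p_value` (one-sided, with the +1
#'   correction), `seed`.
#' @export
surrogate_null <- function(phase, amplitude, n_surrogates = 200, seed = 1L,
                           n_bins = 18, edge_trim_s = 1, min_shift_s = 1) {
  stopifnot(inherits(phase, "analytic_signal"),
            inherits(amplitude, "analytic_signal"))
  n_surrogates <- as.integer(n_surrogates)
  if (n_surrogates < 1L) stop("`n_surrogates` must be >= 1", call. = FALSE)
  n <- amplitude$n_samples
  min_shift <- as.integer(round(min_shift_s * amplitude$fs))
  if (n <= 2L * min_shift) {
    stop("signal shorter than twice the minimum shift", call. = FALSE)
  }
  observed <- modulation_index(phase, amplitude, n_bins = n_bins,
                               edge_trim_s = edge_trim_s)$mi
  shifts <- with_seed(seed, sample(min_shift:(n - min_shift), n_surrogates,
                                   replace = TRUE))
  mis <- vapply(shifts, function(s) {
    shifted <- amplitude
    shifted$amplitude <- c(amplitude$amplitude[(s + 1L):n],
                           amplitude$amplitude[1:s])
    modulation_index(phase, shifted, n_bins = n_bins,
                     edge_trim_s = edge_trim_s)$mi
  }, numeric(1))
  structure(
    list(mi = mis, observed = observed,
         p_value = (sum(mis >= observed) + 1) / (n_surrogates + 1),
         seed = seed),
    class = "surrogate_null"
  )
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf(
    "<surrogate_null> observed MI = %.4g vs %d surrogates (95th pct %.4g), p = %.4g\n",
    x$observed, length(x$mi), quantile(x$mi, 0.95), x$p_value))
  invisible(x)
}
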