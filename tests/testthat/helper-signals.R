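# shared fixture builders: all synthetic, constructed in code

withr_like_tempdir <- function() {
  d <- tempfile("gf_test_")
  dir.create(d)
  d
}

# pure sinusoid as an lfp_signal; t runs over (0, duration_s]
sine_signal <- function(freq, duration_s = 2, fs = 1000, amp = 1, phase = 0) {
  t <- seq_len(round(duration_s * fs)) / fs
  lfp_signal(amp * sin(2 * pi * freq * t + phase), fs = fs)
}

white_noise_signal <- function(n, fs = 1000, sd = 1, seed = 1) {
  lfp_signal(gammaflicker:::with_seed(seed, rnorm(n, 0, sd)), fs = fs)
}

# independent periodogram oracle (one-sided density, units^2/Hz)
periodogram_oracle <- function(x, fs, nfft = NULL) {
  n <- length(x)
  if (is.null(nfft)) nfft <- 2^ceiling(log2(n))
  J <- fft(c(x, numeric(nfft - n)))
  half <- nfft %/% 2
  p <- Mod(J[1:(half + 1)])^2 / (n * fs)
  if (half > 1) p[2:half] <- 2 * p[2:half]
  list(freqs = (0:half) * fs / nfft, power = p)
}

# double-exponential evoked waveform on a ms grid (unit peak, 1 ms delay)
dexp_wave <- function(t_ms, tau_rise = 1, tau_decay = 8, delay_ms = 1) {
  u <- t_ms - delay_ms
  k <- ifelse(u > 0, exp(-u / tau_decay) - exp(-u / tau_rise), 0)
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  k / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
}

# brute-force modulation index oracle: independent binning + KL code path
mi_oracle <- function(ph, am, n_bins = 18, fs = 1000, trim_s = 1) {
  k <- round(trim_s * fs)
  idx <- (k + 1):(length(ph) - k)
  ph <- ph[idx]
  am <- am[idx]
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  b <- cut(ph, breaks = edges, include.lowest = TRUE, labels = FALSE)
  means <- vapply(split(am, factor(b, levels = 1:n_bins)), mean, numeric(1))
  p <- means / sum(means)
  sum(p * log(p / (1 / n_bins))) / log(n_bins)
}
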