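#' Configuration for the synthetic fEPSP experiment generator
#'
#' A phenomenological release-probability model drives paired-pulse
#' facilitation: the first response amplitude is proportional to the
#' initial release probability `p`, and the expected second/first ratio at
#' inter-stimulus interval `D` (ms) is
#' \deqn{R(D) = \frac{p + g (1 - p) e^{-D/\tau}}{p}}
#' with facilitation gain `g` and time constant `tau` -- facilitation is
#' inversely related to `p`. Waveforms are double-exponential fEPSPs
#' (rise 1 ms, decay 8 ms, 1 ms synaptic delay) with multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param protocol `"ppr"`, `"io"`, or `"ltp"` (tetanus variants
#'   `"ltp_nmdar"` -- 100 Hz, 1 s -- and `"ltp_lvgcc"` -- 4 x 200 Hz,
#'   0.5 s, under D-APV -- differ only in recorded metadata).
#' @param release_p initial release probability, in (0, 1).
#' @param facilitation_tau_ms facilitation time constant (default 60 ms).
#' @param facilitation_gain facilitation gain `g` (default 0.5).
#' @param ltp_step_percent post-tetanus plateau as percent of baseline
#'   (default 150).
#' @param noise_cv multiplicative sweep noise CV (default 0.05).
#' @param isis_ms paired-pulse intervals (default 20--200 ms series).
#' @param intensities_mA input-output intensity grid (default 0.1--0.6).
#' @param io_midpoint_mA,io_scale_mA sigmoid midpoint and steepness of the
#'   synthetic input-output relation.
#' @param fs sweep sampling rate, Hz (default 10000).
#' @param tetanus_min,total_min LTP protocol timing (tetanus at 30 min,
#'   90 min total, one sweep per 30 s).
#' @param n_sweeps_per_level replicate sweeps per intensity / ISI.
#' @param seed integer RNG seed.
#' @return An object of class `fepsp_sim_config`.
#' @export
fepsp_sim_config <- function(protocol = c("ppr", "io", "ltp", "ltp_nmdar",
                                          "ltp_lvgcc"),
                             release_p = 0.3, facilitation_tau_ms = 60,
                             facilitation_gain = 0.5,
                             ltp_step_percent = 150, noise_cv = 0.05,
                             isis_ms = c(20, 40, 60, 80, 100, 200),
                             intensities_mA = seq(0.1, 0.6, by = 0.1),
                             io_midpoint_mA = 0.28, io_scale_mA = 0.05,
                             fs = 10000, tetanus_min = 30, total_min = 90,
                             n_sweeps_per_level = 3, seed = 1L) {
  protocol <- match.arg(protocol)
  if (release_p <= 0 || release_p >= 1) {
    stop("`release_p` must be in (0, 1)", call. = FALSE)
  }
  if (length(isis_ms) < 1L || length(intensities_mA) < 1L) {
    stop("`isis_ms` and `intensities_mA` must be nonempty", call. = FALSE)
  }
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  structure(
    list(protocol = protocol, release_p = release_p,
         facilitation_tau_ms = facilitation_tau_ms,
         facilitation_gain = facilitation_gain,
         ltp_step_percent = ltp_step_percent, noise_cv = noise_cv,
         isis_ms = isis_ms, intensities_mA = intensities_mA,
         io_midpoint_mA = io_midpoint_mA, io_scale_mA = io_scale_mA,
         fs = fs, tetanus_min = tetanus_min, total_min = total_min,
         n_sweeps_per_level = as.integer(n_sweeps_per_level),
         seed = as.integer(seed)),
    class = "fepsp_sim_config"
  )
}

#' Expected paired-pulse ratio of the release model
#'
#' Closed form `100 * (p + g (1 - p) exp(-isi/tau)) / p` (percent),
#' clipped at 0; monotone decreasing in `p`.
#'
#' @param release_p initial release probability.
#' @param isi_ms inter-stimulus interval (ms); vectorized.
#' @param facilitation_gain,facilitation_tau_ms model parameters.
#' @return expected PPR in percent.
#' @export
expected_ppr <- function(release_p, isi_ms, facilitation_gain = 0.5,
                         facilitation_tau_ms = 60) {
  r <- (release_p + facilitation_gain * (1 - release_p) *
          exp(-isi_ms / facilitation_tau_ms)) / release_p
  100 * pmax(r, 0)
}

# double-exponential fEPSP kernel on a ms grid, unit peak, with a
# synaptic delay before onset
fepsp_kernel <- function(t_ms, tau_rise = 1, tau_decay = 8, delay_ms = 1) {
  u <- t_ms - delay_ms
  k <- ifelse(u > 0, exp(-u / tau_decay) - exp(-u / tau_rise), 0)
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  k / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
}

# one evoked sweep: negative-going responses of given amplitudes at the
# given stimulus times, plus a brief biphasic stimulus artifact
build_sweep <- function(fs, dur_s, stim_s, amps, noise_cv, intensity = NA,
                        label = NA, artifact_amp = 0.5, noise_floor = 0) {
  n <- as.integer(round(dur_s * fs))
  t_ms <- (seq_len(n) - 1L) / fs * 1000
  x <- numeric(n)
  for (i in seq_along(stim_s)) {
    a <- amps[i] * (1 + noise_cv * rnorm(1))
    x <- x - a * fepsp_kernel(t_ms - stim_s[i] * 1000)
    if (artifact_amp > 0) {
      i0 <- as.integer(round(stim_s[i] * fs)) + 1L
      w <- max(2L, as.integer(round(0.4e-3 * fs)))
      idx <- i0:min(n, i0 + w - 1L)
      x[idx] <- x[idx] + artifact_amp * sin(pi * seq_along(idx) / length(idx))
    }
  }
  if (noise_floor > 0) x <- x + noise_floor * rnorm(n)
  sweep_record(lfp_signal(x, fs), stim_times = stim_s,
               intensity = intensity, label = label)
}

#' Simulate an evoked fEPSP experiment
#'
#' Generates the sweep series for the configured protocol:
#' \itemize{
#' \item `"ppr"`: one two-pulse sweep set per ISI; second-response
#'   amplitude follows the closed-form [expected_ppr()].
#' \item `"io"`: `n_sweeps_per_level` sweeps per intensity with amplitude
#'   following a logistic input-output relation whose midpoint is
#'   `io_midpoint_mA` (the half-maximal intensity ground truth).
#' \item `"ltp"` (and variants): one sweep per 30 s for `total_min`
#'   minutes, amplitudes stepping from baseline to
#'   `ltp_step_percent` percent at the tetanus.
#' }
#'
#' @param config an [fepsp_sim_config()].
#' @return list with `sweeps` (list of [sweep_record()]s), `truth`
#'   (closed-form expectations sufficient to predict every measured
#'   output), and for the LTP protocol `sweep_times_min`.
#' @export
simulate_fepsp_experiment <- function(config) {
  stopifnot(inherits(config, "fepsp_sim_config"))
  p <- config$release_p
  base_amp <- p               # first-pulse amplitude proportional to p

  with_seed(config$seed, {
    if (config$protocol == "ppr") {
      sweeps <- list()
      for (isi in config$isis_ms) {
        r <- expected_ppr(p, isi, config$facilitation_gain,
                          config$facilitation_tau_ms) / 100
        for (s in seq_len(config$n_sweeps_per_level)) {
          dur <- (50 + isi + 120) / 1000
          sweeps[[length(sweeps) + 1L]] <- build_sweep(
            config$fs, dur, stim_s = c(0.05, 0.05 + isi / 1000),
            amps = c(base_amp, base_amp * r), noise_cv = config$noise_cv,
            label = sprintf("isi_%g", isi))
        }
      }
      truth <- list(release_p = p,
                    expected_ppr_percent = expected_ppr(
                      p, config$isis_ms, config$facilitation_gain,
                      config$facilitation_tau_ms),
                    isis_ms = config$isis_ms)
      list(sweeps = sweeps, truth = truth)
    } else if (config$protocol == "io") {
      amp_of <- function(i) {
        1 / (1 + exp(-(i - config$io_midpoint_mA) / config$io_scale_mA))
      }
      sweeps <- list()
      for (i_ma in config$intensities_mA) {
        for (s in seq_len(config$n_sweeps_per_level)) {
          sweeps[[length(sweeps) + 1L]] <- build_sweep(
            config$fs, 0.12, stim_s = 0.05, amps = amp_of(i_ma),
            noise_cv = config$noise_cv, intensity = i_ma)
        }
      }
      truth <- list(half_max_intensity_mA = config$io_midpoint_mA,
                    amplitudes = amp_of(config$intensities_mA))
      list(sweeps = sweeps, truth = truth)
    } else {
      times_min <- seq(0, config$total_min, by = 0.5)
      amps <- ifelse(times_min < config$tetanus_min, base_amp,
                     base_amp * config$ltp_step_percent / 100)
      sweeps <- lapply(seq_along(times_min), function(i) {
        build_sweep(config$fs, 0.12, stim_s = 0.05, amps = amps[i],
                    noise_cv = config$noise_cv, label = config$protocol)
      })
      truth <- list(ltp_step_percent = config$ltp_step_percent,
                    tetanus_min = config$tetanus_min,
                    tetanus_protocol = switch(config$protocol,
                      ltp_nmdar = "100 Hz, 1 s",
                      ltp_lvgcc = "4 trains of 200 Hz, 0.5 s (D-APV 50 uM)",
                      "100 Hz, 1 s"))
      list(sweeps = sweeps, truth = truth, sweep_times_min = times_min)
    }
  })
}
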