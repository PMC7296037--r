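#' Configuration for the synthetic LFP generator
#'
#' Defines a CA1-like local field potential: a theta sinusoid whose phase
#' modulates the envelope of a low-gamma carrier (tunable coupling depth),
#' an independent high-gamma component, 1/f background noise, an optional
#' entrained component at a flicker frequency (or an arrhythmic pulse
#' train of matched mean rate), and a condition preset: `"2vo"`
#' multiplies the low-gamma amplitude and the coupling depth by
#' `attenuation` relative to `"sham"`.
#'
#' Default amplitudes are in nominal microvolts and follow the usual
#' hippocampal LFP hierarchy (theta larger than gamma): theta 50, low
#' gamma 20, high gamma 8, 1/f noise 10.
#'
#' @param fs sampling rate, Hz (default 1000).
#' @param duration_s recording length, s (default 120).
#' @param theta_hz theta frequency (default 8; within 4--12).
#' @param low_gamma_hz low-gamma carrier frequency (default 40).
#' @param high_gamma_hz high-gamma frequency (default 100).
#' @param theta_amp,gamma_amp,high_gamma_amp component amplitudes.
#' @param coupling_depth theta to low-gamma phase-amplitude coupling depth
#'   in [0, 1]: 0 = constant gamma envelope, 1 = envelope fully
#'   concentrated at the theta peak phase.
#' @param entrain_hz optional flicker frequency in Hz (10/30/40/50/80
#'   in the study design), `"arrhythmic"` for a jittered pulse train with
#'   40 Hz mean rate, or `NULL` for no photic drive.
#' @param entrain_amp amplitude of the entrained component (default 60:
#'   a strong driven response that dominates the spectrum).
#' @param theta_phase_jitter phase-diffusion rate of the theta oscillator
#'   in rad^2/s (default 1): the theta phase performs a random walk around
#'   its linear trend, giving the finite line width and decorrelation time
#'   of biological theta (about 1 s at the default). Set 0 for a strictly
#'   periodic oscillator.
#' @param noise_exponent 1/f spectral slope of the background (default 1).
#' @param noise_amp background noise amplitude (SD, default 10).
#' @param condition `"sham"` or `"2vo"`.
#' @param attenuation multiplicative factor applied to low-gamma amplitude
#'   and coupling depth under `"2vo"` (default 0.6).
#' @param seed integer RNG seed.
#' @return An object of class `lfp_sim_config`.
#' @export
lfp_sim_config <- function(fs = 1000, duration_s = 120, theta_hz = 8,
                           low_gamma_hz = 40, high_gamma_hz = 100,
                           theta_amp = 50, gamma_amp = 20,
                           high_gamma_amp = 8, coupling_depth = 0.6,
                           theta_phase_jitter = 1,
                           entrain_hz = NULL, entrain_amp = 60,
                           noise_exponent = 1, noise_amp = 10,
                           condition = c("sham", "2vo"),
                           attenuation = 0.6, seed = 1L) {
  condition <- match.arg(condition)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  for (nm in c("theta_amp", "gamma_amp", "high_gamma_amp", "noise_amp",
               "entrain_amp")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm)
    if (v < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
  }
  if (coupling_depth < 0 || coupling_depth > 1) {
    stop("`coupling_depth` must be in [0, 1]", call. = FALSE)
  }
  if (theta_phase_jitter < 0) {
    stop("`theta_phase_jitter` must be >= 0", call. = FALSE)
  }
  fmax <- max(theta_hz, low_gamma_hz, high_gamma_hz,
              if (is.numeric(entrain_hz)) entrain_hz else 0)
  if (fs <= 2 * fmax) {
    stop("sampling rate must exceed twice the highest component frequency",
         call. = FALSE)
  }
  structure(
    list(fs = fs, duration_s = duration_s, theta_hz = theta_hz,
         low_gamma_hz = low_gamma_hz, high_gamma_hz = high_gamma_hz,
         theta_amp = theta_amp, gamma_amp = gamma_amp,
         high_gamma_amp = high_gamma_amp, coupling_depth = coupling_depth,
         theta_phase_jitter = theta_phase_jitter,
         entrain_hz = entrain_hz, entrain_amp = entrain_amp,
         noise_exponent = noise_exponent, noise_amp = noise_amp,
         condition = condition, attenuation = attenuation,
         seed = as.integer(seed)),
    class = "lfp_sim_config"
  )
}

# 1/f^alpha Gaussian noise with unit SD, by spectral shaping
one_over_f_noise <- function(n, alpha) {
  white <- rnorm(n)
  if (alpha == 0) return(white)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))            # avoid the DC singularity
  f <- pmin(f, n - f + 1)              # symmetric in positive/negative freq
  shape <- f^(-alpha / 2)
  shape[1] <- 0                        # remove DC
  y <- Re(fft(X * shape, inverse = TRUE)) / n
  y / sd(y)
}

# zero-trend phase random walk with diffusion rate `rate` rad^2/s
theta_phase_walk <- function(n, fs, rate) {
  if (rate <= 0) return(numeric(n))
  cumsum(rnorm(n, 0, sqrt(rate / fs)))
}

# jittered pulse train: half-sine pulses, mean rate matched to rate_hz
arrhythmic_drive <- function(n, fs, rate_hz, amp, jitter_frac = 0.5) {
  y <- numeric(n)
  pulse_len <- max(3L, as.integer(round(fs / rate_hz / 2)))
  pulse <- amp * sin(pi * seq_len(pulse_len) / (pulse_len + 1))
  t <- 0
  mean_gap <- 1 / rate_hz
  while (TRUE) {
    gap <- mean_gap * (1 + jitter_frac * (2 * runif(1) - 1))
    t <- t + gap
    i0 <- as.integer(round(t * fs)) + 1L
    if (i0 + pulse_len - 1L > n) break
    y[i0:(i0 + pulse_len - 1L)] <- y[i0:(i0 + pulse_len - 1L)] + pulse
  }
  y - mean(y)
}

#' Simulate a CA1-like local field potential
#'
#' Generates the LFP defined by an [lfp_sim_config()]: theta sinusoid plus
#' a low-gamma carrier whose envelope follows
#' `gamma_amp * (1 - d + d * (1 + cos(theta_phase)) / 2)` at coupling
#' depth `d`, plus high gamma, 1/f noise, and the optional photic drive.
#' Under the `"2vo"` condition the low-gamma amplitude and coupling depth
#' are both multiplied by `attenuation`. Fully determined by the seed.
#'
#' @param config an [lfp_sim_config()].
#' @return An object of class `session_sim`: `lfp` (an [lfp_signal()]),
#'   `event_times` (empty here; see [simulate_session()]), `labels`, and
#'   `truth` (the config plus the realized component amplitudes, coupling
#'   depth and phases).
#' @export
simulate_lfp <- function(config) {
  stopifnot(inherits(config, "lfp_sim_config"))
  n <- as.integer(round(config$duration_s * config$fs))
  t <- (seq_len(n) - 1L) / config$fs

  g_amp <- config$gamma_amp
  depth <- config$coupling_depth
  if (config$condition == "2vo") {
    g_amp <- g_amp * config$attenuation
    depth <- depth * config$attenuation
  }

  sim <- with_seed(config$seed, {
    ph_theta <- runif(1, 0, 2 * pi)
    ph_hg <- runif(1, 0, 2 * pi)
    ph_lg <- runif(1, 0, 2 * pi)
    theta_phase <- 2 * pi * config$theta_hz * t + ph_theta +
      theta_phase_walk(n, config$fs, config$theta_phase_jitter)
    theta <- config$theta_amp * sin(theta_phase)
    envelope <- g_amp * (1 - depth + depth * (1 + cos(theta_phase)) / 2)
    low_gamma <- envelope * sin(2 * pi * config$low_gamma_hz * t + ph_lg)
    high_gamma <- config$high_gamma_amp *
      sin(2 * pi * config$high_gamma_hz * t + ph_hg)
    noise <- config$noise_amp * one_over_f_noise(n, config$noise_exponent)
    drive <- if (is.null(config$entrain_hz)) {
      numeric(n)
    } else if (identical(config$entrain_hz, "arrhythmic")) {
      arrhythmic_drive(n, config$fs, 40, config$entrain_amp)
    } else {
      config$entrain_amp * sin(2 * pi * config$entrain_hz * t)
    }
    list(x = theta + low_gamma + high_gamma + noise + drive,
         phases = c(theta = ph_theta, low_gamma = ph_lg, high_gamma = ph_hg))
  })

  truth <- c(unclass(config),
             list(realized_gamma_amp = g_amp, realized_depth = depth,
                  phases = sim$phases))
  structure(
    list(lfp = lfp_signal(sim$x, fs = config$fs),
         event_times = numeric(0), labels = character(0), truth = truth),
    class = "session_sim"
  )
}

#' @export
print.session_sim <- function(x, ...) {
  cat(sprintf("<session_sim> %s condition, %.0f s @ %g Hz, %d event(s)\n",
              x$truth$condition, duration(x$lfp), x$lfp$fs,
              length(x$event_times)))
  invisible(x)
}

#' Simulate a novel-object session with approach/exploration epochs
#'
#' Adds behavioral structure to [simulate_lfp()]: `n_events`
#' exploration-onset events are placed uniformly (seeded), and during each
#' 2-s exploration epoch the low-gamma envelope is multiplied by a boost
#' factor relative to the preceding 2-s approach epoch -- sham default 2x
#' on amplitude (so ~4x on band power), 2vo default 1.2x. `truth` records
#' the exact factors so expected analysis outputs are computable.
#'
#' @param config an [lfp_sim_config()].
#' @param n_events number of approach-to-exploration transitions.
#' @param epoch_s epoch duration on each side of the event (default 2 s).
#' @param boost low-gamma amplitude boost during exploration; default 2
#'   for sham, 1.2 for 2vo.
#' @return A `session_sim` whose `event_times` are the exploration onsets
#'   and whose `labels` tag each event; `truth$boost` holds the factor.
#' @export
simulate_session <- function(config, n_events = 10, epoch_s = 2,
                             boost = NULL) {
  stopifnot(inherits(config, "lfp_sim_config"))
  if (is.null(boost)) {
    boost <- if (config$condition == "2vo") 1.2 else 2.0
  }
  n <- as.integer(round(config$duration_s * config$fs))
  t <- (seq_len(n) - 1L) / config$fs
  need <- n_events * 2.5 * epoch_s
  if (config$duration_s < need) {
    stop(sprintf("duration %g s too short for %d events (need >= %g s)",
                 config$duration_s, n_events, need), call. = FALSE)
  }

  g_amp <- config$gamma_amp
  depth <- config$coupling_depth
  if (config$condition == "2vo") {
    g_amp <- g_amp * config$attenuation
    depth <- depth * config$attenuation
  }

  sim <- with_seed(config$seed, {
    # event placement: jittered regular grid, each event needs
    # [-epoch_s, +epoch_s] of clear support
    slot <- (config$duration_s - 2 * epoch_s) / n_events
    events <- epoch_s + (seq_len(n_events) - 1) * slot +
      runif(n_events, 0.1 * slot, 0.9 * slot)

    ph_theta <- runif(1, 0, 2 * pi)
    ph_hg <- runif(1, 0, 2 * pi)
    ph_lg <- runif(1, 0, 2 * pi)
    theta_phase <- 2 * pi * config$theta_hz * t + ph_theta +
      theta_phase_walk(n, config$fs, config$theta_phase_jitter)
    theta <- config$theta_amp * sin(theta_phase)

    gain <- rep(1, n)
    for (ev in events) {
      i0 <- as.integer(round(ev * config$fs)) + 1L
      i1 <- min(n, i0 + as.integer(round(epoch_s * config$fs)) - 1L)
      gain[i0:i1] <- boost
    }
    envelope <- g_amp * gain *
      (1 - depth + depth * (1 + cos(theta_phase)) / 2)
    low_gamma <- envelope * sin(2 * pi * config$low_gamma_hz * t + ph_lg)
    high_gamma <- config$high_gamma_amp *
      sin(2 * pi * config$high_gamma_hz * t + ph_hg)
    noise <- config$noise_amp * one_over_f_noise(n, config$noise_exponent)
    list(x = theta + low_gamma + high_gamma + noise, events = events)
  })

  truth <- c(unclass(config),
             list(realized_gamma_amp = g_amp, realized_depth = depth,
                  boost = boost, epoch_s = epoch_s,
                  expected_low_gamma_power_ratio = boost^2))
  structure(
    list(lfp = lfp_signal(sim$x, fs = config$fs),
         event_times = sim$events,
         labels = rep("exploration_onset", n_events), truth = truth),
    class = "session_sim"
  )
}

#' Exploration/approach PSD band ratio for a simulated session
#'
#' For each event, the multitaper PSD of the `epoch_s`-second epoch after
#' the event (exploration) and before it (approach) are computed;
#' ratios are formed per epoch and averaged (`mode = "per_epoch"`,
#' default) or the PSDs are averaged first and one ratio taken
#' (`mode = "averaged"`).
#'
#' @param session a `session_sim` from [simulate_session()].
#' @param band frequency band for the ratio.
#' @param mode `"per_epoch"` or `"averaged"`.
#' @param nw taper time-half-bandwidth (default 3).
#' @return scalar ratio.
#' @export
session_psd_ratio <- function(session, band = band_preset("low_gamma"),
                              mode = c("per_epoch", "averaged"), nw = 3) {
  stopifnot(inherits(session, "session_sim"))
  mode <- match.arg(mode)
  if (length(session$event_times) == 0L) {
    stop("session has no events", call. = FALSE)
  }
  fs <- session$lfp$fs
  x <- session$lfp$samples
  len <- as.integer(round(session$truth$epoch_s * fs))
  tapers <- make_slepian_tapers(len, nw)

  pair_psds <- lapply(session$event_times, function(ev) {
    i_ev <- as.integer(round(ev * fs)) + 1L
    expl <- lfp_signal(x[i_ev:(i_ev + len - 1L)], fs)
    appr <- lfp_signal(x[(i_ev - len):(i_ev - 1L)], fs)
    list(expl = multitaper_psd(expl, tapers),
         appr = multitaper_psd(appr, tapers))
  })
  if (mode == "per_epoch") {
    mean(vapply(pair_psds, function(p) {
      psd_band_ratio(p$expl, p$appr, band)
    }, numeric(1)))
  } else {
    avg <- function(which) {
      psds <- lapply(pair_psds, `[[`, which)
      out <- psds[[1]]
      out$power <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
      out
    }
    psd_band_ratio(avg("expl"), avg("appr"), band)
  }
}
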