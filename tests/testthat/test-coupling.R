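test_that("analytic signal of a pure sine has constant envelope and linear phase", {
  sig <- sine_signal(8, duration_s = 10, fs = 1000, amp = 2)
  as8 <- analytic_signal(sig, "theta")
  core <- 1001:9000                      # trim 1 s edges
  amp <- as8$amplitude[core]
  expect_lt((max(amp) - min(amp)) / mean(amp), 0.02)
  # phase advances 2*pi*8 rad per second
  dph <- diff(as8$phase[core])
  dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
  rate <- mean(dph) * 1000 / (2 * pi)
  expect_equal(rate, 8, tolerance = 0.01)
})

test_that("the envelope of an AM carrier recovers the modulator", {
  fs <- 1000
  t <- seq_len(20 * fs) / fs
  modulator <- 1 + 0.8 * sin(2 * pi * 1.5 * t)
  x <- modulator * sin(2 * pi * 40 * t)
  as40 <- analytic_signal(lfp_signal(x, fs), "low_gamma")
  core <- (2 * fs):(18 * fs)
  expect_gt(cor(as40$amplitude[core], modulator[core]), 0.99)
})

test_that("bands at or above Nyquist are rejected", {
  sig <- sine_signal(8, duration_s = 5, fs = 200)
  expect_error(analytic_signal(sig, c(80, 110)), "Nyquist")
  expect_equal(band_preset("theta")$f_lo, 4)
  expect_equal(band_preset("theta")$f_hi, 12)
})

test_that("modulation index vanishes for a phase-independent envelope", {
  fs <- 1000
  t <- seq_len(90 * fs) / fs             # 90 s -> n >= 60000 after trim
  sig <- lfp_signal(sin(2 * pi * 8 * t) + 0.5 * sin(2 * pi * 40 * t), fs)
  mi <- modulation_index(analytic_signal(sig, "theta"),
                         analytic_signal(sig, "low_gamma"))
  expect_lt(mi$mi, 0.001)
  expect_gte(mi$mi, 0)
})

test_that("modulation index equals an independent histogram/KL oracle", {
  fs <- 1000
  t <- seq_len(120 * fs) / fs
  phase <- 2 * pi * 8 * t
  envelope <- (1 + cos(phase)) / 2       # full-depth coupling
  x <- sin(phase) + envelope * sin(2 * pi * 40 * t)
  sig <- lfp_signal(x, fs)
  ph <- analytic_signal(sig, "theta")
  am <- analytic_signal(sig, "low_gamma")
  mi <- modulation_index(ph, am, n_bins = 18)
  oracle <- mi_oracle(ph$phase, am$amplitude, n_bins = 18, fs = fs)
  expect_equal(mi$mi, oracle, tolerance = 1e-10)
  expect_gte(mi$mi, 0)
  expect_lte(mi$mi, 1)
})

test_that("modulation index increases with coupling depth and falls with length at depth 0", {
  mis <- vapply(c(0, 0.25, 0.5, 1), function(d) {
    sim <- simulate_lfp(lfp_sim_config(duration_s = 40, coupling_depth = d,
                                       seed = 8))
    modulation_index(analytic_signal(sim$lfp, "theta"),
                     analytic_signal(sim$lfp, "low_gamma"))$mi
  }, numeric(1))
  expect_true(all(diff(mis) > 0))

  mi_len <- vapply(c(20, 60, 180), function(dur) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_lfp(lfp_sim_config(duration_s = dur,
                                         coupling_depth = 0,
                                         seed = 12 + s))
      modulation_index(analytic_signal(sim$lfp, "theta"),
                       analytic_signal(sim$lfp, "low_gamma"))$mi
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mi_len) < 0))
})

test_that("modulation index is invariant to amplitude scaling and phase offset", {
  sim <- simulate_lfp(lfp_sim_config(duration_s = 30, coupling_depth = 0.8,
                                     seed = 14))
  ph <- analytic_signal(sim$lfp, "theta")
  am <- analytic_signal(sim$lfp, "low_gamma")
  mi0 <- modulation_index(ph, am)$mi

  am_scaled <- am
  am_scaled$amplitude <- am$amplitude * 37.5
  expect_equal(modulation_index(ph, am_scaled)$mi, mi0, tolerance = 1e-12)

  ph_shift <- ph
  ph_shift$phase <- ((ph$phase + 1.1 + pi) %% (2 * pi)) - pi
  mi_shift <- modulation_index(ph_shift, am)$mi
  # the distribution rotates by a constant offset; KL is nearly unchanged
  # (up to binning granularity)
  expect_equal(mi_shift, mi0, tolerance = 0.1 * mi0 + 1e-4)
})

test_that("the phase-amplitude distribution is a proper distribution", {
  sim <- simulate_lfp(lfp_sim_config(duration_s = 30, seed = 15))
  pad <- phase_amplitude_distribution(analytic_signal(sim$lfp, "theta"),
                                      analytic_signal(sim$lfp, "low_gamma"))
  expect_equal(sum(pad$normalized), 1, tolerance = 1e-12)
  expect_true(all(pad$normalized >= 0))
  expect_equal(pad$n_bins, 18L)
  expect_error(phase_amplitude_distribution(
    analytic_signal(sim$lfp, "theta"),
    analytic_signal(sim$lfp, "low_gamma"), n_bins = 2), ">= 4")
})

test_that("the comodulogram localizes an injected (8, 40) coupling", {
  sim <- simulate_lfp(lfp_sim_config(duration_s = 60, coupling_depth = 1,
                                     seed = 7))
  cm <- comodulogram(sim$lfp)
  expect_lte(abs(cm$peak["phase_hz"] - 8), 2)
  expect_lte(abs(cm$peak["amp_hz"] - 40), 5)
  expect_true(all(cm$mi >= 0))
  expect_equal(dim(cm$mi), c(length(cm$phase_freqs), length(cm$amp_freqs)))
  # the default phase axis spans the 4-12 Hz theta band
  expect_true(all(4:12 %in% cm$phase_freqs))
})

test_that("white noise shows no coupling above the surrogate null", {
  wn <- white_noise_signal(30000, seed = 31)
  cm <- comodulogram(wn)
  # null of the grid MAXIMUM: circularly shift every amplitude envelope by
  # the same random offset and rescan the full grid
  fs <- wn$fs
  phase_as <- lapply(cm$phase_freqs, function(fp) {
    analytic_signal(wn, c(max(fp - 1, 0.5), fp + 1))
  })
  amp_as <- lapply(cm$amp_freqs, function(fa) {
    analytic_signal(wn, c(fa - 10, fa + 10))
  })
  n <- length(wn$samples)
  shifts <- gammaflicker:::with_seed(2, sample(fs:(n - fs), 50))
  null_max <- vapply(shifts, function(s) {
    max(vapply(phase_as, function(ph) {
      max(vapply(amp_as, function(am) {
        am2 <- am
        am2$amplitude <- c(am$amplitude[(s + 1):n], am$amplitude[1:s])
        modulation_index(ph, am2)$mi
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_lte(max(cm$mi), quantile(null_max, 0.95))
})

test_that("surrogate null separates coupled from uncoupled signals", {
  sim <- simulate_lfp(lfp_sim_config(duration_s = 60, coupling_depth = 1,
                                     seed = 7))
  ph <- analytic_signal(sim$lfp, "theta")
  am <- analytic_signal(sim$lfp, "low_gamma")
  null <- surrogate_null(ph, am, n_surrogates = 200, seed = 1)
  expect_gt(null$observed, max(null$mi))
  expect_lt(null$p_value, 0.01)

  # determinism
  n1 <- surrogate_null(ph, am, n_surrogates = 1, seed = 99)
  n2 <- surrogate_null(ph, am, n_surrogates = 1, seed = 99)
  expect_identical(n1$mi, n2$mi)
})

test_that("uncoupled observed MI is calibrated against its surrogate null", {
  hits <- 0L
  reps <- 20L
  for (i in seq_len(reps)) {
    s0 <- simulate_lfp(lfp_sim_config(duration_s = 30, coupling_depth = 0,
                                      seed = 100 + i))
    ph <- analytic_signal(s0$lfp, "theta")
    am <- analytic_signal(s0$lfp, "low_gamma")
    sn <- surrogate_null(ph, am, n_surrogates = 99, seed = i)
    q <- quantile(sn$mi, c(0.025, 0.975))
    hits <- hits + (sn$observed >= q[1] && sn$observed <= q[2])
  }
  expect_gte(hits, 0.9 * reps)
})
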