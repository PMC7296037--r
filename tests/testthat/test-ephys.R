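# helper: sweep whose response is a linear ramp 0 -> -A over ramp_ms
ramp_sweep <- function(A = 1, ramp_ms = 10, fs = 10000, stim_s = 0.02,
                       dur_s = 0.1, intensity = NA) {
  n <- round(dur_s * fs)
  t_ms <- ((seq_len(n) - 1) / fs - stim_s) * 1000
  x <- ifelse(t_ms <= 0, 0, ifelse(t_ms <= ramp_ms, -A * t_ms / ramp_ms, -A))
  sweep_record(lfp_signal(x, fs), stim_times = stim_s, intensity = intensity)
}

dexp_sweep <- function(amps, stim_s, fs = 10000, dur_s = NULL, noise_sd = 0,
                       seed = 1) {
  if (is.null(dur_s)) dur_s <- max(stim_s) + 0.08
  n <- round(dur_s * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  x <- numeric(n)
  for (i in seq_along(stim_s)) {
    x <- x - amps[i] * dexp_wave(t_ms - stim_s[i] * 1000)
  }
  if (noise_sd > 0) {
    x <- x + gammaflicker:::with_seed(seed, rnorm(n, 0, noise_sd))
  }
  sweep_record(lfp_signal(x, fs), stim_times = stim_s)
}

test_that("a linear ramp response yields exact slope and amplitude", {
  f <- fepsp_features(ramp_sweep(A = 1, ramp_ms = 10))
  expect_equal(f$slope, -0.1, tolerance = 1e-12)
  expect_equal(f$amplitude, 1, tolerance = 1e-12)
  expect_equal(f$direction, -1)
})

test_that("double-exponential responses match a dense oracle", {
  fs <- 10000
  f <- fepsp_features(dexp_sweep(0.8, 0.02, fs = fs))
  expect_equal(f$amplitude, 0.8, tolerance = 0.01)

  # dense oracle: least-squares line on a 1 MHz sampling of the same
  # 20-80% rising segment
  td <- seq(0, 10, by = 1e-3)                 # ms after stimulus
  vd <- -0.8 * dexp_wave(td)
  peak <- max(abs(vd))
  r <- abs(vd)
  i_pk <- which.max(r)
  i20 <- max(which(r[1:i_pk] < 0.2 * peak)) + 1L
  i80 <- i20 - 1L + min(which(r[i20:i_pk] >= 0.8 * peak))
  seg <- i20:i80
  oracle_slope <- unname(coef(lm(vd[seg] ~ td[seg]))[2])
  expect_equal(f$slope, oracle_slope, tolerance = 0.02)
})

test_that("a sweep with only artifact and noise raises feature-not-found", {
  fs <- 10000
  x <- gammaflicker:::with_seed(2, rnorm(fs * 0.1, 0, 0.01))
  i0 <- round(0.02 * fs)
  x[i0:(i0 + 3)] <- x[i0:(i0 + 3)] + 2          # stimulus artifact, blanked
  sw <- sweep_record(lfp_signal(x, fs), stim_times = 0.02)
  expect_error(fepsp_features(sw), "feature not found")
})

test_that("input-output curve interpolates the half-maximal intensity", {
  amps <- c(0.1, 0.25, 0.5, 0.75, 1.0)
  sweeps <- lapply(seq_along(amps), function(i) {
    ramp_sweep(A = amps[i], intensity = 0.1 * i)
  })
  io <- io_curve(sweeps)
  expect_equal(io$half_max_intensity, 0.3, tolerance = 1e-9)
  expect_equal(io$intensities, seq(0.1, 0.5, by = 0.1))

  # scaling every sweep leaves the half-max unchanged
  sweeps10 <- lapply(sweeps, function(s) {
    s$trace$samples <- 10 * s$trace$samples
    s
  })
  expect_equal(io_curve(sweeps10)$half_max_intensity, 0.3, tolerance = 1e-9)
})

test_that("the generator's sigmoid midpoint is recovered from waveforms", {
  ex <- simulate_fepsp_experiment(
    fepsp_sim_config(protocol = "io", noise_cv = 0.03, seed = 4))
  io <- io_curve(ex$sweeps)
  expect_equal(io$half_max_intensity, ex$truth$half_max_intensity_mA,
               tolerance = 0.02 / 0.28)   # within 0.02 mA of 0.28
  expect_equal(io$intensities, seq(0.1, 0.6, by = 0.1))
})

test_that("identical paired responses give PPR 100% and gain invariance holds", {
  sw <- dexp_sweep(c(0.5, 0.5), stim_s = c(0.05, 0.09))
  pr <- paired_pulse_ratio(sw)
  expect_equal(pr$ppr_percent, 100, tolerance = 0.5)
  expect_equal(pr$isi_ms, 40)

  sw2 <- sw
  sw2$trace$samples <- 7 * sw$trace$samples
  expect_equal(paired_pulse_ratio(sw2)$ppr_percent, pr$ppr_percent,
               tolerance = 1e-9)
})

test_that("measured PPR matches the release-model closed form", {
  # facilitation is inversely related to release probability
  ppr_at <- function(p) {
    ex <- simulate_fepsp_experiment(
      fepsp_sim_config(protocol = "ppr", release_p = p, noise_cv = 0,
                       isis_ms = 40, n_sweeps_per_level = 1, seed = 1))
    list(measured = ppr_curve(ex$sweeps)$ppr_percent,
         expected = ex$truth$expected_ppr_percent)
  }
  lo <- ppr_at(0.2)
  hi <- ppr_at(0.6)
  expect_equal(lo$measured, lo$expected, tolerance = 0.03)
  expect_equal(hi$measured, hi$expected, tolerance = 0.03)
  expect_gt(lo$measured, hi$measured)

  # closed form is monotone decreasing over the full range
  grid <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(expected_ppr(grid, 40)) < 0))
})

test_that("LTP magnitude is exact for flat responses and recovers a planted step", {
  ex0 <- simulate_fepsp_experiment(
    fepsp_sim_config(protocol = "ltp", ltp_step_percent = 100,
                     noise_cv = 0, seed = 1))
  lt0 <- ltp_timecourse(ex0$sweeps, tetanus_min = 30,
                        sweep_times_min = ex0$sweep_times_min)
  expect_equal(lt0$magnitude_percent, 100, tolerance = 1e-9)
  # baseline mean is 100% by construction
  in_base <- ex0$sweep_times_min < 30
  expect_equal(mean(lt0$timecourse[in_base]), 100, tolerance = 1e-9)

  ex <- simulate_fepsp_experiment(
    fepsp_sim_config(protocol = "ltp", ltp_step_percent = 150,
                     noise_cv = 0.05, seed = 2))
  lt <- ltp_timecourse(ex$sweeps, tetanus_min = 30,
                       sweep_times_min = ex$sweep_times_min)
  expect_equal(lt$magnitude_percent, 150, tolerance = 2 / 150)
  expect_equal(lt$measure_window, c(45, 60))   # default convention

  # unit invariance: scaling all sweeps leaves the time course unchanged
  scaled <- lapply(ex$sweeps, function(s) {
    s$trace$samples <- 0.013 * s$trace$samples
    s
  })
  lts <- ltp_timecourse(scaled, tetanus_min = 30,
                        sweep_times_min = ex$sweep_times_min)
  expect_equal(lts$timecourse, lt$timecourse, tolerance = 1e-9)

  # the 0-60 min alternative window is supported
  lt_alt <- ltp_timecourse(ex$sweeps, tetanus_min = 30,
                           sweep_times_min = ex$sweep_times_min,
                           measure_window = c(0, 60))
  expect_equal(lt_alt$magnitude_percent, 150, tolerance = 2 / 150)
})

test_that("sweep and window validation errors are raised", {
  sw <- dexp_sweep(c(0.5, 0.6), stim_s = c(0.05, 0.09))
  expect_error(ltp_timecourse(list(sw, sw, sw, sw), tetanus_min = 1,
                              sweep_times_min = c(0, 0.5, 1, 1.5),
                              measure_window = c(45, 60)),
               "empty measurement window")
  expect_error(paired_pulse_ratio(dexp_sweep(0.5, 0.05)), "exactly 2")
  expect_error(sweep_record(lfp_signal(rnorm(100), 10000),
                            stim_times = c(0.5)), "inside the trace")
})
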