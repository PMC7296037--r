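test_that("multitaper PSD is zero for a zero signal and peaks at a sine frequency", {
  zero <- lfp_signal(numeric(2000), 1000)
  expect_equal(max(multitaper_psd(zero, make_slepian_tapers(2000, 3))$power), 0)

  sig <- sine_signal(40, duration_s = 2, fs = 1000)
  psd <- multitaper_psd(sig, nw = 3)
  # oracle: single-taper periodogram peak location
  oracle <- periodogram_oracle(sig$samples, 1000)
  f_oracle <- oracle$freqs[which.max(oracle$power)]
  expect_equal(psd$freqs[which.max(psd$power)], f_oracle)
  expect_lt(abs(f_oracle - 40), 1000 / 2048)  # nearest grid frequency
  expect_true(all(psd$power >= 0))
  expect_true(all(diff(psd$freqs) > 0))
})

test_that("with one rectangular taper the estimator reduces to the periodogram", {
  x <- white_noise_signal(2000, seed = 11)
  psd <- multitaper_psd(x, rectangular_taper(2000))
  oracle <- periodogram_oracle(x$samples, x$fs)
  expect_lt(max(abs(psd$power - oracle$power)) / max(oracle$power), 1e-10)
})

test_that("the density integrates to the signal mean square (Parseval)", {
  x <- white_noise_signal(4096, seed = 3)
  psd <- multitaper_psd(x, make_slepian_tapers(4096, 3))
  expect_equal(pracma::trapz(psd$freqs, psd$power), mean(x$samples^2),
               tolerance = 0.05)
})

test_that("white-noise multitaper PSD is flat across 10 Hz bands", {
  x <- white_noise_signal(16384, seed = 5)
  psd <- multitaper_psd(x, make_slepian_tapers(16384, 3, k = 5))
  bands <- seq(0, 490, by = 10)
  avg <- vapply(bands, function(b) {
    mean(psd$power[psd$freqs >= b & psd$freqs < b + 10])
  }, numeric(1))
  expect_lt(max(avg) / min(avg), 1.5)
})

test_that("signals longer than the tapers need explicit segmentation", {
  x <- white_noise_signal(5000, seed = 7)
  tp <- make_slepian_tapers(2000, 3)
  expect_error(multitaper_psd(x, tp), "segmented")
  psd <- multitaper_psd(x, tp, segmented = TRUE)
  expect_equal(psd$n_segments, 2L)
  expect_equal(pracma::trapz(psd$freqs, psd$power),
               mean(x$samples[1:4000]^2), tolerance = 0.05)
})

test_that("band power integrates the density over the band", {
  psd <- multitaper_psd(sine_signal(40), nw = 3)
  # flat density c over the grid integrates to width * c
  flat <- psd
  flat$power <- rep(2.5, length(flat$power))
  expect_equal(band_power(flat, c(30, 50)), 20 * 2.5)

  # a 40 Hz sine concentrates power in low gamma
  expect_gt(band_power(psd, "low_gamma") / band_power(psd, "theta"), 10)
  expect_gt(band_power(psd, "low_gamma") / band_power(psd, "high_gamma"), 10)
  expect_error(band_power(psd, c(400, 600)), "outside")
})

test_that("the 2vo preset attenuates low gamma but not theta", {
  sham <- simulate_lfp(lfp_sim_config(duration_s = 30, condition = "sham",
                                      seed = 42))
  vo <- simulate_lfp(lfp_sim_config(duration_s = 30, condition = "2vo",
                                    seed = 42))
  tp <- make_slepian_tapers(2000, 3)
  p_sham <- multitaper_psd(sham$lfp, tp, segmented = TRUE)
  p_vo <- multitaper_psd(vo$lfp, tp, segmented = TRUE)
  expect_lt(band_power(p_vo, "low_gamma"), band_power(p_sham, "low_gamma"))
  expect_equal(band_power(p_vo, "theta"), band_power(p_sham, "theta"),
               tolerance = 0.15)
})

test_that("psd_band_ratio is exact, quadratic in amplitude, and scale-invariant", {
  a <- multitaper_psd(sine_signal(40, amp = 1), nw = 3)
  expect_identical(psd_band_ratio(a, a, "low_gamma"), 1)

  b <- multitaper_psd(sine_signal(40, amp = 2), nw = 3)
  expect_equal(psd_band_ratio(b, a, c(30, 50)), 4.0, tolerance = 0.02)

  # scaling both signals by c leaves the ratio unchanged
  a10 <- multitaper_psd(sine_signal(40, amp = 10), nw = 3)
  b10 <- multitaper_psd(sine_signal(40, amp = 20), nw = 3)
  expect_equal(psd_band_ratio(b10, a10, c(30, 50)),
               psd_band_ratio(b, a, c(30, 50)), tolerance = 1e-10)

  zero <- multitaper_psd(lfp_signal(numeric(2000), 1000),
                         make_slepian_tapers(2000, 3))
  expect_error(psd_band_ratio(a, zero, "low_gamma"), "zero denominator")
})

test_that("epoch selection returns seeded, artifact-free, non-overlapping epochs", {
  sim <- simulate_lfp(lfp_sim_config(duration_s = 120, seed = 9))
  ep <- select_epochs(sim$lfp, n_epochs = 10, epoch_s = 2.0, seed = 123)
  expect_length(ep$epochs, 10)
  expect_true(all(vapply(ep$epochs, function(e) length(e$samples),
                         integer(1)) == 2000L))
  # non-overlap
  expect_true(all(diff(ep$indices) >= 2000))
  # determinism
  ep2 <- select_epochs(sim$lfp, n_epochs = 10, epoch_s = 2.0, seed = 123)
  expect_identical(ep$indices, ep2$indices)
  expect_false(identical(
    ep$indices, select_epochs(sim$lfp, seed = 124)$indices))
})

test_that("selected epochs avoid injected artifacts", {
  sim <- simulate_lfp(lfp_sim_config(duration_s = 120, seed = 10))
  x <- sim$lfp$samples
  art_at <- c(11, 37, 63, 89, 110)  # artifact start times, s
  amp <- 20 * sd(x)
  for (a in art_at) {
    idx <- (a * 1000):(a * 1000 + 499)
    x[idx] <- x[idx] + amp
  }
  dirty <- lfp_signal(x, 1000)
  ep <- select_epochs(dirty, n_epochs = 10, epoch_s = 2.0, seed = 5)
  art_samples <- unlist(lapply(art_at, function(a) (a * 1000):(a * 1000 + 499)))
  for (s in ep$indices) {
    expect_length(intersect(s:(s + 1999), art_samples), 0)
  }
  # an impossible request reports availability
  expect_error(select_epochs(dirty, n_epochs = 100), "available")
})
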