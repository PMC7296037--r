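make_punctum <- function(intensity, times = seq(0, 600, by = 26.5),
                         diameter = 1.0, circ = 0.9, bg_mean = 10,
                         bg_sd = 2, id = NA_character_) {
  punctum_trace(times, intensity, diameter_um = diameter, circularity = circ,
                background_mean = bg_mean, background_sd = bg_sd, id = id)
}

decay_intensity <- function(times, k, amp = 100, residual = 0.08,
                            bg = 10) {
  bg + amp * (residual + (1 - residual) * exp(-k * times))
}

test_that("punctum QC applies the three selection criteria", {
  times <- seq(0, 600, by = 26.5)
  good <- make_punctum(decay_intensity(times, 0.05), id = "good")
  # intensity = mean + 3 SD passes; diameter and circularity in range
  pass3sd <- make_punctum(16 + 0 * times, id = "pass3sd")      # 10 + 3*2
  big <- make_punctum(decay_intensity(times, 0.05), diameter = 2.5,
                      id = "big")
  dim2sd <- make_punctum(14 + 0 * times, id = "exactly2sd")    # 10 + 2*2
  squiggle <- make_punctum(decay_intensity(times, 0.05), circ = 0.5,
                           id = "squiggle")

  qc <- qc_puncta(list(good, pass3sd, big, dim2sd, squiggle))
  ids <- vapply(qc$accepted, `[[`, character(1), "id")
  expect_setequal(ids, c("good", "pass3sd"))
  expect_equal(qc$rejected$reason[qc$rejected$id == "big"], "diameter")
  # "more than two standard deviations" is a strict inequality
  expect_equal(qc$rejected$reason[qc$rejected$id == "exactly2sd"],
               "intensity")
  expect_equal(qc$rejected$reason[qc$rejected$id == "squiggle"],
               "circularity")
})

test_that("normalization is idempotent, flags high residuals, and is affine-invariant", {
  times <- seq(0, 600, by = 26.5)
  # a curve already decaying 1 -> 0 (exact zero tail) passes through
  y <- pmax(1 - times / 450, 0)
  uc <- normalize_unloading(make_punctum(y))
  expect_equal(uc$normalized, y, tolerance = 1e-12)
  expect_equal(max(uc$normalized), 1, tolerance = 1e-12)

  # 8% residual: starts at 1, tail ~ 0, no flag
  y8 <- 0.08 + 0.92 * exp(-0.02 * times)
  uc8 <- normalize_unloading(make_punctum(y8))
  expect_false(uc8$flagged)
  expect_equal(uc8$normalized[1], 1, tolerance = 1e-6)
  expect_lt(min(uc8$normalized), 0.01)

  # 15% residual plateau: flagged
  y15 <- 0.15 + 0.85 * exp(-0.02 * times)
  expect_true(normalize_unloading(make_punctum(y15))$flagged)

  # affine transform a*I + b leaves the normalized curve unchanged
  uc_aff <- normalize_unloading(make_punctum(3.7 * y8 + 0.5))
  expect_equal(uc_aff$normalized, uc8$normalized, tolerance = 1e-9)

  expect_error(normalize_unloading(make_punctum(rep(5, length(times)))),
               "degenerate")
})

test_that("unloading kinetics recover a closed-form exponential", {
  times <- seq(0, 300, by = 26.5)
  k_true <- log(2) / 10            # t_half = 10 s
  uc <- normalize_unloading(
    make_punctum(exp(-k_true * times) + 1e-9, times = times))
  kin <- unloading_rate(uc)
  expect_equal(kin$k, k_true, tolerance = 0.01)
  expect_equal(kin$t_half, 10, tolerance = 0.01)
  expect_equal(kin$inv_t_half, 0.1, tolerance = 0.01)
  # internal consistency of the three parametrizations
  expect_equal(kin$t_half, log(2) / kin$k, tolerance = 1e-12)
  expect_equal(kin$inv_t_half, kin$k / log(2), tolerance = 1e-12)
})

test_that("fit and interpolation half-times agree on a noiseless exponential", {
  times <- seq(0, 900, by = 26.5)
  uc <- normalize_unloading(
    make_punctum(decay_intensity(times, 0.01, residual = 0.01),
                 times = times))
  fit <- unloading_rate(uc, method = "fit")
  interp <- unloading_rate(uc, method = "interpolation")
  expect_equal(interp$t_half, fit$t_half, tolerance = 0.05)
})

test_that("non-decaying curves raise a no-decay error", {
  times <- seq(0, 600, by = 26.5)
  rising <- make_punctum(100 * (1 + times / 600))
  expect_error(unloading_rate(normalize_unloading(rising)), "no decay")
})

test_that("the generator's decay rate is recovered and planted QC failures rejected", {
  fm <- simulate_fm143(fm_sim_config(snr = Inf, k_per_s = 0.05, seed = 5))
  kin <- unloading_rate(normalize_unloading(fm$puncta[[1]]))
  expect_equal(kin$k, fm$truth$k, tolerance = 0.005)

  fmq <- simulate_fm143(fm_sim_config(n_puncta = 5, seed = 6,
                                      inject_qc_failures = TRUE))
  qc <- qc_puncta(fmq$puncta)
  expect_true(all(fmq$truth$planted_failures %in% qc$rejected$id))
  expect_equal(qc$rejected$reason[qc$rejected$id == "qc_fail_diameter"],
               "diameter")
  expect_equal(qc$rejected$reason[qc$rejected$id == "qc_fail_intensity"],
               "intensity")

  # estimator bias stays small on noisy traces at the imaging cadence
  fm_noisy <- simulate_fm143(fm_sim_config(n_puncta = 30, snr = 10,
                                           k_per_s = 0.01, n_frames = 30,
                                           seed = 7))
  rates <- vapply(fm_noisy$puncta, function(p) {
    unloading_rate(normalize_unloading(p))$inv_t_half
  }, numeric(1))
  expect_equal(mean(rates), fm_noisy$truth$inv_t_half, tolerance = 0.05)
})

test_that("the 2vo preset slows unloading by the configured factor", {
  rates <- vapply(c("sham", "2vo"), function(cond) {
    fm <- simulate_fm143(fm_sim_config(n_puncta = 15, condition = cond,
                                       snr = 10, n_frames = 40, seed = 8))
    mean(vapply(fm$puncta, function(p) {
      unloading_rate(normalize_unloading(p))$inv_t_half
    }, numeric(1)))
  }, numeric(1))
  expect_lt(rates["2vo"], rates["sham"])
  expect_equal(unname(rates["2vo"] / rates["sham"]), 0.6, tolerance = 0.1)
})
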