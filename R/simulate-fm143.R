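#' Configuration for the synthetic FM1-43 destaining generator
#'
#' Punctum intensities follow
#' `I(t) = background + A * (residual_frac + (1 - residual_frac) * exp(-k t))`
#' plus Gaussian noise with SD `A / snr`; frames every
#' `frame_interval_s` seconds (default 26.5, matching the 26--27 s
#' acquisition cadence). Quality-control attributes (diameter,
#' circularity) are drawn from configured uniform ranges; with
#' `inject_qc_failures = TRUE` two additional puncta planted to fail the
#' selection criteria are appended (diameter 2.5 um; initial intensity at
#' exactly background + 2 SD). Condition `"2vo"` scales the decay rate by
#' `k_scale` (default 0.6), reproducing slowed vesicle release.
#'
#' @param n_puncta number of puncta (default 15).
#' @param k_per_s true first-order decay rate, 1/s. The default 0.01
#'   (t-half about 69 s) gives a destaining time course resolved by the
#'   default 26.5 s frame cadence.
#' @param residual_frac residual plateau fraction in (0, 1)
#'   (default 0.08).
#' @param frame_interval_s frame interval, s.
#' @param n_frames frames per trace (default 24, ~10.6 min).
#' @param snr initial amplitude over noise SD; `Inf` for noiseless.
#' @param amp mean fluorescence amplitude above background (a.u.).
#' @param background_mean,background_sd background statistics (a.u.).
#' @param diameter_range,circularity_range uniform draw ranges.
#' @param condition `"sham"` or `"2vo"`.
#' @param k_scale decay-rate multiplier applied under `"2vo"`.
#' @param inject_qc_failures append planted QC-failing puncta.
#' @param seed integer RNG seed.
#' @return An object of class `fm_sim_config`.
#' @export
fm_sim_config <- function(n_puncta = 15, k_per_s = 0.01,
                          residual_frac = 0.08, frame_interval_s = 26.5,
                          n_frames = 24, snr = 10, amp = 100,
                          background_mean = 10, background_sd = 2,
                          diameter_range = c(0.5, 1.5),
                          circularity_range = c(0.75, 0.95),
                          condition = c("sham", "2vo"), k_scale = 0.6,
                          inject_qc_failures = FALSE, seed = 1L) {
  condition <- match.arg(condition)
  stopifnot_scalar_number(k_per_s, "k_per_s", positive = TRUE)
  if (residual_frac <= 0 || residual_frac >= 1) {
    stop("`residual_frac` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(n_puncta = as.integer(n_puncta), k_per_s = k_per_s,
         residual_frac = residual_frac, frame_interval_s = frame_interval_s,
         n_frames = as.integer(n_frames), snr = snr, amp = amp,
         background_mean = background_mean, background_sd = background_sd,
         diameter_range = diameter_range,
         circularity_range = circularity_range, condition = condition,
         k_scale = k_scale, inject_qc_failures = inject_qc_failures,
         seed = as.integer(seed)),
    class = "fm_sim_config"
  )
}

#' Simulate FM1-43 punctum destaining traces
#'
#' @param config an [fm_sim_config()].
#' @return list with `puncta` (list of [punctum_trace()]s) and `truth`
#'   (realized decay rate `k`, `t_half`, `inv_t_half`, residual fraction,
#'   and ids of any planted QC failures).
#' @export
simulate_fm143 <- function(config) {
  stopifnot(inherits(config, "fm_sim_config"))
  k <- config$k_per_s
  if (config$condition == "2vo") k <- k * config$k_scale
  times <- (seq_len(config$n_frames) - 1L) * config$frame_interval_s
  noise_sd <- if (is.finite(config$snr)) config$amp / config$snr else 0

  with_seed(config$seed, {
    make_trace <- function(id, diameter, circularity, intensity0 = NULL) {
      mean_curve <- config$background_mean + config$amp *
        (config$residual_frac + (1 - config$residual_frac) * exp(-k * times))
      y <- mean_curve + noise_sd * rnorm(length(times))
      if (!is.null(intensity0)) {
        # planted boundary case: initial frame pinned to an exact level
        y[1] <- intensity0
      }
      punctum_trace(times, pmax(y, 0), diameter_um = diameter,
                    circularity = circularity,
                    background_mean = config$background_mean,
                    background_sd = config$background_sd, id = id)
    }
    puncta <- lapply(seq_len(config$n_puncta), function(i) {
      make_trace(sprintf("p%02d", i),
                 runif(1, config$diameter_range[1], config$diameter_range[2]),
                 runif(1, config$circularity_range[1],
                       config$circularity_range[2]))
    })
    planted <- character(0)
    if (config$inject_qc_failures) {
      puncta[[length(puncta) + 1L]] <- make_trace("qc_fail_diameter", 2.5, 0.9)
      puncta[[length(puncta) + 1L]] <- make_trace(
        "qc_fail_intensity", 1.0, 0.9,
        intensity0 = config$background_mean + 2 * config$background_sd)
      planted <- c("qc_fail_diameter", "qc_fail_intensity")
    }
    list(
      puncta = puncta,
      truth = list(k = k, t_half = log(2) / k, inv_t_half = k / log(2),
                   residual_frac = config$residual_frac,
                   planted_failures = planted)
    )
  })
}
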