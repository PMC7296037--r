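#' Construct an evoked-sweep record
#'
#' One evoked fEPSP trace with its stimulus timestamps: the container for
#' input-output, paired-pulse and LTP protocols.
#'
#' @param trace an [lfp_signal()] (nominal sampling >= 5 kHz for evoked
#'   sweeps; a warning is issued below that).
#' @param stim_times stimulus times in seconds, strictly increasing,
#'   inside the trace.
#' @param intensity stimulus intensity in mA (optional).
#' @param label condition tag (optional).
#' @return An object of class `sweep_record`.
#' @export
sweep_record <- function(trace, stim_times, intensity = NA_real_,
                         label = NA_character_) {
  stopifnot(inherits(trace, "lfp_signal"))
  if (length(stim_times) < 1L || is.unsorted(stim_times, strictly = TRUE)) {
    stop("`stim_times` must be nonempty and strictly increasing",
         call. = FALSE)
  }
  t_end <- trace$t0 + (length(trace$samples) - 1L) / trace$fs
  if (min(stim_times) < trace$t0 || max(stim_times) > t_end) {
    stop("`stim_times` must lie inside the trace", call. = FALSE)
  }
  if (trace$fs < 5000) {
    warning("sweep sampling rate below the nominal 5 kHz for evoked responses")
  }
  structure(
    list(trace = trace, stim_times = as.numeric(stim_times),
         intensity = intensity, label = label),
    class = "sweep_record"
  )
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf("<sweep_record> %d stim(s), %g kHz, %.1f ms%s%s\n",
              length(x$stim_times), x$trace$fs / 1000,
              1000 * duration(x$trace),
              if (!is.na(x$intensity)) sprintf(", %g mA", x$intensity) else "",
              if (!is.na(x$label)) sprintf(", [%s]", x$label) else ""))
  invisible(x)
}

#' fEPSP slope, amplitude and latency
#'
#' Measures one evoked response: amplitude is the absolute deflection of
#' the extremum from the pre-stimulus baseline; slope is the least-squares
#' line fitted over the 20--80% span of the rising phase (signed by
#' deflection direction, units/ms); latency is stimulus-to-peak in ms. The
#' first `blank_ms` after the stimulus are excluded to blank the stimulus
#' artifact. A response must exceed `detect_snr` times the baseline noise
#' SD, otherwise a feature-not-found error is raised.
#'
#' @param sweep a [sweep_record()].
#' @param stim_index which stimulus to measure (default 1).
#' @param slope_window fractions of peak deflection bounding the fitted
#'   rising segment (default `c(0.2, 0.8)`).
#' @param blank_ms artifact blanking interval after the stimulus
#'   (default 1 ms).
#' @param baseline_ms pre-stimulus window for the baseline mean and noise
#'   SD (default 5 ms).
#' @param response_window_ms search window after blanking (default 50 ms,
#'   truncated at the next stimulus).
#' @param detect_snr detection threshold in baseline-noise SDs (default 5).
#' @return An object of class `fepsp_features`: `slope` (units/ms,
#'   signed), `amplitude` (>= 0), `latency_to_peak` (ms), `baseline`,
#'   `peak_value`, `direction` (+1/-1).
#' @export
fepsp_features <- function(sweep, stim_index = 1, slope_window = c(0.2, 0.8),
                           blank_ms = 1, baseline_ms = 5,
                           response_window_ms = 50, detect_snr = 5) {
  stopifnot(inherits(sweep, "sweep_record"))
  stim_index <- as.integer(stim_index)
  if (stim_index < 1L || stim_index > length(sweep$stim_times)) {
    stop("`stim_index` out of range", call. = FALSE)
  }
  tr <- sweep$trace
  fs <- tr$fs
  x <- tr$samples
  i_stim <- as.integer(round((sweep$stim_times[stim_index] - tr$t0) * fs)) + 1L

  i_base0 <- max(1L, i_stim - as.integer(round(baseline_ms * fs / 1000)))
  i_base1 <- max(1L, i_stim - 1L)
  baseline <- mean(x[i_base0:i_base1])
  noise_sd <- sd(x[i_base0:i_base1])
  if (!is.finite(noise_sd)) noise_sd <- 0

  i0 <- i_stim + as.integer(round(blank_ms * fs / 1000))
  i1 <- i_stim + as.integer(round(response_window_ms * fs / 1000))
  if (stim_index < length(sweep$stim_times)) {
    i_next <- as.integer(round((sweep$stim_times[stim_index + 1L] - tr$t0) * fs)) + 1L
    i1 <- min(i1, i_next - 1L)
  }
  i1 <- min(i1, length(x))
  if (i1 <= i0 + 3L) stop("response window too short", call. = FALSE)

  d <- x[i0:i1] - baseline
  i_peak_rel <- which.max(abs(d))
  peak_defl <- d[i_peak_rel]
  amplitude <- abs(peak_defl)
  if (amplitude <= max(detect_snr * noise_sd, 1e-12)) {
    stop("feature not found: no deflection above the noise floor",
         call. = FALSE)
  }
  direction <- sign(peak_defl)

  # rising limb: samples between the 20% and 80% crossings of the peak
  # deflection, with the exact crossing points added by linear
  # interpolation so the fitted window does not depend on where the
  # sampling grid happens to fall
  r <- d * direction            # positive-going copy
  lo_th <- slope_window[1] * amplitude
  hi_th <- slope_window[2] * amplitude
  below <- which(r[1:i_peak_rel] < lo_th)
  i_a <- if (length(below)) max(below) + 1L else 1L
  above <- which(r[i_a:i_peak_rel] >= hi_th)
  i_b <- if (length(above)) i_a + min(above) - 1L else i_peak_rel
  if (i_b - i_a < 1L) {  # too few samples on the rising limb
    i_a <- max(1L, i_b - 1L)
  }
  cross_t <- function(i, th) {  # crossing time (ms) just before sample i
    if (i <= 1L || r[i] == r[i - 1L]) return((i - 1L) / fs * 1000)
    ((i - 2L) + (th - r[i - 1L]) / (r[i] - r[i - 1L])) / fs * 1000
  }
  seg <- i_a:max(i_a, i_b - 1L)       # samples strictly inside the crossings
  t_ms <- (seg - 1L) / fs * 1000
  tt <- c(cross_t(i_a, lo_th), t_ms, cross_t(i_b, hi_th))
  vv <- c(direction * lo_th, d[seg], direction * hi_th)
  fit <- lm(vv ~ tt)
  slope <- unname(coef(fit)[2])

  structure(
    list(slope = slope, amplitude = amplitude,
         latency_to_peak = (i0 - i_stim + i_peak_rel - 1L) / fs * 1000,
         baseline = baseline, peak_value = baseline + peak_defl,
         direction = direction, noise_sd = noise_sd),
    class = "fepsp_features"
  )
}

#' @export
print.fepsp_features <- function(x, ...) {
  cat(sprintf(
    "<fepsp_features> slope %.4g units/ms, amplitude %.4g, peak latency %.2f ms\n",
    x$slope, x$amplitude, x$latency_to_peak))
  invisible(x)
}

#' Input-output curve and half-maximal stimulus intensity
#'
#' Groups sweeps by stimulus intensity, averages fEPSP slope and amplitude
#' per intensity, and locates the intensity at which the mean absolute
#' slope first crosses 50% of its maximum, by linear interpolation between
#' grid points (the intensity conventionally selected for subsequent
#' paired-pulse and LTP recordings).
#'
#' @param sweeps list of [sweep_record()]s with `intensity` set; at least
#'   3 distinct intensities.
#' @param ... passed to [fepsp_features()].
#' @return An object of class `io_curve`: `intensities` (mA, increasing),
#'   `slopes`, `amplitudes` (per-intensity means), `half_max_intensity`
#'   (mA), `n_sweeps` (per intensity), `flagged` (TRUE when the crossing
#'   had to be taken at the grid edge or the curve is non-monotone).
#' @export
io_curve <- function(sweeps, ...) {
  if (!is.list(sweeps) || !all(vapply(sweeps, inherits, logical(1), "sweep_record"))) {
    stop("`sweeps` must be a list of sweep_record objects", call. = FALSE)
  }
  ints <- vapply(sweeps, `[[`, numeric(1), "intensity")
  if (anyNA(ints)) stop("every sweep needs an `intensity`", call. = FALSE)
  grid <- sort(unique(ints))
  if (length(grid) < 3L) stop("need >= 3 distinct intensities", call. = FALSE)

  feats <- lapply(sweeps, fepsp_features, ...)
  slopes <- vapply(grid, function(g) {
    mean(vapply(feats[ints == g], `[[`, numeric(1), "slope"))
  }, numeric(1))
  amps <- vapply(grid, function(g) {
    mean(vapply(feats[ints == g], `[[`, numeric(1), "amplitude"))
  }, numeric(1))
  ns <- vapply(grid, function(g) sum(ints == g), integer(1))

  a <- abs(slopes)
  target <- 0.5 * max(a)
  flagged <- FALSE
  if (a[1] >= target) {
    half <- grid[1]
    flagged <- TRUE
  } else {
    cross <- which(a[-1] >= target & a[-length(a)] < target)[1]
    if (is.na(cross)) {
      half <- grid[which.max(a)]
      flagged <- TRUE
    } else {
      i <- cross
      half <- grid[i] + (target - a[i]) / (a[i + 1] - a[i]) *
        (grid[i + 1] - grid[i])
    }
  }
  if (any(diff(a) < -0.05 * max(a))) flagged <- TRUE

  structure(
    list(intensities = grid, slopes = slopes, amplitudes = amps,
         half_max_intensity = half, n_sweeps = ns, flagged = flagged),
    class = "io_curve"
  )
}

#' @export
print.io_curve <- function(x, ...) {
  cat(sprintf("<io_curve> %d intensities %g-%g mA, half-max at %.3g mA%s\n",
              length(x$intensities), min(x$intensities), max(x$intensities),
              x$half_max_intensity, if (x$flagged) " (flagged)" else ""))
  invisible(x)
}

#' Paired-pulse ratio from a two-stimulus sweep
#'
#' PPR (%) is 100 times the slope of the second pulse-induced fEPSP
#' divided by that of the first. Before measuring the second response, the
#' decaying tail of the first is removed by fitting a single exponential
#' to the first response's decay (from shortly after its peak up to the
#' second stimulus) and subtracting its extrapolation.
#'
#' @param sweep a [sweep_record()] with exactly two stimulus times.
#' @param tail_skip_ms delay after the first peak before the decay fit
#'   window starts (default 3 ms).
#' @param ... passed to [fepsp_features()].
#' @return An object of class `ppr_result`: `isi_ms`, `ppr_percent`,
#'   `slope1`, `slope2`.
#' @export
paired_pulse_ratio <- function(sweep, tail_skip_ms = 3, ...) {
  stopifnot(inherits(sweep, "sweep_record"))
  if (length(sweep$stim_times) != 2L) {
    stop("paired-pulse sweep must contain exactly 2 stimulus times",
         call. = FALSE)
  }
  isi_ms <- diff(sweep$stim_times) * 1000
  f1 <- fepsp_features(sweep, 1, ...)
  if (abs(f1$slope) < 1e-12) {
    stop("first-response slope is ~0; ratio undefined", call. = FALSE)
  }

  tr <- sweep$trace
  fs <- tr$fs
  x <- tr$samples
  i_stim1 <- as.integer(round((sweep$stim_times[1] - tr$t0) * fs)) + 1L
  i_stim2 <- as.integer(round((sweep$stim_times[2] - tr$t0) * fs)) + 1L
  i_peak1 <- i_stim1 + as.integer(round(f1$latency_to_peak * fs / 1000))

  # single-exponential fit to the first response's decay, extrapolated
  # under the second response and subtracted
  j0 <- i_peak1 + as.integer(round(tail_skip_ms * fs / 1000))
  j1 <- i_stim2 - 1L
  corrected <- x
  if (j1 - j0 >= 4L) {
    seg <- j0:j1
    d <- (x[seg] - f1$baseline) * f1$direction
    pos <- d > 1e-12 * max(1, f1$amplitude)
    if (sum(pos) >= 4L) {
      t_s <- (seg[pos] - i_peak1) / fs
      cf <- coef(lm(log(d[pos]) ~ t_s))
      if (cf[2] < 0) {
        # genuine decay: subtract the extrapolated tail from the fit
        # window onward, so the pre-stimulus-2 baseline is corrected too
        k_idx <- j0:length(x)
        t_ext <- (k_idx - i_peak1) / fs
        corrected[k_idx] <- x[k_idx] -
          f1$direction * exp(cf[1] + cf[2] * t_ext)
      }
    }
  }
  sweep2 <- sweep
  sweep2$trace$samples <- corrected
  f2 <- fepsp_features(sweep2, 2, ...)

  structure(
    list(isi_ms = isi_ms, ppr_percent = 100 * f2$slope / f1$slope,
         slope1 = f1$slope, slope2 = f2$slope),
    class = "ppr_result"
  )
}

#' @export
print.ppr_result <- function(x, ...) {
  cat(sprintf("<ppr_result> ISI %g ms: PPR = %.1f%%\n", x$isi_ms,
              x$ppr_percent))
  invisible(x)
}

#' Paired-pulse ratio across an ISI series
#'
#' @param sweeps list of two-stimulus [sweep_record()]s (one or more per
#'   ISI); ratios at a common ISI are averaged.
#' @param ... passed to [paired_pulse_ratio()].
#' @return data.frame with columns `isi_ms`, `ppr_percent`, `n_sweeps`.
#' @export
ppr_curve <- function(sweeps, ...) {
  res <- lapply(sweeps, paired_pulse_ratio, ...)
  isi <- vapply(res, `[[`, numeric(1), "isi_ms")
  ppr <- vapply(res, `[[`, numeric(1), "ppr_percent")
  grid <- sort(unique(round(isi, 6)))
  data.frame(
    isi_ms = grid,
    ppr_percent = vapply(grid, function(g) mean(ppr[round(isi, 6) == g]),
                         numeric(1)),
    n_sweeps = vapply(grid, function(g) sum(round(isi, 6) == g), integer(1))
  )
}

#' LTP time course and magnitude
#'
#' Normalizes per-sweep fEPSP slopes to the mean over a pre-tetanus
#' baseline window (so the baseline mean is 100% by construction) and
#' reports the LTP magnitude as the mean normalized response over a
#' post-tetanus measurement window, by default 45--60 min after the
#' conditioning stimulation (`measure_window = c(0, 60)` is the supported
#' alternative convention).
#'
#' @param sweeps time-ordered list of [sweep_record()]s, one evoked
#'   response per 30 s by convention.
#' @param tetanus_min time of the tetanus in minutes from the first sweep.
#' @param sweep_times_min sweep times in minutes; default a 30-s cadence
#'   `0, 0.5, 1, ...`.
#' @param baseline_window `c(from, to)` minutes (absolute); default the 30
#'   minutes before the tetanus.
#' @param measure_window `c(from, to)` minutes relative to the tetanus
#'   (default `c(45, 60)`).
#' @param ... passed to [fepsp_features()].
#' @return An object of class `ltp_result`: `times_min`, `timecourse`
#'   (normalized %, per sweep), `magnitude_percent`, `baseline_window`,
#'   `measure_window`, `tetanus_min`.
#' @export
ltp_timecourse <- function(sweeps, tetanus_min, sweep_times_min = NULL,
                           baseline_window = NULL,
                           measure_window = c(45, 60), ...) {
  if (!is.list(sweeps) || length(sweeps) < 4L) {
    stop("need a time-ordered list of sweeps", call. = FALSE)
  }
  if (is.null(sweep_times_min)) {
    sweep_times_min <- (seq_along(sweeps) - 1L) * 0.5
  }
  if (length(sweep_times_min) != length(sweeps)) {
    stop("`sweep_times_min` must match the number of sweeps", call. = FALSE)
  }
  if (is.null(baseline_window)) {
    baseline_window <- c(max(0, tetanus_min - 30), tetanus_min)
  }
  if (baseline_window[2] > tetanus_min + 1e-9) {
    stop("baseline window must precede the tetanus", call. = FALSE)
  }
  if (measure_window[1] < 0 || measure_window[2] <= measure_window[1]) {
    stop("invalid measurement window", call. = FALSE)
  }

  slopes <- vapply(sweeps, function(s) fepsp_features(s, ...)$slope,
                   numeric(1))
  in_base <- sweep_times_min >= baseline_window[1] &
    sweep_times_min < baseline_window[2]
  if (!any(in_base)) stop("empty baseline window", call. = FALSE)
  base_mean <- mean(slopes[in_base])
  if (abs(base_mean) < 1e-15) stop("baseline mean slope ~0", call. = FALSE)
  norm <- 100 * slopes / base_mean

  lo <- tetanus_min + measure_window[1]
  hi <- tetanus_min + measure_window[2]
  in_meas <- sweep_times_min >= lo & sweep_times_min <= hi
  if (!any(in_meas)) stop("empty measurement window", call. = FALSE)

  structure(
    list(times_min = sweep_times_min, timecourse = norm,
         magnitude_percent = mean(norm[in_meas]),
         baseline_window = baseline_window, measure_window = measure_window,
         tetanus_min = tetanus_min),
    class = "ltp_result"
  )
}

#' @export
print.ltp_result <- function(x, ...) {
  cat(sprintf(
    "<ltp_result> magnitude %.1f%% at %g-%g min post-tetanus (%d sweeps)\n",
    x$magnitude_percent, x$measure_window[1], x$measure_window[2],
    length(x$timecourse)))
  invisible(x)
}
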