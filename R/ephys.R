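#' Detect miniature endplate potentials in a voltage trace
#'
#' Baseline is tracked with a running median; noise SD is estimated as the
#' MAD of the baseline-subtracted trace (robust to the sparse events).
#' Events are local depolarization peaks exceeding
#' `threshold_sd * noise SD` above baseline, separated by at least
#' `min_interval_ms`; the amplitude of each event is its peak minus the
#' local pre-event baseline.
#'
#' The residual is smoothed with a short boxcar before peak finding so that
#' single-sample noise excursions cannot trigger detections; the threshold
#' itself stays in units of the raw baseline-noise SD.
#'
#' @param trace A [voltage_trace()] without stimulus annotations in the
#'   analysed window.
#' @param threshold_sd Detection threshold in baseline-noise SDs.
#' @param min_interval_ms Minimum separation between reported events, ms.
#' @param baseline_window_ms Width of the running-median baseline window.
#' @param pre_window_ms Pre-event window used for the local baseline.
#' @param smooth_ms Boxcar width for the peak-finding smoother.
#'
#' @return A tibble with columns `time_ms` (peak time) and `amplitude_mv`.
#' @examples
#' sim <- simulate_spontaneous(10, 20, quantal_params(), membrane_model(),
#'                             seed = 2)
#' detect_mepps(sim$trace)
#' @export
detect_mepps <- function(trace, threshold_sd = 3, min_interval_ms = 5,
                         baseline_window_ms = 200, pre_window_ms = 5,
                         smooth_ms = 1) {
  stopifnot(inherits(trace, "voltage_trace"))
  sr <- attr(trace, "sample_rate")
  dt_ms <- 1000 / sr
  k <- floor(baseline_window_ms / dt_ms)
  if (k %% 2 == 0) k <- k + 1L
  if (nrow(trace) <= k) {
    abort("Trace shorter than the baseline-estimation window.")
  }
  v <- trace$v_mv
  baseline <- stats::runmed(v, k, endrule = "median")
  resid <- v - baseline
  noise_sd <- mad(resid)
  thr <- threshold_sd * noise_sd

  ks <- max(1L, round(smooth_ms / dt_ms))
  sm <- as.numeric(stats::filter(resid, rep(1 / ks, ks), sides = 2))
  sm[is.na(sm)] <- 0

  above <- sm > thr
  if (!any(above)) {
    return(tibble::tibble(time_ms = numeric(), amplitude_mv = numeric()))
  }
  # contiguous supra-threshold runs -> candidate peaks (on the smoothed
  # residual, so amplitudes are insensitive to single-sample noise maxima)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  peak_idx <- purrr::map2_int(run_start, run_end, function(a, b) {
    a + which.max(sm[a:b]) - 1L
  })
  # enforce the refractory interval: greedy left-to-right, keep first of
  # any cluster closer than min_interval_ms
  keep <- logical(length(peak_idx))
  last_t <- -Inf
  for (i in seq_along(peak_idx)) {
    t_i <- (peak_idx[i] - 1L) * dt_ms
    if (t_i - last_t >= min_interval_ms) {
      keep[i] <- TRUE
      last_t <- t_i
    }
  }
  peak_idx <- peak_idx[keep]
  run_start <- run_start[keep]

  pre_n <- max(1L, floor(pre_window_ms / dt_ms))
  amp <- purrr::map2_dbl(peak_idx, run_start, function(p, s) {
    lo <- max(1L, s - pre_n)
    hi <- max(1L, s - 1L)
    sm[p] - median(sm[lo:hi])
  })
  # a peak only counts as an event if it rises a full threshold above its
  # own pre-event baseline; this rejects re-crossings on decaying tails
  keep_amp <- amp >= thr
  tibble::tibble(time_ms = (peak_idx[keep_amp] - 1L) * dt_ms,
                 amplitude_mv = amp[keep_amp])
}

#' Measure evoked endplate potential amplitudes
#'
#' For each annotated stimulus, the amplitude is the peak within
#' `window_ms` after the stimulus minus the baseline immediately before it
#' (median over `baseline_ms`). Baselines are tracked per pulse, so a pure
#' baseline drift yields zero amplitudes.
#'
#' With closely spaced stimuli (paired-pulse protocols) a response rides on
#' the decaying tail of the previous one; with `subtract_prev_decay = TRUE`
#' the tail is fitted with a single exponential over the inter-stimulus gap
#' and its extrapolation is subtracted under the following response before
#' the peak is taken.
#'
#' @param trace A [voltage_trace()] with stimulus annotations.
#' @param window_ms Post-stimulus search window in ms; must not reach the
#'   next stimulus.
#' @param baseline_ms Pre-stimulus baseline window in ms.
#' @param subtract_prev_decay Fit and subtract the previous response's
#'   exponential decay (recommended for paired-pulse intervals shorter
#'   than a few decay constants).
#'
#' @return A tibble with columns `stim_time_ms` and `amplitude_mv`, one row
#'   per stimulus in order.
#' @export
measure_epps <- function(trace, window_ms = 10, baseline_ms = 2,
                         subtract_prev_decay = FALSE) {
  stopifnot(inherits(trace, "voltage_trace"))
  stims <- attr(trace, "stim_times_ms")
  if (!length(stims)) {
    return(tibble::tibble(stim_time_ms = numeric(), amplitude_mv = numeric()))
  }
  if (length(stims) > 1 && window_ms > min(diff(stims))) {
    abort("`window_ms` overlaps the next stimulus at this frequency.")
  }
  sr <- attr(trace, "sample_rate")
  dt_ms <- 1000 / sr
  v <- trace$v_mv
  n <- length(v)

  if (!subtract_prev_decay) {
    amp <- purrr::map_dbl(stims, function(tm) {
      i_stim <- floor(tm / dt_ms) + 1L
      i_lo <- max(1L, i_stim - floor(baseline_ms / dt_ms))
      i_base_hi <- max(1L, i_stim - 1L)
      base <- median(v[i_lo:i_base_hi])
      i_hi <- min(n, i_stim + ceiling(window_ms / dt_ms))
      max(v[i_stim:i_hi]) - base
    })
    return(tibble::tibble(stim_time_ms = stims, amplitude_mv = amp))
  }

  # decay-subtraction path: amplitudes are referenced to the pre-train
  # baseline, with the fitted exponential tail of the previous response
  # removed under each subsequent window
  i_stim1 <- floor(stims[1] / dt_ms) + 1L
  i_lo <- max(1L, i_stim1 - floor(baseline_ms / dt_ms))
  base0 <- median(v[i_lo:max(1L, i_stim1 - 1L)])
  amp <- numeric(length(stims))
  prev_peak_idx <- NA_integer_
  for (i in seq_along(stims)) {
    i_stim <- floor(stims[i] / dt_ms) + 1L
    i_hi <- min(n, i_stim + ceiling(window_ms / dt_ms))
    win <- i_stim:i_hi
    pred <- rep(0, length(win))
    if (i > 1L && !is.na(prev_peak_idx)) {
      seg <- (prev_peak_idx + 3L):(i_stim - 1L)
      seg <- seg[seg > 0 & seg <= n]
      y <- v[seg] - base0
      ok <- y > 0
      if (sum(ok) >= 4) {
        t_seg <- seg[ok] * dt_ms
        fit <- lm(log(y[ok]) ~ t_seg)
        if (is.finite(coef(fit)[2]) && coef(fit)[2] < 0) {
          pred <- exp(coef(fit)[1] + coef(fit)[2] * (win * dt_ms))
        }
      }
    }
    amp[i] <- max(v[win] - base0 - pred)
    prev_peak_idx <- win[which.max(v[win] - pred)]
  }
  tibble::tibble(stim_time_ms = stims, amplitude_mv = amp)
}

#' Normalize an amplitude to a -50 mV resting potential
#'
#' Synaptic amplitudes scale with the driving force `v_rev - v_rest`;
#' recordings from fibers with different resting potentials are made
#' comparable by rescaling to the driving force at -50 mV:
#' `v * (v_rev - (-50)) / (v_rev - v_rest)`.
#'
#' @param v Amplitude(s) in mV, >= 0.
#' @param v_rest Fiber resting potential in mV.
#' @param v_rev Synaptic reversal potential in mV (default 0).
#'
#' @return Normalized amplitude(s) in mV.
#' @examples
#' normalize_to_minus50(8, v_rest = -40) # 10
#' @export
normalize_to_minus50 <- function(v, v_rest, v_rev = 0) {
  if (any(v < 0)) abort("`v` must be non-negative.")
  if (v_rest >= v_rev) abort("`v_rest` must be below `v_rev`.")
  v * (v_rev + 50) / (v_rev - v_rest)
}

#' Correct an amplitude for nonlinear summation
#'
#' McLachlan-Martin correction: the recorded amplitude `v` saturates as it
#' approaches the driving force `E = v_rev - v_rest`; the linear amplitude
#' is recovered as `v / (1 - f * v / E)`. Exact inverse of [saturate()].
#'
#' @param v Recorded amplitude(s) in mV; must satisfy `f * v < E`.
#' @param v_rest Fiber resting potential in mV.
#' @param v_rev Synaptic reversal potential in mV (default 0).
#' @param f Correction shape factor in `[0, 1]` (default 0.8).
#'
#' @return Corrected (linear) amplitude(s) in mV, `>= v`.
#' @examples
#' nls_correct(10, v_rest = -50) # 11.905
#' @export
nls_correct <- function(v, v_rest, v_rev = 0, f = 0.8) {
  check_number(f, "f", lower = 0, upper = 1)
  if (v_rest >= v_rev) abort("`v_rest` must be below `v_rev`.")
  E <- v_rev - v_rest
  if (any(f * v >= E)) {
    abort("Correction singular: `f * v` must stay below the driving force.")
  }
  v / (1 - f * v / E)
}

#' Condition raw amplitudes for quantal analysis
#'
#' Applies the two conditioning steps in a fixed order: nonlinear-summation
#' correction at the fiber's own resting potential first, then linear
#' normalization to -50 mV. The order matters because the correction is
#' nonlinear; the pipeline pins correct-then-normalize.
#'
#' @inheritParams nls_correct
#' @return Conditioned amplitude(s) in mV.
#' @export
condition_amplitudes <- function(v, v_rest, v_rev = 0, f = 0.8) {
  normalize_to_minus50(nls_correct(v, v_rest, v_rev, f), v_rest, v_rev)
}

#' Quantal content by the direct method
#'
#' `m = mean EPP amplitude / mean MEPP amplitude`, both conditioned the
#' same way (corrected for nonlinear summation and normalized to -50 mV).
#'
#' @param mean_epp Mean evoked endplate potential amplitude in mV.
#' @param mean_mepp Mean miniature endplate potential amplitude in mV, > 0.
#'
#' @return The quantal content `m` (dimensionless).
#' @examples
#' quantal_content_direct(7.27, 0.61)
#' @export
quantal_content_direct <- function(mean_epp, mean_mepp) {
  if (any(mean_mepp <= 0)) abort("`mean_mepp` must be positive.")
  mean_epp / mean_mepp
}

#' Paired-pulse ratio
#'
#' Second response as a percentage of the first for two stimuli a few ms
#' apart; values above 100% indicate facilitation (and hence low release
#' probability).
#'
#' @param epp1,epp2 First and second response amplitudes in mV; `epp1 > 0`.
#' @return The ratio in percent, `100 * epp2 / epp1`.
#' @examples
#' paired_pulse_ratio(4, 5) # 125
#' @export
paired_pulse_ratio <- function(epp1, epp2) {
  if (any(epp1 <= 0)) abort("`epp1` must be positive.")
  100 * epp2 / epp1
}

#' Estimate the readily releasable pool (Elmqvist-Quastel)
#'
#' Plots the quantal content of each response in a high-frequency train
#' against the cumulative quantal content released before it, fits the
#' initial linear depression phase by least squares and extrapolates to the
#' x-axis: the x-intercept estimates the readily releasable pool. The first
#' response is always excluded from the fit (it is facilitated).
#'
#' With constant release probability `p` and no replenishment the expected
#' relation is exactly linear, `m_i = p * (N - C_i)`, so the x-intercept is
#' `N` and the slope is `-p`. At low `p` the per-pulse depression is small
#' relative to binomial noise and a longer `fit_range` is needed for a
#' stable slope.
#'
#' @param per_pulse_qc Numeric vector of per-pulse quantal contents `m_i`
#'   (>= 6 pulses).
#' @param fit_range Indices of pulses entering the fit. Default `2:6`;
#'   `"auto"` grows the window from pulse 2 while the fit keeps
#'   `r^2 >= r2_floor`. Index 1 is dropped if supplied.
#' @param r2_floor Minimum `r^2`: below it the fit is rejected as having no
#'   resolvable depression phase (and the floor drives the `"auto"` rule).
#'
#' @return An object of class `rrp_fit`: list with `per_pulse_qc`,
#'   `cumulative_qc`, `rrp`, `p_release`, `fit_slope`, `fit_intercept`,
#'   `fit_r2`, `fit_range`. `p_release = per_pulse_qc[1] / rrp`.
#' @examples
#' m <- numeric(10); pool <- 100
#' for (i in 1:10) { m[i] <- 0.1 * pool; pool <- pool - m[i] }
#' fit <- estimate_rrp(m)
#' fit$rrp
#' @export
estimate_rrp <- function(per_pulse_qc, fit_range = 2:6, r2_floor = 0) {
  if (length(per_pulse_qc) < 6) {
    abort("At least 6 pulses are required for the depletion fit.")
  }
  n <- length(per_pulse_qc)
  cum_qc <- c(0, cumsum(per_pulse_qc)[-n])

  if (identical(fit_range, "auto")) {
    fit_range <- eq_auto_range(per_pulse_qc, cum_qc, r2_floor)
  }
  fit_range <- sort(unique(as.integer(fit_range)))
  fit_range <- fit_range[fit_range >= 2L & fit_range <= n]
  if (length(fit_range) < 2) {
    abort("`fit_range` must contain at least 2 pulses after excluding pulse 1.")
  }

  fit <- lm(m ~ cum, data = data.frame(m = per_pulse_qc[fit_range],
                                       cum = cum_qc[fit_range]))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  tss <- sum((per_pulse_qc[fit_range] - mean(per_pulse_qc[fit_range]))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 0
  if (!is.finite(slope) || slope >= 0 || tss == 0 || r2 < r2_floor) {
    abort("No depression phase: quantal content does not decline over the fit range.")
  }
  rrp <- -intercept / slope
  p_rel <- per_pulse_qc[1] / rrp
  if (p_rel > 1) {
    warn("Estimated release probability exceeds 1; check the fit range.")
  }
  structure(
    list(per_pulse_qc = per_pulse_qc, cumulative_qc = cum_qc, rrp = rrp,
         p_release = p_rel, fit_slope = slope, fit_intercept = intercept,
         fit_r2 = r2, fit_range = fit_range),
    class = "rrp_fit"
  )
}

# longest initial window starting at pulse 2 keeping r^2 above the floor
eq_auto_range <- function(m, cum, r2_floor) {
  n <- length(m)
  floor_use <- if (r2_floor > 0) r2_floor else 0.9
  best <- 2:4
  for (hi in 4:n) {
    idx <- 2:hi
    fit <- lm(m[idx] ~ cum[idx])
    if (is.na(coef(fit)[2]) || coef(fit)[2] >= 0) break
    tss <- sum((m[idx] - mean(m[idx]))^2)
    r2i <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 0
    if (r2i < floor_use) break
    best <- idx
  }
  best
}

#' Release probability from first-pulse quantal content and pool size
#'
#' @param m_first Quantal content of the first response.
#' @param rrp Readily-releasable-pool size in quanta, > 0.
#' @return `p = m_first / rrp`; a warning is issued when `p > 1`.
#' @examples
#' release_probability(17.3, 640)
#' @export
release_probability <- function(m_first, rrp) {
  if (any(rrp <= 0)) abort("`rrp` must be positive.")
  p <- m_first / rrp
  if (any(p > 1)) warn("Release probability above 1; reporting unclipped value.")
  p
}

#' @export
print.rrp_fit <- function(x, ...) {
  cat(sprintf(
    "<rrp_fit> RRP %.1f quanta, p_release %.4g, slope %.4g, r2 %.3f (pulses %d-%d)\n",
    x$rrp, x$p_release, x$fit_slope, x$fit_r2,
    min(x$fit_range), max(x$fit_range)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rrp_fit <- function(x, ...) {
  tibble::tibble(
    pulse = seq_along(x$per_pulse_qc),
    quantal_content = x$per_pulse_qc,
    cumulative_qc = x$cumulative_qc,
    in_fit = seq_along(x$per_pulse_qc) %in% x$fit_range
  )
}

#' @exportS3Method generics::glance
glance.rrp_fit <- function(x, ...) {
  tibble::tibble(
    rrp = x$rrp, p_release = x$p_release, fit_slope = x$fit_slope,
    fit_intercept = x$fit_intercept, fit_r2 = x$fit_r2,
    n_pulses = length(x$per_pulse_qc)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.rrp_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$cumulative_qc, .data$quantal_content)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_fit)) +
    ggplot2::geom_abline(slope = object$fit_slope,
                         intercept = object$fit_intercept,
                         linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$rrp, colour = "firebrick") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "Cumulative quantal content",
                  y = "Quantal content per pulse",
                  colour = "In fit",
                  subtitle = sprintf("RRP = %.0f quanta, p = %.3g",
                                     object$rrp, object$p_release))
}

#' Summarize junction records by group
#'
#' Takes a per-junction table (one row per neuromuscular junction) and
#' returns per-group mean, SEM and n of MEPP amplitude, MEPP frequency,
#' EPP amplitude and quantal content; two-group tables also receive a
#' pooled-t comparison per measure via [group_compare()].
#'
#' @param junctions A data frame with columns `group` and any of
#'   `mepp_amplitude`, `mepp_freq_per_min`, `epp_amplitude`,
#'   `quantal_content` (one value per junction; group statistics are over
#'   junctions, not pooled events).
#' @param control Name of the control group (default: first level).
#'
#' @return A tibble with one row per measure x group: `measure`, `group`,
#'   `mean`, `sem`, `n`, and for two-group input `t`, `p_value`,
#'   `percent_change` (vs control, on control rows `NA`).
#' @export
summarize_junctions <- function(junctions, control = NULL) {
  stopifnot(is.data.frame(junctions), "group" %in% names(junctions))
  measures <- intersect(
    c("mepp_amplitude", "mepp_freq_per_min", "epp_amplitude",
      "quantal_content"),
    names(junctions)
  )
  if (!length(measures)) abort("No recognized measure columns present.")
  groups <- unique(junctions$group)
  control <- control %||% groups[1]

  long <- junctions |>
    dplyr::select(dplyr::all_of(c("group", measures))) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))

  summ <- long |>
    dplyr::group_by(.data$measure, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )

  if (length(groups) == 2) {
    cmp <- long |>
      dplyr::group_by(.data$measure) |>
      dplyr::group_modify(function(d, key) {
        gc <- group_compare(d, value = "value", control = control)
        g <- glance(gc)
        tibble::tibble(group = setdiff(groups, control), t = g$statistic,
                       p_value = g$p_value, percent_change = g$percent_change)
      }) |>
      dplyr::ungroup()
    summ <- dplyr::left_join(summ, cmp, by = c("measure", "group"))
  }
  summ
}
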