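#' Draw quantal amplitudes
#'
#' Samples single-vesicle depolarizations from a Gaussian with mean
#' `q_mean` and standard deviation `q_cv * q_mean`, truncated below at
#' `0.05 * q_mean` so every quantum is strictly positive. Means-only
#' summary data constrain nothing beyond the first two moments, and the
#' truncated Gaussian is the conventional quantal model.
#'
#' @param params A [quantal_params()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers that already fixed a seed stay reproducible).
#'
#' @return Numeric vector of `n` strictly positive amplitudes in mV.
#' @examples
#' sample_quantal_amplitude(quantal_params(q_mean = 0.61, q_cv = 0), n = 3)
#' @export
sample_quantal_amplitude <- function(params, n = 1, seed = NULL) {
  stopifnot(inherits(params, "quantal_params"))
  draw <- function() {
    floor_mv <- 0.05 * params$q_mean
    sd_mv <- params$q_cv * params$q_mean
    if (sd_mv == 0) return(rep(params$q_mean, n))
    out <- rnorm(n, params$q_mean, sd_mv)
    bad <- which(out <= floor_mv)
    while (length(bad)) {
      out[bad] <- rnorm(length(bad), params$q_mean, sd_mv)
      bad <- bad[out[bad] <= floor_mv]
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Nonlinear summation of summed quantal depolarizations
#'
#' Forward saturation model: as the summed depolarization approaches the
#' driving force `E = v_rev - v_rest`, the recorded amplitude compresses as
#' `v / (1 + f_sat * v / E)`. This is the exact inverse of the
#' McLachlan-Martin correction applied by [nls_correct()].
#'
#' @param v_linear Linear (unsaturated) summed depolarization in mV, >= 0.
#' @param membrane A [membrane_model()] providing `v_rest`, `v_rev`, `f_sat`.
#'
#' @return Recorded amplitude in mV, `<= v_linear`, bounded by `E / f_sat`.
#' @examples
#' m <- membrane_model(v_rest = -50, f_sat = 0.8)
#' saturate(11.905, m)
#' @export
saturate <- function(v_linear, membrane) {
  stopifnot(inherits(membrane, "membrane_model"))
  if (any(v_linear < 0)) abort("`v_linear` must be non-negative.")
  E <- membrane$v_rev - membrane$v_rest
  if (E <= 0) abort("Driving force `v_rev - v_rest` must be positive.")
  v_linear / (1 + membrane$f_sat * v_linear / E)
}

new_simulated_trace <- function(trace, event_truth, model_truth) {
  structure(
    list(trace = trace, event_truth = event_truth, model_truth = model_truth),
    class = "simulated_trace"
  )
}

#' @export
print.simulated_trace <- function(x, ...) {
  cat(sprintf(
    "<simulated_trace> %.3g s at %g Hz, %d ground-truth events\n",
    nrow(x$trace) / attr(x$trace, "sample_rate"),
    attr(x$trace, "sample_rate"), nrow(x$event_truth)
  ))
  invisible(x)
}

#' Simulate spontaneous miniature endplate potentials
#'
#' Event times follow a homogeneous Poisson process at `rate_per_min`; each
#' event adds one quantal waveform (difference-of-exponentials kernel,
#' amplitude drawn by [sample_quantal_amplitude()]) to the resting
#' potential, with Gaussian recording noise per sample.
#'
#' @param rate_per_min Miniature event rate in events per minute.
#' @param duration_s Recording duration in seconds.
#' @param quantal A [quantal_params()] object.
#' @param membrane A [membrane_model()] object.
#' @param seed Integer seed.
#'
#' @return A `simulated_trace`: list with `trace` (a [voltage_trace()]),
#'   `event_truth` (tibble `time_ms`, `quanta`, `amplitude_mv`) and
#'   `model_truth` (the parameter objects used).
#' @examples
#' sim <- simulate_spontaneous(9, 10, quantal_params(), membrane_model(),
#'                             seed = 1)
#' nrow(sim$event_truth)
#' @export
simulate_spontaneous <- function(rate_per_min, duration_s, quantal, membrane,
                                 seed = 1) {
  check_number(rate_per_min, "rate_per_min", lower = 0)
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(quantal, "quantal_params"),
            inherits(membrane, "membrane_model"))
  withr::with_seed(seed, {
    n_samp <- round(duration_s * membrane$sample_rate)
    dt_ms <- 1000 / membrane$sample_rate
    n_ev <- rpois(1, rate_per_min / 60 * duration_s)
    times_ms <- sort(runif(n_ev, 0, duration_s * 1000))
    amps <- if (n_ev) sample_quantal_amplitude(quantal, n_ev) else numeric()
    v <- rep(membrane$v_rest, n_samp)
    kern <- quantal_kernel(quantal$rise_tau, quantal$decay_tau, dt_ms)
    for (i in seq_len(n_ev)) {
      v <- add_kernel(v, floor(times_ms[i] / dt_ms) + 1L,
                      saturate(amps[i], membrane), kern)
    }
    if (membrane$noise_sd > 0) v <- v + rnorm(n_samp, 0, membrane$noise_sd)
    tr <- voltage_trace(v, membrane$sample_rate, v_rest = membrane$v_rest)
    truth <- tibble::tibble(
      time_ms = times_ms,
      quanta = rep(1L, n_ev),
      amplitude_mv = amps
    )
    new_simulated_trace(tr, truth,
                        list(quantal = quantal, membrane = membrane,
                             rate_per_min = rate_per_min, seed = seed))
  })
}

#' Simulate evoked release for a stimulus train
#'
#' At each stimulus the number of released quanta is
#' `Binomial(floor(pool), p)`. The pool is decremented by the released
#' quanta and replenished continuously at `replenishment_rate` vesicles/ms
#' (never above `pool_size`). After each stimulus the release probability
#' gains `facilitation_increment`, decaying exponentially with
#' `facilitation_tau`; the facilitated probability is clamped at 1. The
#' summed quantal depolarization of each response passes through
#' [saturate()] before being written into the trace.
#'
#' @param release A [release_model()] object.
#' @param quantal A [quantal_params()] object.
#' @param membrane A [membrane_model()] object.
#' @param stim_times_ms Strictly increasing stimulus times in ms.
#' @param seed Integer seed.
#' @param tail_ms Quiet time appended after the last stimulus, in ms.
#'
#' @return A `simulated_trace`; `event_truth` has one row per stimulus with
#'   `time_ms`, `quanta` and the saturated summed `amplitude_mv`.
#' @examples
#' sim <- simulate_train(release_model(100, 0.2), quantal_params(),
#'                       membrane_model(), stim_times_ms = seq(0, 380, 20),
#'                       seed = 1)
#' sim$event_truth$quanta
#' @export
simulate_train <- function(release, quantal, membrane, stim_times_ms,
                           seed = 1, tail_ms = 50) {
  stopifnot(inherits(release, "release_model"),
            inherits(quantal, "quantal_params"),
            inherits(membrane, "membrane_model"))
  if (!length(stim_times_ms) || any(diff(stim_times_ms) <= 0)) {
    abort("`stim_times_ms` must be non-empty and strictly increasing.")
  }
  withr::with_seed(seed, {
    dt_ms <- 1000 / membrane$sample_rate
    duration_ms <- max(stim_times_ms) + tail_ms
    n_samp <- ceiling(duration_ms / dt_ms)
    v <- rep(membrane$v_rest, n_samp)
    kern <- quantal_kernel(quantal$rise_tau, quantal$decay_tau, dt_ms)

    pool <- as.numeric(release$pool_size)
    facil <- 0
    t_prev <- stim_times_ms[1]
    quanta <- integer(length(stim_times_ms))
    amps <- numeric(length(stim_times_ms))
    for (i in seq_along(stim_times_ms)) {
      dt_stim <- stim_times_ms[i] - t_prev
      # continuous replenishment and facilitation decay since last stimulus
      pool <- min(release$pool_size,
                  pool + release$replenishment_rate * dt_stim)
      facil <- facil * exp(-dt_stim / release$facilitation_tau)
      p <- min(1, release$p0 + facil)
      k <- rbinom(1, floor(pool), p)
      pool <- pool - k
      facil <- facil + release$facilitation_increment
      t_prev <- stim_times_ms[i]
      quanta[i] <- k
      v_lin <- if (k > 0) sum(sample_quantal_amplitude(quantal, k)) else 0
      amps[i] <- saturate(v_lin, membrane)
      if (k > 0) {
        v <- add_kernel(v, floor(stim_times_ms[i] / dt_ms) + 1L, amps[i], kern)
      }
    }
    if (membrane$noise_sd > 0) v <- v + rnorm(n_samp, 0, membrane$noise_sd)
    tr <- voltage_trace(v, membrane$sample_rate,
                        stim_times_ms = stim_times_ms,
                        v_rest = membrane$v_rest)
    truth <- tibble::tibble(
      time_ms = stim_times_ms, quanta = quanta, amplitude_mv = amps
    )
    new_simulated_trace(tr, truth,
                        list(release = release, quantal = quantal,
                             membrane = membrane, seed = seed))
  })
}

#' Simulate per-unit morphometry count tables
#'
#' Per-unit counts (synapses per neuron, cells per section, ...) are drawn
#' from a negative binomial with the stated mean and dispersion (`size`
#' parameter; `Inf` gives the Poisson limit), perimeters and areas from
#' Gamma distributions with the stated mean and coefficient of variation.
#'
#' @param group_specs A data frame with one row per group and columns
#'   `group`, `mean_count`, `n`, and optionally `dispersion` (default
#'   `Inf`), `perimeter_mean`/`perimeter_cv` (um), `area_mean`/`area_cv`
#'   (um^2), `p_exclude` (probability a unit is flagged for exclusion,
#'   default 0).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `unit_id`, `animal_id`, `group`, `count`,
#'   `perimeter_um`, `area_um2`, `include_flag`.
#' @examples
#' specs <- tibble::tibble(group = c("control", "mutant"),
#'                         mean_count = c(64.3, 46.1), n = c(30, 30))
#' simulate_morphometry(specs, seed = 1)
#' @export
simulate_morphometry <- function(group_specs, seed = 1) {
  stopifnot(is.data.frame(group_specs))
  need <- c("group", "mean_count", "n")
  if (!all(need %in% names(group_specs))) {
    abort(sprintf("`group_specs` must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  specs <- tibble::as_tibble(group_specs)
  if (!"dispersion" %in% names(specs)) specs$dispersion <- Inf
  if (!"perimeter_mean" %in% names(specs)) specs$perimeter_mean <- 120
  if (!"perimeter_cv" %in% names(specs)) specs$perimeter_cv <- 0.2
  if (!"area_mean" %in% names(specs)) specs$area_mean <- 500
  if (!"area_cv" %in% names(specs)) specs$area_cv <- 0.25
  if (!"p_exclude" %in% names(specs)) specs$p_exclude <- 0
  if (any(specs$mean_count < 0) || any(specs$n < 1)) {
    abort("Group means must be >= 0 and group sizes >= 1.")
  }

  rgamma_mean_cv <- function(n, mean, cv) {
    if (cv <= 0) return(rep(mean, n))
    shape <- 1 / cv^2
    rgamma(n, shape = shape, rate = shape / mean)
  }

  withr::with_seed(seed, {
    rows <- purrr::pmap(specs, function(group, mean_count, n, dispersion,
                                        perimeter_mean, perimeter_cv,
                                        area_mean, area_cv, p_exclude, ...) {
      n <- as.integer(n)
      counts <- if (mean_count == 0) {
        rep(0L, n)
      } else if (is.infinite(dispersion)) {
        rpois(n, mean_count)
      } else {
        rnbinom(n, mu = mean_count, size = dispersion)
      }
      tibble::tibble(
        group = group,
        count = as.integer(counts),
        perimeter_um = rgamma_mean_cv(n, perimeter_mean, perimeter_cv),
        area_um2 = rgamma_mean_cv(n, area_mean, area_cv),
        include_flag = runif(n) >= p_exclude
      )
    })
    out <- dplyr::bind_rows(rows)
    out$unit_id <- sprintf("u%04d", seq_len(nrow(out)))
    # units spread over notional animals in blocks of ~20
    out$animal_id <- paste0(out$group, "_a",
                            (seq_len(nrow(out)) - 1) %/% 20 + 1)
    dplyr::select(out, "unit_id", "animal_id", "group", "count",
                  "perimeter_um", "area_um2", "include_flag")
  })
}

#' Simulate muscle tension traces
#'
#' A single twitch is a difference-of-exponentials pulse of amplitude
#' `peak_g`. In a train, each stimulus adds a twitch scaled by
#' `1 - F(t)/F_max` where `F(t)` is the instantaneous force and
#' `F_max = peak_g / fusion`, so summation saturates and high-frequency
#' trains approach a fused plateau near `F_max`. `fusion -> 0` recovers
#' linear summation; a single twitch always reaches exactly `peak_g`.
#'
#' @param peak_g Single-twitch peak force in grams.
#' @param rise_tau,decay_tau Twitch rise/decay time constants in ms.
#' @param stim_freq Stimulation frequency in Hz.
#' @param n_stim Number of stimuli.
#' @param fusion Saturation parameter in `(0, 1]`; plateau ~ `peak_g/fusion`.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param noise_sd Force noise SD in g (default 0, noiseless).
#' @param sample_rate Sampling rate in Hz.
#' @param mode `"indirect"` (nerve) or `"direct"` (muscle) stimulation.
#' @param csa_mm2 Muscle cross-sectional area in mm^2 (optional metadata).
#' @param pre_ms Quiet baseline before the first stimulus, in ms.
#'
#' @return A tibble of class `tension_record` with columns `time_s`,
#'   `force_g`; attributes `sample_rate`, `mode`, `frequency`,
#'   `stim_times_ms`, `csa_mm2`.
#' @examples
#' rec <- simulate_tension(2, stim_freq = 1, n_stim = 1)
#' peak_force(rec)
#' @export
simulate_tension <- function(peak_g, rise_tau = 10, decay_tau = 40,
                             stim_freq = 1, n_stim = 1, fusion = 0.4,
                             seed = 1, noise_sd = 0, sample_rate = 2000,
                             mode = c("indirect", "direct"),
                             csa_mm2 = NA_real_, pre_ms = 100) {
  check_number(peak_g, "peak_g", lower = 0)
  check_number(fusion, "fusion", lower = 0, upper = 1, strict_lower = TRUE)
  mode <- match.arg(mode)
  withr::with_seed(seed, {
    dt_ms <- 1000 / sample_rate
    isi_ms <- 1000 / stim_freq
    stim_times_ms <- pre_ms + (seq_len(n_stim) - 1) * isi_ms
    duration_ms <- max(stim_times_ms) + 6 * decay_tau + pre_ms
    n_samp <- ceiling(duration_ms / dt_ms)
    f <- rep(0, n_samp)
    kern <- quantal_kernel(rise_tau, decay_tau, dt_ms)
    f_max <- peak_g / fusion
    for (tm in stim_times_ms) {
      i0 <- floor(tm / dt_ms) + 1L
      scale <- if (peak_g > 0) max(0, 1 - f[i0] / f_max) else 0
      f <- add_kernel(f, i0, peak_g * scale, kern)
    }
    if (noise_sd > 0) f <- f + rnorm(n_samp, 0, noise_sd)
    out <- tibble::tibble(time_s = (seq_len(n_samp) - 1) / sample_rate,
                          force_g = f)
    attr(out, "sample_rate") <- sample_rate
    attr(out, "mode") <- mode
    attr(out, "frequency") <- stim_freq
    attr(out, "stim_times_ms") <- stim_times_ms
    attr(out, "csa_mm2") <- csa_mm2
    class(out) <- c("tension_record", class(out))
    out
  })
}
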