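#' Peak or plateau force of a tension record
#'
#' Baseline (mean of the pre-stimulus segment) is subtracted. For twitch
#' and low-frequency records the amplitude is the maximum; for tetanic
#' records (>= `tetanic_freq` Hz) it is the plateau, read as the mean of
#' the top decile of baseline-subtracted samples, which is robust to
#' ripple and the initial rise.
#'
#' @param rec A `tension_record` (see [simulate_tension()]) or a data frame
#'   with columns `time_s`, `force_g` plus attributes `sample_rate`,
#'   `frequency`, `stim_times_ms`.
#' @param tetanic_freq Frequency at and above which the plateau rule is
#'   used (default 40 Hz).
#' @param top_fraction Fraction of samples averaged for the plateau.
#'
#' @return Baseline-subtracted force in grams.
#' @examples
#' peak_force(simulate_tension(2, stim_freq = 1, n_stim = 1))
#' @export
peak_force <- function(rec, tetanic_freq = 40, top_fraction = 0.1) {
  stopifnot(is.data.frame(rec), all(c("time_s", "force_g") %in% names(rec)))
  if (!nrow(rec)) abort("Empty tension record.")
  freq <- attr(rec, "frequency")
  stims <- attr(rec, "stim_times_ms")
  f <- rec$force_g
  if (is.null(stims) || !length(stims)) {
    if (diff(range(f)) == 0) {
      abort("Constant trace with no stimulus metadata.")
    }
    base <- f[1]
  } else {
    pre <- rec$time_s * 1000 < min(stims)
    base <- if (any(pre)) mean(f[pre]) else f[1]
  }
  d <- f - base
  if (!is.null(freq) && is.finite(freq) && freq >= tetanic_freq) {
    k <- max(1L, ceiling(top_fraction * length(d)))
    mean(sort(d, decreasing = TRUE)[seq_len(k)])
  } else {
    max(d)
  }
}

#' Summarize tension records for one muscle
#'
#' @param records A list of tension records (each carrying `mode` and
#'   `frequency` attributes), or a data frame manifest is handled upstream.
#' @param csa_mm2 Optional muscle cross-sectional area in mm^2 for
#'   specific force.
#' @return A tibble of class `tension_summary` with columns `mode`,
#'   `frequency`, `peak_g`.
#' @export
summarize_tension <- function(records, csa_mm2 = NA_real_) {
  stopifnot(is.list(records))
  out <- purrr::map_dfr(records, function(r) {
    tibble::tibble(
      mode = attr(r, "mode") %||% NA_character_,
      frequency = attr(r, "frequency") %||% NA_real_,
      peak_g = peak_force(r)
    )
  })
  attr(out, "csa_mm2") <- csa_mm2
  class(out) <- c("tension_summary", class(out))
  out
}

#' Indirect/direct stimulation force ratio per frequency
#'
#' The ratio of nerve-evoked to muscle-evoked force at matching
#' frequencies. A healthy junction transmits every impulse, so the ratio
#' is close to one; transmission failures push it below one.
#'
#' @param summary A `tension_summary` (or data frame with `mode`,
#'   `frequency`, `peak_g`) containing both modes; alternatively pass
#'   `indirect` and `direct` as two data frames with `frequency`, `peak_g`.
#' @param indirect,direct Optional two-table form.
#' @return A tibble with `frequency`, `indirect_g`, `direct_g`, `ratio`.
#' @examples
#' s <- tibble::tibble(mode = rep(c("indirect", "direct"), each = 2),
#'                     frequency = c(1, 100, 1, 100),
#'                     peak_g = c(1.94, 4.1, 2.0, 4.0))
#' stim_ratio(s)
#' @export
stim_ratio <- function(summary = NULL, indirect = NULL, direct = NULL) {
  if (is.null(indirect)) {
    stopifnot(is.data.frame(summary),
              all(c("mode", "frequency", "peak_g") %in% names(summary)))
    indirect <- dplyr::filter(summary, .data$mode == "indirect")
    direct <- dplyr::filter(summary, .data$mode == "direct")
  }
  merged <- dplyr::inner_join(
    dplyr::summarise(dplyr::group_by(tibble::as_tibble(indirect),
                                     .data$frequency),
                     indirect_g = mean(.data$peak_g), .groups = "drop"),
    dplyr::summarise(dplyr::group_by(tibble::as_tibble(direct),
                                     .data$frequency),
                     direct_g = mean(.data$peak_g), .groups = "drop"),
    by = "frequency"
  )
  if (!nrow(merged)) abort("No matching frequencies between modes.")
  if (any(merged$direct_g == 0)) abort("Zero direct force at some frequency.")
  dplyr::mutate(merged, ratio = .data$indirect_g / .data$direct_g)
}

#' Specific force
#'
#' Maximal force (direct muscle stimulation at 100 Hz) normalized to the
#' muscle cross-sectional area.
#'
#' @param max_force_g Maximal tetanic force in grams.
#' @param csa_mm2 Cross-sectional area in mm^2, > 0.
#' @return Specific force in g/mm^2.
#' @examples
#' specific_force(2, 0.5) # 4
#' @export
specific_force <- function(max_force_g, csa_mm2) {
  if (any(csa_mm2 <= 0)) abort("`csa_mm2` must be positive.")
  max_force_g / csa_mm2
}

#' @exportS3Method ggplot2::autoplot
autoplot.tension_record <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$force_g)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time (s)", y = "Force (g)",
      subtitle = sprintf("%s stimulation, %g Hz",
                         attr(object, "mode") %||% "?",
                         attr(object, "frequency") %||% NA)
    )
}
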