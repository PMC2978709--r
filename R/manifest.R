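#' Analyze a directory of traces listed in a manifest
#'
#' Routes each trace to the analyzer its protocol requires: `mepp` traces
#' go through miniature detection, `epp1hz` through evoked-amplitude
#' measurement, `paired` through paired-pulse analysis (with decay
#' subtraction) and `train50hz` through the cumulative-release pool fit.
#' Amplitudes are conditioned (correction, then normalization to -50 mV)
#' using each trace's own resting potential.
#'
#' @param manifest A validated ephys manifest (see [read_manifest()]) or a
#'   path to one.
#' @param dir Directory that the manifest's `file` column is relative to;
#'   default the manifest's own directory (or `.` for a data-frame input).
#' @param v_rev,f Conditioning parameters.
#' @param fit_range Pulse range for the pool fit on `train50hz` traces;
#'   `NULL` fits all pulses after the first.
#' @param ... Passed to [detect_mepps()].
#'
#' @return A tibble with one row per manifest entry: `id`, `group`,
#'   `protocol`, and protocol-dependent results (`n_events`,
#'   `mean_amplitude`, `freq_per_min`, `quantal_content` inputs, `ppf_pct`,
#'   `rrp`, `p_release`).
#' @export
analyze_manifest <- function(manifest, dir = NULL, v_rev = 0, f = 0.8,
                             fit_range = NULL, ...) {
  if (is.character(manifest)) {
    dir <- dir %||% dirname(manifest)
    manifest <- read_manifest(manifest, kind = "ephys")
  }
  dir <- dir %||% "."
  purrr::pmap_dfr(manifest, function(id, group, protocol, file, ...) {
    tr <- read_trace(file.path(dir, file))
    v_rest <- attr(tr, "v_rest")
    base <- tibble::tibble(id = id, group = group, protocol = protocol,
                           n_events = NA_integer_,
                           mean_amplitude = NA_real_,
                           freq_per_min = NA_real_, ppf_pct = NA_real_,
                           rrp = NA_real_, p_release = NA_real_)
    if (protocol == "mepp") {
      ev <- detect_mepps(tr)
      base$n_events <- nrow(ev)
      if (nrow(ev)) {
        base$mean_amplitude <- mean(condition_amplitudes(ev$amplitude_mv,
                                                         v_rest, v_rev, f))
      }
      base$freq_per_min <- nrow(ev) / (trace_duration_ms(tr) / 60000)
    } else if (protocol == "epp1hz") {
      ev <- measure_epps(tr)
      base$n_events <- nrow(ev)
      if (nrow(ev)) {
        base$mean_amplitude <- mean(condition_amplitudes(ev$amplitude_mv,
                                                         v_rest, v_rev, f))
      }
    } else if (protocol == "paired") {
      ev <- measure_epps(tr, window_ms = 8, subtract_prev_decay = TRUE)
      a <- condition_amplitudes(pmax(ev$amplitude_mv, 0), v_rest, v_rev, f)
      base$n_events <- nrow(ev)
      base$mean_amplitude <- mean(a)
      if (nrow(ev) >= 2 && a[1] > 0) {
        base$ppf_pct <- paired_pulse_ratio(a[1], a[2])
      }
    } else if (protocol == "train50hz") {
      ev <- measure_epps(tr)
      a <- condition_amplitudes(ev$amplitude_mv, v_rest, v_rev, f)
      base$n_events <- nrow(ev)
      base$mean_amplitude <- mean(a)
      fit <- tryCatch(
        estimate_rrp(a / a[1],
                     fit_range = fit_range %||% seq(2L, length(a))),
        error = function(e) NULL
      )
      # per-pulse values are in units of the first response here; callers
      # with a miniature reference rescale rrp by m_1 afterwards
      if (!is.null(fit)) {
        base$rrp <- fit$rrp
        base$p_release <- fit$p_release
      }
    }
    base
  })
}
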