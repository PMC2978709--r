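#' Build a voltage trace
#'
#' A voltage trace is a tibble with columns `time_s` (s) and `v_mv` (mV),
#' uniformly sampled, carrying the sampling rate, optional stimulus
#' annotations and the fiber's resting potential as attributes. All
#' downstream analyses (event detection, evoked-amplitude measurement)
#' consume this container.
#'
#' @param v_mv Numeric vector of membrane potential samples in mV.
#' @param sample_rate Sampling rate in Hz.
#' @param stim_times_ms Optional sorted vector of stimulus times in ms.
#' @param v_rest Resting potential in mV; defaults to the median sample.
#'
#' @return A tibble of class `voltage_trace` with columns `time_s`, `v_mv`.
#' @examples
#' tr <- voltage_trace(rep(-70, 1000), sample_rate = 10000, v_rest = -70)
#' trace_duration_ms(tr)
#' @export
voltage_trace <- function(v_mv, sample_rate, stim_times_ms = numeric(),
                          v_rest = NULL) {
  if (length(v_mv) == 0L) abort("A voltage trace needs at least one sample.")
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  duration_ms <- length(v_mv) / sample_rate * 1000
  if (length(stim_times_ms) && is.unsorted(stim_times_ms)) {
    abort("`stim_times_ms` must be sorted.")
  }
  if (length(stim_times_ms) && max(stim_times_ms) > duration_ms) {
    abort("Stimulus times must lie within the trace duration.")
  }
  out <- tibble::tibble(
    time_s = (seq_along(v_mv) - 1) / sample_rate,
    v_mv = as.numeric(v_mv)
  )
  attr(out, "sample_rate") <- sample_rate
  attr(out, "stim_times_ms") <- as.numeric(stim_times_ms)
  attr(out, "v_rest") <- v_rest %||% median(out$v_mv)
  class(out) <- c("voltage_trace", class(out))
  out
}

#' @rdname voltage_trace
#' @param trace A `voltage_trace`.
#' @export
trace_duration_ms <- function(trace) {
  nrow(trace) / attr(trace, "sample_rate") * 1000
}

#' @exportS3Method ggplot2::autoplot
autoplot.voltage_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$v_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Membrane potential (mV)")
  stims <- attr(object, "stim_times_ms")
  if (length(stims)) {
    p <- p + ggplot2::geom_vline(
      xintercept = stims / 1000, colour = "firebrick",
      linetype = "dashed", linewidth = 0.2
    )
  }
  p
}

# difference-of-exponentials event kernel, normalized to unit peak, sampled
# at dt_ms spacing over ~8 decay constants
quantal_kernel <- function(rise_tau, decay_tau, dt_ms) {
  t_ms <- seq(0, 8 * decay_tau, by = dt_ms)
  k <- exp(-t_ms / decay_tau) - exp(-t_ms / rise_tau)
  k / max(k)
}

# add `amplitude * kernel` starting at sample index i0 (1-based), clipped
# to the trace length
add_kernel <- function(v, i0, amplitude, kernel) {
  n <- length(v)
  if (i0 > n) return(v)
  idx <- i0:min(n, i0 + length(kernel) - 1L)
  v[idx] <- v[idx] + amplitude * kernel[seq_along(idx)]
  v
}
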