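#' Quantal amplitude and kinetics parameters
#'
#' Describes the postsynaptic response to a single vesicle (one quantum):
#' the mean depolarization it produces, its trial-to-trial variability, and
#' the rise/decay kinetics of the stereotyped event waveform.
#'
#' @param q_mean Mean single-quantum depolarization in mV (default 0.61 mV,
#'   the control miniature endplate potential amplitude scale).
#' @param q_cv Coefficient of variation of quantal amplitude (dimensionless).
#' @param rise_tau,decay_tau Rise and decay time constants of the
#'   difference-of-exponentials event kernel, in ms. `rise_tau` must be
#'   smaller than `decay_tau`.
#'
#' @return An object of class `quantal_params`.
#' @examples
#' quantal_params(q_mean = 0.61, q_cv = 0.3)
#' @export
quantal_params <- function(q_mean = 0.61, q_cv = 0.3,
                           rise_tau = 0.5, decay_tau = 5) {
  check_number(q_mean, "q_mean", lower = 0, strict_lower = TRUE)
  check_number(q_cv, "q_cv", lower = 0)
  check_number(rise_tau, "rise_tau", lower = 0, strict_lower = TRUE)
  check_number(decay_tau, "decay_tau", lower = 0, strict_lower = TRUE)
  if (rise_tau >= decay_tau) {
    abort("`rise_tau` must be strictly smaller than `decay_tau`.")
  }
  structure(
    list(q_mean = q_mean, q_cv = q_cv,
         rise_tau = rise_tau, decay_tau = decay_tau),
    class = "quantal_params"
  )
}

#' Presynaptic release model
#'
#' Binomial release from a depletable readily releasable pool (RRP):
#' each stimulus releases `Binomial(pool, p)` vesicles, the pool is
#' decremented and replenished continuously, and the release probability is
#' transiently facilitated after each stimulus.
#'
#' @param pool_size Number of vesicles in the readily releasable pool (N).
#' @param p0 Per-vesicle release probability at the first stimulus, in
#'   `[0, 1]`.
#' @param facilitation_increment Additive increase in release probability
#'   after each stimulus; decays exponentially with `facilitation_tau`.
#'   Facilitated probability is clamped at 1.
#' @param facilitation_tau Facilitation decay time constant in ms.
#' @param replenishment_rate Vesicles restored to the pool per ms; the pool
#'   never exceeds `pool_size`.
#'
#' @return An object of class `release_model`.
#' @examples
#' release_model(pool_size = 640, p0 = 0.027)
#' @export
release_model <- function(pool_size = 640, p0 = 0.027,
                          facilitation_increment = 0,
                          facilitation_tau = 50,
                          replenishment_rate = 0) {
  if (!is.numeric(pool_size) || length(pool_size) != 1L ||
      pool_size < 0 || pool_size != floor(pool_size)) {
    abort("`pool_size` must be a single non-negative integer.")
  }
  check_number(p0, "p0", lower = 0, upper = 1)
  check_number(facilitation_increment, "facilitation_increment",
               lower = 0, upper = 1)
  check_number(facilitation_tau, "facilitation_tau",
               lower = 0, strict_lower = TRUE)
  check_number(replenishment_rate, "replenishment_rate", lower = 0)
  structure(
    list(pool_size = as.integer(pool_size), p0 = p0,
         facilitation_increment = facilitation_increment,
         facilitation_tau = facilitation_tau,
         replenishment_rate = replenishment_rate),
    class = "release_model"
  )
}

#' Postsynaptic membrane and recording model
#'
#' Resting and reversal potentials, the nonlinear-summation shape factor
#' used by the forward saturation model, recording noise and sampling rate.
#'
#' The defaults (`v_rev = 0` mV, `f_sat = 0.8`) are the conventional values
#' for the McLachlan-Martin nonlinear-summation correction at the endplate;
#' both are configurable because they are rarely measured directly.
#'
#' @param v_rest Resting membrane potential in mV (negative).
#' @param v_rev Synaptic reversal potential in mV; must exceed `v_rest`.
#' @param f_sat Nonlinear-summation shape factor in `[0, 1]`; 0 disables
#'   saturation.
#' @param noise_sd Recording noise standard deviation in mV.
#' @param sample_rate Sampling rate in Hz.
#'
#' @return An object of class `membrane_model`.
#' @examples
#' membrane_model(v_rest = -50)
#' @export
membrane_model <- function(v_rest = -70, v_rev = 0, f_sat = 0.8,
                           noise_sd = 0.05, sample_rate = 10000) {
  check_number(v_rest, "v_rest")
  check_number(v_rev, "v_rev")
  if (v_rest >= v_rev) abort("`v_rest` must be below `v_rev`.")
  check_number(f_sat, "f_sat", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  structure(
    list(v_rest = v_rest, v_rev = v_rev, f_sat = f_sat,
         noise_sd = noise_sd, sample_rate = sample_rate),
    class = "membrane_model"
  )
}

#' @export
print.quantal_params <- function(x, ...) {
  cat(sprintf(
    "<quantal_params> q_mean %.3g mV, cv %.3g, rise %.3g ms, decay %.3g ms\n",
    x$q_mean, x$q_cv, x$rise_tau, x$decay_tau
  ))
  invisible(x)
}

#' @export
print.release_model <- function(x, ...) {
  cat(sprintf(
    "<release_model> N %d, p0 %.4g, facil +%.3g (tau %.3g ms), repl %.3g /ms\n",
    x$pool_size, x$p0, x$facilitation_increment, x$facilitation_tau,
    x$replenishment_rate
  ))
  invisible(x)
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf(
    "<membrane_model> v_rest %g mV, v_rev %g mV, f_sat %.3g, noise %.3g mV, %g Hz\n",
    x$v_rest, x$v_rev, x$f_sat, x$noise_sd, x$sample_rate
  ))
  invisible(x)
}
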