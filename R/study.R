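#' Simulate one junction's recording session
#'
#' Produces the two traces quantal analysis needs from a single
#' neuromuscular junction: a spontaneous recording (miniature endplate
#' potentials) and an evoked low-frequency train.
#'
#' @param release A [release_model()].
#' @param quantal A [quantal_params()].
#' @param membrane A [membrane_model()].
#' @param mepp_rate_per_min Spontaneous event rate, events/min.
#' @param mepp_duration_s Spontaneous recording duration, s.
#' @param n_epp Number of evoked stimuli.
#' @param epp_freq_hz Evoked stimulation frequency, Hz.
#' @param seed Integer seed.
#' @return List with elements `mepp` and `epp`, each a `simulated_trace`.
#' @export
simulate_junction <- function(release, quantal, membrane,
                              mepp_rate_per_min = 8.97,
                              mepp_duration_s = 60,
                              n_epp = 40, epp_freq_hz = 1, seed = 1) {
  list(
    mepp = simulate_spontaneous(mepp_rate_per_min, mepp_duration_s,
                                quantal, membrane,
                                seed = derive_seed(seed, 1)),
    epp = simulate_train(release, quantal, membrane,
                         stim_times_ms = 20 + (seq_len(n_epp) - 1) *
                           1000 / epp_freq_hz,
                         seed = derive_seed(seed, 2))
  )
}

#' Quantal analysis of one junction
#'
#' Runs the full per-junction pipeline: miniature-event detection on the
#' spontaneous trace, evoked-amplitude measurement on the stimulated
#' trace, amplitude conditioning (nonlinear-summation correction at the
#' fiber's own resting potential, then normalization to -50 mV) and the
#' direct-method quantal content. A junction is `analysis_grade` when it
#' yields at least `min_mepps` miniatures and `min_epps` evoked responses.
#'
#' @param mepp_trace,epp_trace [voltage_trace()] objects (the spontaneous
#'   trace must carry no stimulus annotations; the evoked trace must).
#' @param v_rev Reversal potential used in conditioning, mV.
#' @param f Nonlinear-summation factor.
#' @param threshold_sd,min_interval_ms Passed to [detect_mepps()].
#' @param epp_window_ms Passed to [measure_epps()].
#' @param min_mepps,min_epps Analysis-grade thresholds (defaults 7 and 40).
#' @return A one-row tibble: `n_mepp`, `mepp_amplitude`,
#'   `mepp_freq_per_min`, `n_epp`, `epp_amplitude`, `quantal_content`,
#'   `v_rest`, `analysis_grade`.
#' @export
analyze_junction <- function(mepp_trace, epp_trace, v_rev = 0, f = 0.8,
                             threshold_sd = 3, min_interval_ms = 5,
                             epp_window_ms = 10,
                             min_mepps = 7, min_epps = 40) {
  v_rest_m <- attr(mepp_trace, "v_rest")
  v_rest_e <- attr(epp_trace, "v_rest")
  mepps <- detect_mepps(mepp_trace, threshold_sd = threshold_sd,
                        min_interval_ms = min_interval_ms)
  epps <- measure_epps(epp_trace, window_ms = epp_window_ms)
  mepp_amp <- if (nrow(mepps)) {
    mean(condition_amplitudes(mepps$amplitude_mv, v_rest_m, v_rev, f))
  } else NA_real_
  epp_amp <- if (nrow(epps)) {
    mean(condition_amplitudes(epps$amplitude_mv, v_rest_e, v_rev, f))
  } else NA_real_
  qc <- if (!is.na(mepp_amp) && !is.na(epp_amp) && mepp_amp > 0) {
    quantal_content_direct(epp_amp, mepp_amp)
  } else NA_real_
  tibble::tibble(
    n_mepp = nrow(mepps),
    mepp_amplitude = mepp_amp,
    mepp_freq_per_min = nrow(mepps) / (trace_duration_ms(mepp_trace) / 60000),
    n_epp = nrow(epps),
    epp_amplitude = epp_amp,
    quantal_content = qc,
    v_rest = v_rest_m,
    analysis_grade = nrow(mepps) >= min_mepps && nrow(epps) >= min_epps
  )
}

#' Facilitation increment reproducing a target paired-pulse ratio
#'
#' Inverts the release model's expectation for a two-pulse protocol: the
#' expected ratio of second to first response is
#' `(p0 + inc * exp(-isi/tau)) / p0 * (1 - p0)` (the `1 - p0` factor is
#' first-pulse pool depletion), so the increment needed for a target ratio
#' follows in closed form.
#'
#' @param target_ratio_pct Target paired-pulse ratio in percent.
#' @param release A [release_model()] providing `p0` and
#'   `facilitation_tau`.
#' @param interval_ms Inter-stimulus interval in ms.
#' @return The `facilitation_increment` value.
#' @export
ppf_increment_for_target <- function(target_ratio_pct, release,
                                     interval_ms = 10) {
  r <- target_ratio_pct / 100
  inc <- (r / (1 - release$p0) - 1) * release$p0 /
    exp(-interval_ms / release$facilitation_tau)
  if (inc < 0) abort("Target ratio implies depression, not facilitation.")
  inc
}

#' Study configuration
#'
#' Bundles the seed, problem sizes and analysis parameters for
#' [run_study()]. The defaults run a desk-scale version of the full study
#' in a few minutes; the group-level parameterization (means, rates,
#' probabilities) always comes from [published_group_stats()].
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_junctions Junctions per group for the 1 Hz quantal cohort.
#' @param mepp_duration_s Spontaneous recording length per junction, s.
#' @param n_epp Evoked stimuli per junction at 1 Hz.
#' @param n_ppf_junctions,n_ppf_sweeps Paired-pulse cohort size and sweeps
#'   averaged per junction.
#' @param n_trains Junctions per group for the 50 Hz pool-depletion
#'   protocol.
#' @param n_pulses Stimuli per 50 Hz train.
#' @param n_muscles Muscles per group for the tension protocol.
#' @param n_endplates Endplates per group for innervation classification.
#' @param f_sat,v_rev Conditioning parameters.
#' @param threshold_sd,min_interval_ms Miniature-detection parameters.
#' @param fit_range Pulse range for the pool fit; `NULL` uses
#'   `2:n_pulses` (the depletion model is linear over the whole train when
#'   replenishment is negligible).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1, n_junctions = 12, mepp_duration_s = 60,
                         n_epp = 40, n_ppf_junctions = 12, n_ppf_sweeps = 20,
                         n_trains = 15, n_pulses = 40, n_muscles = 9,
                         n_endplates = 500, f_sat = 0.8, v_rev = 0,
                         threshold_sd = 3, min_interval_ms = 5,
                         fit_range = NULL) {
  cfg <- as.list(environment())
  cfg$fit_range <- fit_range %||% seq(2L, n_pulses)
  class(cfg) <- "study_config"
  cfg
}

# truncated-normal helper for strictly positive physiological quantities
rnorm_pos <- function(n, mean, sd, floor = .Machine$double.eps) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= floor)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= floor]
  }
  out
}

study_groups <- function() c("control", "smndelta7")

# fetch one measure row from the published table as a two-group list
pub_row <- function(stats, msr, tp = NULL) {
  r <- dplyr::filter(stats, .data$measure == msr,
                     if (is.null(tp)) TRUE else .data$timepoint == tp)
  if (nrow(r) != 1) abort(sprintf("Ambiguous published measure '%s'.", msr))
  as.list(r)
}

#' Run the desk-scale study
#'
#' Simulates every input class of the study at the published group scale
#' and pushes each through its analysis: quantal cohort (miniature and
#' evoked recordings at 1 Hz), paired-pulse facilitation, 50 Hz
#' pool-depletion trains with Elmqvist-Quastel extrapolation and release
#' probability, muscle tension (indirect/direct ratio per frequency,
#' specific force), and the morphometry battery (synapse counts and
#' densities, innervation classification, dorsal-root axon counts,
#' stereological proprioceptive-cell totals, microglia density and
#' association, postsynaptic-density fraction). Identical configuration
#' and seed give identical reports.
#'
#' @param config A [study_config()].
#' @return An object of class `study_report`: a named list of result
#'   tibbles plus the configuration.
#' @examples
#' \donttest{
#' rep <- run_study(study_config(seed = 42, n_junctions = 4, n_trains = 4,
#'                               mepp_duration_s = 30))
#' rep$group_results
#' }
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stats <- published_group_stats()
  seed <- config$seed
  groups <- study_groups()

  ## ---- quantal cohort at 1 Hz -------------------------------------------
  qc_pub <- pub_row(stats, "quantal_content")
  mepp_pub <- pub_row(stats, "mepp_amplitude")
  freq_pub <- pub_row(stats, "mepp_frequency")
  rrp_pub <- pub_row(stats, "rrp_size")
  pr_pub <- pub_row(stats, "release_probability")

  grp_par <- list(
    control = list(q50 = mepp_pub$control_mean, rate = freq_pub$control_mean,
                   pool = round(rrp_pub$control_mean),
                   m = qc_pub$control_mean, p50 = pr_pub$control_mean),
    smndelta7 = list(q50 = mepp_pub$smndelta7_mean,
                     rate = freq_pub$smndelta7_mean,
                     pool = round(rrp_pub$smndelta7_mean),
                     m = qc_pub$smndelta7_mean, p50 = pr_pub$smndelta7_mean)
  )

  junctions <- purrr::map_dfr(seq_along(groups), function(gi) {
    g <- groups[gi]
    par <- grp_par[[g]]
    purrr::map_dfr(seq_len(config$n_junctions), function(j) {
      s <- derive_seed(seed, 100 * gi + j)
      v_rest <- withr::with_seed(derive_seed(s, 99), rnorm(1, -68, 3))
      memb <- membrane_model(v_rest = v_rest, v_rev = config$v_rev,
                             f_sat = config$f_sat)
      # quantal size scales with the fiber's driving force; conditioning
      # rescales it back to the -50 mV reference
      q <- quantal_params(q_mean = par$q50 * (config$v_rev - v_rest) / 50)
      # at 1 Hz the pool fully recovers between stimuli; replenishment is
      # set fast enough that each response draws on a full pool
      rel <- release_model(pool_size = par$pool, p0 = par$m / par$pool,
                           replenishment_rate = par$pool / 100)
      sim <- simulate_junction(rel, q, memb,
                               mepp_rate_per_min = par$rate,
                               mepp_duration_s = config$mepp_duration_s,
                               n_epp = config$n_epp, seed = s)
      dplyr::mutate(
        analyze_junction(sim$mepp$trace, sim$epp$trace,
                         v_rev = config$v_rev, f = config$f_sat,
                         threshold_sd = config$threshold_sd,
                         min_interval_ms = config$min_interval_ms),
        group = g, junction = sprintf("%s_j%02d", g, j), .before = 1
      )
    })
  })
  junction_summary <- summarize_junctions(junctions, control = "control")

  ## ---- paired-pulse facilitation ----------------------------------------
  ppf_pub <- pub_row(stats, "paired_pulse_ratio")
  ppf_target <- c(control = ppf_pub$control_mean,
                  smndelta7 = ppf_pub$smndelta7_mean)
  memb50 <- membrane_model(v_rest = -50, v_rev = config$v_rev,
                           f_sat = config$f_sat)
  q50 <- function(par) quantal_params(q_mean = par$q50)
  ppf <- purrr::map_dfr(seq_along(groups), function(gi) {
    g <- groups[gi]
    par <- grp_par[[g]]
    base_rel <- release_model(pool_size = par$pool, p0 = par$p50)
    inc <- ppf_increment_for_target(ppf_target[[g]], base_rel, 10)
    rel <- release_model(pool_size = par$pool, p0 = par$p50,
                         facilitation_increment = inc)
    purrr::map_dfr(seq_len(config$n_ppf_junctions), function(j) {
      s <- derive_seed(seed, 2000 + 100 * gi + j)
      amps <- purrr::map_dfr(seq_len(config$n_ppf_sweeps), function(k) {
        sim <- simulate_train(rel, q50(par), memb50, c(10, 20),
                              seed = derive_seed(s, k))
        m <- measure_epps(sim$trace, window_ms = 8,
                          subtract_prev_decay = TRUE)
        a <- condition_amplitudes(pmax(m$amplitude_mv, 0), -50,
                                  config$v_rev, config$f_sat)
        tibble::tibble(a1 = a[1], a2 = a[2])
      })
      tibble::tibble(group = g, junction = j,
                     ppf_pct = paired_pulse_ratio(mean(amps$a1),
                                                  mean(amps$a2)))
    })
  })
  ppf_cmp <- group_compare(ppf, value = "ppf_pct", control = "control")

  ## ---- 50 Hz trains: pool size and release probability ------------------
  trains <- purrr::map_dfr(seq_along(groups), function(gi) {
    g <- groups[gi]
    par <- grp_par[[g]]
    rel <- release_model(pool_size = par$pool, p0 = par$p50)
    q <- q50(par)
    stim <- 10 + (seq_len(config$n_pulses) - 1) * 20
    purrr::map_dfr(seq_len(config$n_trains), function(j) {
      s <- derive_seed(seed, 4000 + 100 * gi + j)
      sim <- simulate_train(rel, q, memb50, stim, seed = s)
      epps <- measure_epps(sim$trace, window_ms = 10)
      mepp_ref <- mean(condition_amplitudes(
        sample_quantal_amplitude(q, 30, seed = derive_seed(s, 7)),
        -50, config$v_rev, config$f_sat
      ))
      m_i <- condition_amplitudes(pmax(epps$amplitude_mv, 0), -50,
                                  config$v_rev, config$f_sat) / mepp_ref
      fit <- tryCatch(estimate_rrp(m_i, fit_range = config$fit_range),
                      error = function(e) NULL)
      tibble::tibble(
        group = g, junction = j,
        rrp = if (is.null(fit)) NA_real_ else fit$rrp,
        p_release = if (is.null(fit)) NA_real_ else fit$p_release,
        m_first = m_i[1]
      )
    })
  })
  trains_ok <- dplyr::filter(trains, !is.na(.data$rrp))
  rrp_cmp <- group_compare(trains_ok, value = "rrp", control = "control")
  pr_cmp <- group_compare(trains_ok, value = "p_release", control = "control")

  ## ---- muscle tension ----------------------------------------------------
  sf_pub <- pub_row(stats, "specific_force")
  csa_pub <- pub_row(stats, "muscle_csa")
  ratio_pub <- purrr::map_dfr(c(1, 10, 40, 100), function(fq) {
    r <- pub_row(stats, sprintf("stim_ratio_%dhz", fq))
    tibble::tibble(frequency = fq, control = r$control_mean,
                   smndelta7 = r$smndelta7_mean)
  })
  n_stim_for <- c(`1` = 1, `10` = 10, `40` = 20, `100` = 50)
  fusion <- 0.25
  # tetanic plateau per unit twitch amplitude (deterministic calibration)
  plateau_unit <- peak_force(simulate_tension(1, stim_freq = 100,
                                              n_stim = 50, fusion = fusion))
  tension <- purrr::map_dfr(seq_along(groups), function(gi) {
    g <- groups[gi]
    sf_mean <- if (g == "control") sf_pub$control_mean else sf_pub$smndelta7_mean
    sf_sd <- if (g == "control") {
      sf_pub$control_sem * sqrt(sf_pub$control_n)
    } else sf_pub$smndelta7_sem * sqrt(sf_pub$smndelta7_n)
    csa_mean <- if (g == "control") csa_pub$control_mean else csa_pub$smndelta7_mean
    purrr::map_dfr(seq_len(config$n_muscles), function(j) {
      s <- derive_seed(seed, 6000 + 100 * gi + j)
      withr::with_seed(s, {
        csa <- rnorm_pos(1, csa_mean, 0.1 * csa_mean)
        sf <- rnorm_pos(1, sf_mean, sf_sd, floor = 0.3)
        peak_d <- sf * csa / plateau_unit   # twitch amplitude hitting the
                                            # target 100 Hz plateau
        recs <- purrr::map_dfr(c(1, 10, 40, 100), function(fq) {
          r_target <- ratio_pub[[g]][ratio_pub$frequency == fq]
          r_true <- r_target * exp(rnorm(1, 0, 0.03))
          direct <- simulate_tension(peak_d, stim_freq = fq,
                                     n_stim = n_stim_for[[as.character(fq)]],
                                     fusion = fusion, noise_sd = 0.005,
                                     seed = derive_seed(s, fq),
                                     mode = "direct")
          indirect <- simulate_tension(peak_d * r_true, stim_freq = fq,
                                       n_stim = n_stim_for[[as.character(fq)]],
                                       fusion = fusion, noise_sd = 0.005,
                                       seed = derive_seed(s, fq + 1000),
                                       mode = "indirect")
          stim_ratio(summarize_tension(list(indirect, direct)))
        })
        f100 <- peak_force(simulate_tension(peak_d, stim_freq = 100,
                                            n_stim = 50, fusion = fusion,
                                            noise_sd = 0.005,
                                            seed = derive_seed(s, 77),
                                            mode = "direct"))
        dplyr::mutate(recs, group = g, muscle = j, csa_mm2 = csa,
                      specific_force = specific_force(f100, csa),
                      .before = 1)
      })
    })
  })
  tension_ratios <- tension |>
    dplyr::group_by(.data$group, .data$frequency) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio),
                     sem = sd(.data$ratio) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  sf_tab <- dplyr::distinct(tension, .data$group, .data$muscle,
                            .data$specific_force)
  sf_cmp <- group_compare(sf_tab, value = "specific_force",
                          control = "control")

  ## ---- morphometry battery ----------------------------------------------
  sim_norm_cohort <- function(msr, tp, k, round_counts = FALSE) {
    r <- pub_row(stats, msr, tp)
    withr::with_seed(derive_seed(seed, 8000 + k), {
      vals <- c(
        rnorm_pos(r$control_n, r$control_mean,
                  r$control_sem * sqrt(r$control_n)),
        rnorm_pos(r$smndelta7_n, r$smndelta7_mean,
                  r$smndelta7_sem * sqrt(r$smndelta7_n))
      )
      if (round_counts) vals <- round(vals)
      tibble::tibble(
        group = rep(groups, c(r$control_n, r$smndelta7_n)),
        value = vals
      )
    })
  }

  morpho_list <- list()

  # synapse counts per neuron: negative binomial matched to the published
  # mean and SEM, filtered to large included motoneurons
  sc <- pub_row(stats, "synapse_count")
  sc_specs <- tibble::tibble(
    group = groups,
    mean_count = c(sc$control_mean, sc$smndelta7_mean),
    dispersion = c(
      nb_size_from_sem(sc$control_mean, sc$control_sem, sc$control_n),
      nb_size_from_sem(sc$smndelta7_mean, sc$smndelta7_sem, sc$smndelta7_n)
    ),
    n = c(sc$control_n, sc$smndelta7_n),
    area_mean = 550, area_cv = 0.2, p_exclude = 0.02
  )
  sc_tab <- simulate_morphometry(sc_specs, seed = derive_seed(seed, 8101)) |>
    filter_motoneurons(min_area_um2 = 300)
  morpho_list$synapse_count <- list(
    tab = dplyr::transmute(sc_tab, group = .data$group,
                           value = as.numeric(.data$count)),
    tp = "P14"
  )

  # synapse density per 100 um perimeter: counts simulated at the density
  # scale on a fixed 100 um reference perimeter
  sd14 <- pub_row(stats, "synapse_density", "P14")
  sd_specs <- tibble::tibble(
    group = groups,
    mean_count = c(sd14$control_mean, sd14$smndelta7_mean),
    dispersion = c(
      nb_size_from_sem(sd14$control_mean, sd14$control_sem, sd14$control_n),
      nb_size_from_sem(sd14$smndelta7_mean, sd14$smndelta7_sem,
                       sd14$smndelta7_n)
    ),
    n = c(sd14$control_n, sd14$smndelta7_n),
    perimeter_mean = 100, perimeter_cv = 0, area_mean = 550, area_cv = 0.2
  )
  sd_tab <- simulate_morphometry(sd_specs, seed = derive_seed(seed, 8102))
  morpho_list$synapse_density <- list(
    tab = dplyr::transmute(sd_tab, group = .data$group,
                           value = density_per_100um(.data$count,
                                                     .data$perimeter_um)),
    tp = "P14"
  )

  morpho_list$em_terminal_density <- list(
    tab = sim_norm_cohort("em_terminal_density", "P14", 3), tp = "P14")
  morpho_list$psd_length_fraction <- list(
    tab = sim_norm_cohort("psd_length_fraction", "P14", 4), tp = "P14")
  morpho_list$dorsal_root_axons <- list(
    tab = sim_norm_cohort("dorsal_root_axons", "P14", 5, round_counts = TRUE),
    tp = "P14")
  for (tp in c("P4", "P14")) {
    morpho_list[[paste0("microglia_density_", tp)]] <- list(
      tab = sim_norm_cohort("microglia_density", tp,
                            6 + as.integer(tp == "P14")),
      tp = tp)
  }

  # stereological proprioceptive-cell totals: per-animal ganglia with a
  # known cell total spread over 60 sections, 1-in-5 systematic sampling
  pv <- pub_row(stats, "pv_cells")
  pv_tab <- purrr::map_dfr(seq_along(groups), function(gi) {
    g <- groups[gi]
    mu <- if (g == "control") pv$control_mean else pv$smndelta7_mean
    sdev <- if (g == "control") pv$control_sem * sqrt(pv$control_n) else
      pv$smndelta7_sem * sqrt(pv$smndelta7_n)
    n_animal <- if (g == "control") pv$control_n else pv$smndelta7_n
    purrr::map_dfr(seq_len(n_animal), function(a) {
      withr::with_seed(derive_seed(seed, 8500 + 100 * gi + a), {
        total <- round(rnorm_pos(1, mu, sdev))
        n_sections <- 60
        # bell-shaped section profile through the ganglion
        w <- sin(seq(0.1, pi - 0.1, length.out = n_sections))
        per_section <- as.vector(stats::rmultinom(1, total, w / sum(w)))
        start <- sample.int(5, 1)
        sampled <- per_section[seq(start, n_sections, by = 5)]
        tibble::tibble(group = g, animal = a,
                       value = stereology_total(sampled, n_sections),
                       true_total = total)
      })
    })
  })
  morpho_list$pv_cells <- list(
    tab = dplyr::select(pv_tab, "group", "value"), tp = "P14")

  # microglia association: per-animal neuron tables with Bernoulli contacts
  assoc <- pub_row(stats, "microglia_association", "P14")
  assoc_tab <- purrr::map_dfr(seq_along(groups), function(gi) {
    g <- groups[gi]
    p <- (if (g == "control") assoc$control_mean else
      assoc$smndelta7_mean) / 100
    n_animal <- if (g == "control") assoc$control_n else assoc$smndelta7_n
    purrr::map_dfr(seq_len(n_animal), function(a) {
      withr::with_seed(derive_seed(seed, 8700 + 100 * gi + a), {
        neurons <- tibble::tibble(contacted = runif(50) < p)
        tibble::tibble(group = g, animal = a,
                       value = association_fraction(neurons))
      })
    })
  })
  morpho_list$microglia_association <- list(tab = assoc_tab, tp = "P14")

  group_results <- purrr::imap_dfr(morpho_list, function(x, nm) {
    cmp <- group_compare(x$tab, control = "control")
    g <- glance(cmp)
    t2 <- tidy(cmp)
    tibble::tibble(
      measure = sub("_P\\d+$", "", nm), timepoint = x$tp,
      control_mean = t2$mean[1], control_sem = t2$sem[1],
      control_n = t2$n[1],
      test_mean = t2$mean[2], test_sem = t2$sem[2], test_n = t2$n[2],
      t = g$statistic, p_value = g$p_value,
      percent_change = g$percent_change, direction = g$direction
    )
  })

  # innervation classification at the end-stage scale
  innerv_probs <- list(control = c(full = 0.97, partial = 0.02,
                                   denervated = 0.01),
                       smndelta7 = c(full = 0.91, partial = 0.04,
                                     denervated = 0.05))
  innervation <- purrr::map_dfr(seq_along(groups), function(gi) {
    g <- groups[gi]
    withr::with_seed(derive_seed(seed, 8900 + gi), {
      status <- sample(names(innerv_probs[[g]]), config$n_endplates,
                       replace = TRUE, prob = innerv_probs[[g]])
      overlap <- dplyr::case_when(
        status == "full" ~ runif(config$n_endplates, 0.95, 1),
        status == "partial" ~ runif(config$n_endplates, 0.2, 0.8),
        TRUE ~ runif(config$n_endplates, 0, 0.05)
      )
      cls <- classify_innervation(overlap)
      tibble::tibble(group = g,
                     status = factor(levels(cls), levels = levels(cls)),
                     percent = 100 * as.vector(table(cls)) /
                       config$n_endplates)
    })
  })

  structure(
    list(
      config = config,
      junctions = junctions,
      junction_summary = junction_summary,
      ppf = ppf, ppf_comparison = glance(ppf_cmp),
      trains = trains_ok,
      rrp_comparison = glance(rrp_cmp),
      p_release_comparison = glance(pr_cmp),
      tension = tension,
      tension_ratios = tension_ratios,
      specific_force_comparison = glance(sf_cmp),
      group_results = group_results,
      innervation = innervation,
      pv_truth = pv_tab
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d junctions analysed; %d pool-depletion trains\n",
              nrow(x$junctions), nrow(x$trains)))
  cat(sprintf("  morphometry measures: %s\n",
              paste(unique(x$group_results$measure), collapse = ", ")))
  invisible(x)
}

#' Write a study report to delimited tables
#'
#' Each tabular element of the report is written as a tab-separated file;
#' a YAML run log records the configuration, seed, configuration hash and
#' package version so any table can be regenerated.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if absent).
#' @param overwrite Allow replacing existing tables.
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir, overwrite = FALSE) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tabs <- purrr::keep(report, is.data.frame)
  cfg_hash <- rlang::hash(report$config)
  for (nm in names(tabs)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    if (file.exists(path) && !overwrite) {
      abort(sprintf("'%s' exists; pass `overwrite = TRUE`.", path))
    }
    out <- dplyr::mutate(tibble::as_tibble(tabs[[nm]]),
                         config_hash = cfg_hash)
    readr::write_tsv(out, path, progress = FALSE)
  }
  log <- list(
    config = unclass(report$config)[setdiff(names(report$config), "fit_range")],
    fit_range = range(report$config$fit_range),
    config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("nmjquant")),
    written = format(Sys.time(), tz = "UTC")
  )
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}
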