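#' Write and read voltage traces as plain-text tables
#'
#' A trace is stored as a two-column tab-separated file (`time_s`, `v_mv`)
#' with a YAML sidecar (`<path>.meta.yaml`) carrying the sampling rate,
#' resting potential, stimulus annotations and an optional protocol label.
#'
#' @param trace A [voltage_trace()].
#' @param path Output path for the table; the sidecar is written next to it.
#' @param protocol Optional protocol label (`"mepp"`, `"epp1hz"`,
#'   `"paired"`, `"train50hz"`).
#' @param overwrite Allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, protocol = NULL, overwrite = FALSE) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (file.exists(path) && !overwrite) {
    abort(sprintf("'%s' exists; pass `overwrite = TRUE` to replace it.", path))
  }
  readr::write_tsv(tibble::tibble(time_s = trace$time_s, v_mv = trace$v_mv),
                   path, progress = FALSE)
  meta <- list(
    sample_rate = attr(trace, "sample_rate"),
    v_rest = attr(trace, "v_rest"),
    stim_times_ms = as.numeric(attr(trace, "stim_times_ms")),
    protocol = protocol
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    time_s = readr::col_double(), v_mv = readr::col_double()
  ), progress = FALSE)
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path)) {
    abort(sprintf("Missing sidecar metadata '%s'.", meta_path))
  }
  meta <- yaml::read_yaml(meta_path)
  tr <- voltage_trace(tab$v_mv, meta$sample_rate,
                      stim_times_ms = as.numeric(meta$stim_times_ms %||%
                                                   numeric()),
                      v_rest = meta$v_rest)
  attr(tr, "protocol") <- meta$protocol
  tr
}

known_protocols <- c("mepp", "epp1hz", "paired", "train50hz")
known_modes <- c("indirect", "direct")

#' Read and validate a recording manifest
#'
#' A manifest lists the files of a study as a delimited table. Ephys
#' manifests need columns `id`, `group`, `protocol`, `file`; tension
#' manifests need `id`, `group`, `mode`, `frequency`, `file` (plus
#' optionally `csa_mm2`); morphometry manifests are count tables with
#' `unit_id`, `animal_id`, `group`, `count` (optional `perimeter_um`,
#' `area_um2`, `include_flag`).
#'
#' @param path Path to a tab- or comma-separated manifest.
#' @param kind One of `"ephys"`, `"tension"`, `"morphometry"`.
#' @return The validated manifest as a tibble.
#' @export
read_manifest <- function(path, kind = c("ephys", "tension", "morphometry")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("Manifest '%s' does not exist.", path))
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                         progress = FALSE)
  required <- switch(kind,
    ephys = c("id", "group", "protocol", "file"),
    tension = c("id", "group", "mode", "frequency", "file"),
    morphometry = c("unit_id", "animal_id", "group", "count")
  )
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    abort(sprintf("Manifest is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  id_col <- if (kind == "morphometry") "unit_id" else "id"
  dup <- m[[id_col]][duplicated(m[[id_col]])]
  if (length(dup)) {
    abort(sprintf("Duplicate %s in manifest: %s.", id_col,
                  paste(unique(dup), collapse = ", ")))
  }
  if (kind == "ephys") {
    bad <- setdiff(unique(m$protocol), known_protocols)
    if (length(bad)) {
      abort(sprintf("Unknown protocol(s): %s.", paste(bad, collapse = ", ")))
    }
  }
  if (kind == "tension") {
    bad <- setdiff(unique(m$mode), known_modes)
    if (length(bad)) {
      abort(sprintf("Unknown mode(s): %s.", paste(bad, collapse = ", ")))
    }
  }
  if (kind == "morphometry" && any(m$count < 0, na.rm = TRUE)) {
    abort("Counts must be non-negative.")
  }
  m
}

#' Published group summary statistics
#'
#' Reference group means (mean, SEM, n; control vs SMNDelta7) for every
#' quantified readout of the study: miniature/evoked endplate potentials,
#' quantal content, paired-pulse ratio, pool size and release probability,
#' muscle force ratios and specific force, synapse counts and densities,
#' dorsal-root axon and proprioceptive cell counts, microglia density and
#' association, and postsynaptic-density measurements. These are the
#' inputs for recomputing every derived percentage and for parameterizing
#' the simulator at the study's scale.
#'
#' @return A tibble with columns `measure`, `timepoint`, `units`,
#'   `control_mean`, `control_sem`, `control_n`, `smndelta7_mean`,
#'   `smndelta7_sem`, `smndelta7_n`.
#' @examples
#' head(published_group_stats())
#' @export
published_group_stats <- function() {
  path <- system.file("extdata", "published_group_stats.csv",
                      package = "nmjquant", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    measure = readr::col_character(),
    timepoint = readr::col_character(),
    units = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Negative-binomial size parameter matching a printed SEM
#'
#' Given a group mean, SEM and n for count data, returns the
#' negative-binomial `size` (dispersion) whose variance matches
#' `n * sem^2`; returns `Inf` (the Poisson limit) when the implied
#' variance does not exceed the mean.
#'
#' @param mean_count Group mean count.
#' @param sem Standard error of the mean.
#' @param n Number of units.
#' @return The `size` parameter for [stats::rnbinom()].
#' @export
nb_size_from_sem <- function(mean_count, sem, n) {
  v <- n * sem^2
  if (v <= mean_count) return(Inf)
  mean_count^2 / (v - mean_count)
}
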