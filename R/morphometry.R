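#' Percent change relative to a control mean
#'
#' Sign convention: positive values are reductions relative to control
#' (`100 * (control - test) / control`); negative values are increases.
#' This is the arithmetic used for every "reduced by X%" statement derived
#' from two group means.
#'
#' @param control_mean,test_mean Group means; `control_mean` must be
#'   non-zero.
#' @return Signed percent change (positive = reduction).
#' @examples
#' percent_change(64.3, 46.1) # ~28.3
#' percent_change(49.0, 65.5) # ~ -33.7 (an increase)
#' @export
percent_change <- function(control_mean, test_mean) {
  if (any(control_mean == 0)) abort("`control_mean` must be non-zero.")
  100 * (control_mean - test_mean) / control_mean
}

#' Two-group comparison with Student's t-test
#'
#' Classic pooled-variance two-sample two-tailed t-test (Welch's unequal
#' variance form behind `welch = TRUE`). Reports per-group mean, SEM and n,
#' the t statistic and p-value, and the percent change of the test group
#' relative to the control group (positive = reduction, negative =
#' increase; the direction is also reported explicitly).
#'
#' @param data A data frame with a group column and a value column.
#' @param value Name of the value column (default `"value"`).
#' @param group Name of the group column (default `"group"`).
#' @param control Control group label; default the first group encountered.
#' @param welch Use Welch's t-test instead of the pooled-variance form.
#'
#' @return An object of class `group_comparison`; use [tidy()] for the
#'   per-group summary and [glance()] for the test result.
#' @examples
#' d <- data.frame(group = rep(c("control", "mutant"), each = 5),
#'                 value = c(10, 11, 9, 10, 10, 7, 8, 7, 8, 7))
#' glance(group_compare(d))
#' @export
group_compare <- function(data, value = "value", group = "group",
                          control = NULL, welch = FALSE) {
  stopifnot(is.data.frame(data))
  if (!all(c(value, group) %in% names(data))) {
    abort(sprintf("`data` must have columns `%s` and `%s`.", group, value))
  }
  x <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  levels_g <- unique(g)
  if (length(levels_g) != 2) abort("Exactly two groups are required.")
  control <- control %||% levels_g[1]
  if (!control %in% levels_g) {
    abort(sprintf("Control group '%s' not present.", control))
  }
  test_grp <- setdiff(levels_g, control)
  xc <- x[g == control]
  xt <- x[g == test_grp]
  if (length(xc) < 2 || length(xt) < 2) {
    abort("Each group needs at least 2 observations.")
  }

  tt <- tryCatch(
    t.test(xt, xc, var.equal = !welch),
    error = function(e) NULL  # degenerate: zero variance in both groups
  )
  if (is.null(tt)) {
    stat <- if (mean(xt) == mean(xc)) 0 else Inf * sign(mean(xt) - mean(xc))
    pval <- if (mean(xt) == mean(xc)) 1 else 0
  } else {
    stat <- unname(tt$statistic)
    pval <- tt$p.value
  }

  pc <- percent_change(mean(xc), mean(xt))
  structure(
    list(
      groups = tibble::tibble(
        group = c(control, test_grp),
        role = c("control", "test"),
        mean = c(mean(xc), mean(xt)),
        sem = c(sd(xc) / sqrt(length(xc)), sd(xt) / sqrt(length(xt))),
        n = c(length(xc), length(xt))
      ),
      statistic = stat, p_value = pval, percent_change = pc,
      direction = if (pc >= 0) "reduction" else "increase",
      method = if (welch) "welch" else "student"
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  g <- x$groups
  cat(sprintf(
    "<group_comparison> %s %.4g +/- %.3g (n=%d) vs %s %.4g +/- %.3g (n=%d)\n",
    g$group[1], g$mean[1], g$sem[1], g$n[1],
    g$group[2], g$mean[2], g$sem[2], g$n[2]
  ))
  cat(sprintf("  t = %.3g, p = %.3g, %.1f%% %s vs control (%s t-test)\n",
              x$statistic, x$p_value, abs(x$percent_change), x$direction,
              x$method))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) x$groups

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value,
    percent_change = x$percent_change, direction = x$direction,
    method = x$method
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(width = 0.6, fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.15
    ) +
    ggplot2::labs(
      y = "Mean +/- SEM", x = NULL,
      subtitle = sprintf("p = %.3g (%.1f%% %s)", object$p_value,
                         abs(object$percent_change), object$direction)
    )
}

#' Filter a morphometry table to analysable motoneurons
#'
#' Retains rows with soma area strictly above `min_area_um2` (alpha
#' motoneurons) and `include_flag` true (the flag encodes "clear nucleus,
#' no necrotic/apoptotic features" from the histology check).
#'
#' @param table A morphometry data frame with columns `area_um2` and
#'   (optionally) `include_flag`.
#' @param min_area_um2 Area threshold in um^2 (default 300; strictly
#'   greater-than).
#' @return The filtered tibble.
#' @examples
#' t <- tibble::tibble(area_um2 = c(299, 300, 301), include_flag = TRUE)
#' filter_motoneurons(t)
#' @export
filter_motoneurons <- function(table, min_area_um2 = 300) {
  stopifnot(is.data.frame(table))
  if (!"area_um2" %in% names(table)) {
    abort("`table` must have an `area_um2` column.")
  }
  out <- tibble::as_tibble(table)
  if (!"include_flag" %in% names(out)) out$include_flag <- TRUE
  dplyr::filter(out, .data$area_um2 > min_area_um2, .data$include_flag)
}

#' Synapse density per 100 um of perimeter
#'
#' @param count Synapse count(s), >= 0.
#' @param perimeter_um Cell perimeter(s) in um, > 0.
#' @return Synapses per 100 um of perimeter.
#' @examples
#' density_per_100um(50, 100) # 50
#' @export
density_per_100um <- function(count, perimeter_um) {
  if (any(perimeter_um <= 0)) abort("`perimeter_um` must be positive.")
  100 * count / perimeter_um
}

#' Classify endplate innervation status
#'
#' Thresholds on the nerve-terminal/receptor overlap fraction: `full` at or
#' above the upper threshold, `denervated` at or below the lower threshold,
#' `partial` in between. The thresholds operationalize a visual
#' classification and are configurable.
#'
#' @param overlap_fraction Overlap fraction(s) in `[0, 1]`.
#' @param full_threshold,denervated_threshold Upper/lower cutoffs
#'   (defaults 0.9 and 0.1).
#' @return A factor with levels `full`, `partial`, `denervated`.
#' @examples
#' classify_innervation(c(1, 0.5, 0))
#' @export
classify_innervation <- function(overlap_fraction, full_threshold = 0.9,
                                 denervated_threshold = 0.1) {
  if (any(overlap_fraction < 0 | overlap_fraction > 1)) {
    abort("`overlap_fraction` must lie in [0, 1].")
  }
  out <- ifelse(overlap_fraction >= full_threshold, "full",
         ifelse(overlap_fraction <= denervated_threshold, "denervated",
                "partial"))
  factor(out, levels = c("full", "partial", "denervated"))
}

#' Stereological total from systematically sampled sections
#'
#' Estimates a whole-structure count (e.g. proprioceptive neurons in a
#' dorsal root ganglion) as the mean count over the sampled sections times
#' the total number of sections cut through the structure. Unbiased under
#' uniform section sampling.
#'
#' @param counts_per_section Counts in the sampled sections (non-empty).
#' @param total_sections Total number of sections through the structure.
#' @return The estimated total count.
#' @examples
#' stereology_total(c(9, 11, 10), 100) # 1000
#' @export
stereology_total <- function(counts_per_section, total_sections) {
  if (!length(counts_per_section)) abort("Empty section sample.")
  if (total_sections < 1) abort("`total_sections` must be >= 1.")
  mean(counts_per_section) * total_sections
}

#' Fraction of neurons contacted by microglia
#'
#' @param table A data frame with a logical `contacted` column and
#'   optionally `include_flag`.
#' @return Percentage of included neurons with a microglial contact.
#' @examples
#' association_fraction(tibble::tibble(contacted = c(TRUE, FALSE,
#'                                                   rep(FALSE, 14))))
#' @export
association_fraction <- function(table) {
  stopifnot(is.data.frame(table), "contacted" %in% names(table))
  tab <- tibble::as_tibble(table)
  if ("include_flag" %in% names(tab)) {
    tab <- dplyr::filter(tab, .data$include_flag)
  }
  if (!nrow(tab)) abort("No included rows.")
  100 * mean(as.logical(tab$contacted))
}
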