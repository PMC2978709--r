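test_that("motoneuron filtering applies the strict area rule and flags", {
  t3 <- tibble::tibble(area_um2 = c(299, 300, 301), include_flag = TRUE)
  expect_identical(nrow(filter_motoneurons(t3, 300)), 1L)

  excluded <- tibble::tibble(area_um2 = c(400, 500), include_flag = FALSE)
  expect_identical(nrow(filter_motoneurons(excluded)), 0L)

  set.seed(1)
  big <- tibble::tibble(area_um2 = c(runif(40, 100, 300), runif(160, 301, 900)))
  expect_identical(nrow(filter_motoneurons(big, 300)), 160L)

  expect_error(filter_motoneurons(tibble::tibble(count = 1)), "area_um2")
})

test_that("synapse density normalizes counts to 100 um of perimeter", {
  expect_equal(density_per_100um(50, 100), 50)
  expect_equal(density_per_100um(30, 60), 50)
  expect_equal(density_per_100um(3 * 50, 3 * 100), density_per_100um(50, 100))
  expect_error(density_per_100um(10, 0), "positive")
})

test_that("innervation classes partition endplates and recover frequencies", {
  expect_identical(as.character(classify_innervation(1)), "full")
  expect_identical(as.character(classify_innervation(0)), "denervated")
  expect_identical(as.character(classify_innervation(0.5)), "partial")

  # multinomial cohort at the end-stage scale
  probs <- c(full = 0.91, partial = 0.04, denervated = 0.05)
  n <- 2000
  overlap <- withr::with_seed(8, {
    status <- sample(names(probs), n, replace = TRUE, prob = probs)
    ifelse(status == "full", runif(n, 0.95, 1),
           ifelse(status == "partial", runif(n, 0.2, 0.8), runif(n, 0, 0.05)))
  })
  cls <- classify_innervation(overlap)
  freqs <- as.vector(table(cls)) / n
  expect_equal(sum(freqs), 1)
  for (i in 1:3) {
    se <- sqrt(probs[i] * (1 - probs[i]) / n)
    expect_lt(abs(freqs[i] - probs[i]), 4 * se)
  }
  expect_error(classify_innervation(1.2), "0, 1")
})

test_that("stereological totals are exact on full samples and unbiased on 1-in-5", {
  expect_equal(stereology_total(rep(10, 20), 100), 1000)

  # exhaustive sampling returns the true sum
  per_section <- c(3, 7, 11, 9, 5)
  expect_equal(stereology_total(per_section, 5), sum(per_section))
  expect_error(stereology_total(numeric(), 10), "Empty")

  # systematic 1-in-5 sampling over 500 seeds: mean within 3 SE of truth
  truth <- 1138; n_sections <- 60
  w <- sin(seq(0.1, pi - 0.1, length.out = n_sections))
  est <- vapply(1:500, function(s) {
    withr::with_seed(s, {
      per_sec <- as.vector(rmultinom(1, truth, w / sum(w)))
      start <- sample.int(5, 1)
      stereology_total(per_sec[seq(start, n_sections, by = 5)], n_sections)
    })
  }, numeric(1))
  se <- sd(est) / sqrt(500)
  expect_lt(abs(mean(est) - truth), 3 * se)
  expect_lt(abs(mean(est) - truth) / truth, 0.03)
})

test_that("microglia association is the percentage of contacted neurons", {
  none <- tibble::tibble(contacted = rep(FALSE, 10))
  expect_equal(association_fraction(none), 0)
  some <- tibble::tibble(contacted = c(rep(TRUE, 2), rep(FALSE, 14)))
  expect_equal(association_fraction(some), 12.5)
  all_c <- tibble::tibble(contacted = rep(TRUE, 5))
  expect_equal(association_fraction(all_c), 100)
  flagged <- tibble::tibble(contacted = c(TRUE, TRUE, FALSE),
                            include_flag = c(FALSE, TRUE, TRUE))
  expect_equal(association_fraction(flagged), 50)
})

test_that("percent change uses the control-referenced sign convention", {
  expect_equal(percent_change(64.3, 46.1), 100 * (64.3 - 46.1) / 64.3)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(5, 0), 100)
  expect_lt(percent_change(49.0, 65.5), 0)  # increases are negative
  expect_error(percent_change(0, 1), "non-zero")
})

test_that("group comparison reports pooled-t results and handles degeneracy", {
  d <- cohort_with_means(64.3, 46.1, n = 10, spread = 4)
  cmp <- group_compare(d, control = "control")
  gl <- glance(cmp)
  expect_equal(gl$percent_change, percent_change(64.3, 46.1),
               tolerance = 1e-12)
  expect_identical(gl$direction, "reduction")

  # pooled t statistic agrees with the closed form
  xc <- d$value[d$group == "control"]; xt <- d$value[d$group == "test"]
  sp2 <- ((length(xc) - 1) * var(xc) + (length(xt) - 1) * var(xt)) /
    (length(xc) + length(xt) - 2)
  t_manual <- (mean(xt) - mean(xc)) / sqrt(sp2 * (1 / length(xc) + 1 / length(xt)))
  expect_equal(gl$statistic, t_manual, tolerance = 1e-12)
  p_manual <- 2 * pt(-abs(t_manual), length(xc) + length(xt) - 2)
  expect_equal(gl$p_value, p_manual, tolerance = 1e-12)

  # Welch flag switches the method
  expect_identical(glance(group_compare(d, welch = TRUE))$method, "welch")

  # identical constant groups: no change, p reported as 1
  const <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                          value = rep(7, 6))
  glc <- glance(group_compare(const))
  expect_equal(glc$percent_change, 0)
  expect_equal(glc$p_value, 1)

  expect_error(group_compare(tibble::tibble(group = "a", value = 1)),
               "two groups")
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_identical(tidy(cmp)$role, c("control", "test"))
})

test_that("the t-test keeps its nominal type-I error under the null", {
  n_rep <- 1500
  rejections <- withr::with_seed(99, {
    vapply(seq_len(n_rep), function(i) {
      d <- tibble::tibble(group = rep(c("a", "b"), each = 8),
                          value = rnorm(16))
      glance(group_compare(d))$p_value < 0.05
    }, logical(1))
  })
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rejections) - 0.05), 3 * se)
})

test_that("negative-binomial size reproduces a printed SEM", {
  size <- nb_size_from_sem(64.3, 3.6, 180)
  expect_equal(64.3 + 64.3^2 / size, 180 * 3.6^2, tolerance = 1e-9)
  expect_identical(nb_size_from_sem(10, 0.1, 5), Inf)
})
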