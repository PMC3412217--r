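test_that("friedman statistic is 0 for undiscriminating data and 6 for perfect agreement", {
  flat <- matrix(5, nrow = 4, ncol = 3)
  expect_equal(friedman_rank_test(flat)$statistic, 0)

  agree <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 3, 9))
  res <- friedman_rank_test(agree)
  expect_equal(res$statistic, 6) # Rj = 3, 6, 9 in the hand formula
  expect_equal(res$df, 2)
  expect_equal(res$p.value, pchisq(6, 2, lower.tail = FALSE))

  expect_error(friedman_rank_test(rbind(c(1, NA, 2), c(3, 2, 1))),
               "missing")
  expect_error(friedman_rank_test(matrix(1:3, 1)), "at least 2")
})

test_that("friedman matches stats::friedman.test including tie handling", {
  withr::with_seed(10, {
    for (i in 1:20) {
      n <- sample(4:10, 1)
      k <- sample(3:5, 1)
      g <- matrix(round(rnorm(n * k), sample(0:1, 1)), n, k) # ties likely
      ref <- stats::friedman.test(g)
      got <- friedman_rank_test(g)
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p.value, unname(ref$p.value), tolerance = 1e-10)
    }
  })
})

test_that("the exact permutation p matches brute-force enumeration on a small grid", {
  withr::with_seed(4, {
    g <- matrix(rnorm(9), 3, 3)
  })
  got <- friedman_rank_test(g, exact = TRUE)

  # oracle: enumerate all (3!)^3 rearrangements, statistic via stats::
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  stat_obs <- unname(stats::friedman.test(g)$statistic)
  count <- 0L
  for (i in 1:6) for (j in 1:6) for (l in 1:6) {
    g2 <- rbind(g[1, perms[i, ]], g[2, perms[j, ]], g[3, perms[l, ]])
    if (unname(stats::friedman.test(g2)$statistic) >= stat_obs - 1e-12) {
      count <- count + 1L
    }
  }
  expect_equal(got$p.value, count / 216)
  expect_equal(got$statistic, stat_obs)
})

test_that("friedman is invariant under monotone transforms of the data", {
  withr::with_seed(12, {
    g <- matrix(runif(24, 1, 5), 6, 4)
  })
  s0 <- friedman_rank_test(g)$statistic
  expect_equal(friedman_rank_test(exp(g))$statistic, s0)
  expect_equal(friedman_rank_test(g^3)$statistic, s0)
})

test_that("within-subject SD follows the Bland-Altman formula and ANOVA identity", {
  expect_equal(within_subject_sd(cbind(c(1, 4, 7), c(1, 4, 7))), 0)
  expect_equal(within_subject_sd(rbind(c(1, 2), c(3, 5))), sqrt(5 / 4))
  expect_error(within_subject_sd(matrix(numeric(0), 0, 2)), "at least one")
  expect_error(within_subject_sd(cbind(1:3, 1:3, 1:3)), "two columns")

  withr::with_seed(8, {
    pairs <- cbind(rnorm(12, 10), rnorm(12, 10))
    # one-way ANOVA with subject as the factor: within-subject mean square
    long <- data.frame(subject = factor(rep(1:12, 2)),
                       value = c(pairs[, 1], pairs[, 2]))
    ms_within <- summary(aov(value ~ subject, data = long))[[1]][
      "Residuals", "Mean Sq"]
    expect_equal(within_subject_sd(pairs), sqrt(ms_within),
                 tolerance = 1e-10)
    # homogeneity: scales linearly with the data
    expect_equal(within_subject_sd(pairs * 3.7),
                 3.7 * within_subject_sd(pairs), tolerance = 1e-12)
  })
})

test_that("pooled prevalence reproduces whole-count arithmetic", {
  expect_equal(pooled_prevalence(c(70, 50, 50), c(10, 10, 10)), 57)
  expect_equal(pooled_prevalence(c(30, 20, 0), c(10, 10, 10)), 17)
  expect_equal(pooled_prevalence(c(0, 0), c(5, 8)), 0)
  expect_error(pooled_prevalence(c(33), c(10)), "whole counts")
  expect_error(pooled_prevalence(c(50, 50), c(10)), "equal length")
})

test_that("report tables are deterministic, exact and round-trip", {
  results <- tidyr::expand_grid(
    subject = 1:3,
    sequence = c("kt_fast", "SENSE"),
    metric = c("rim_thickness", "mpr")
  )
  results$value <- seq_len(nrow(results)) / 2
  results$units <- ifelse(results$metric == "mpr", "ratio", "mm")
  out_dir <- withr::local_tempdir()
  tabs <- report_tables(results, out_dir)

  expect_true(all(file.exists(file.path(
    out_dir, c("per_subject.csv", "table2_image_metrics.csv",
               "table6_flows.csv")
  ))))
  # preset column order: SENSE before kt_fast
  expect_equal(names(tabs$image_metrics), c("metric", "SENSE", "kt_fast"))
  # means of injected values are exact
  m <- results[results$metric == "rim_thickness" &
                 results$sequence == "SENSE", ]
  expect_equal(tabs$image_metrics$SENSE, mean(m$value))
  # round trip
  back <- readr::read_csv(file.path(out_dir, "table6_flows.csv"),
                          show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tabs$flows))

  single <- tibble::tibble(subject = 1, sequence = "SENSE",
                           metric = "mpr", value = 2.5)
  t1 <- report_tables(single, withr::local_tempdir())
  expect_equal(nrow(t1$flows), 1)
  expect_equal(t1$flows$SENSE, 2.5)

  bad <- results
  bad$units[1] <- "furlong"
  expect_error(report_tables(bad, withr::local_tempdir()), "mixed units")
})

test_that("repeated-measures ANOVA companion returns global and pairwise p-values", {
  withr::with_seed(5, {
    g <- matrix(rnorm(40, 10), 10, 4,
                dimnames = list(NULL, c("SENSE", "kt_high", "kt_fast",
                                        "kt_hybrid")))
  })
  res <- rm_anova_bonferroni(g)
  expect_true(res$p_global > 0 && res$p_global <= 1)
  expect_equal(dim(res$pairwise_p), c(3L, 3L))
})
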