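#' Friedman rank test for nonparametric repeated measures
#'
#' Ranks conditions within each subject (mid-ranks for ties) and computes
#' the tie-corrected Friedman chi-square; without ties this reduces to
#' `12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1)`. The p-value uses the
#' chi-square approximation on k-1 degrees of freedom, or — for small
#' samples — the exact permutation distribution over all within-subject
#' orderings.
#'
#' @param grid Numeric matrix or data frame, subjects in rows, conditions
#'   in columns; no missing cells.
#' @param exact Use the exact permutation null (all `(k!)^n` within-subject
#'   rearrangements; feasible for about n <= 6 at k <= 4). Default `FALSE`.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @examples
#' g <- rbind(c(1, 2, 3), c(2, 4, 6), c(1, 3, 9))
#' friedman_rank_test(g) # statistic 6 (all subjects agree on the order)
#' @export
friedman_rank_test <- function(grid, exact = FALSE) {
  grid <- as.matrix(grid)
  if (anyNA(grid)) abort("repeated-measures grid has missing cells")
  n <- nrow(grid); k <- ncol(grid)
  if (n < 2L || k < 2L) abort("need at least 2 subjects and 2 conditions")
  stat <- friedman_statistic(grid)
  if (exact) {
    perms <- permutations_of(k)
    n_perm <- nrow(perms)^n
    if (n_perm > 2e6) {
      abort("exact permutation null too large; use exact = FALSE")
    }
    idx <- rep(1L, n)
    count <- 0L
    total <- 0L
    repeat {
      g2 <- t(vapply(seq_len(n),
                     function(i) grid[i, perms[idx[i], ]], numeric(k)))
      if (friedman_statistic(g2) >= stat - 1e-12) count <- count + 1L
      total <- total + 1L
      j <- 1L
      while (j <= n) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nrow(perms)) break
        idx[j] <- 1L
        j <- j + 1L
      }
      if (j > n) break
    }
    p <- count / total
    method <- "Friedman rank test (exact permutation)"
  } else {
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "Friedman rank test (chi-square approximation)"
  }
  tibble(statistic = stat, df = k - 1, p.value = p, method = method)
}

# tie-corrected Friedman chi-square
friedman_statistic <- function(grid) {
  n <- nrow(grid); k <- ncol(grid)
  r <- t(apply(grid, 1, rank))
  Rj <- colSums(r)
  ties <- sum(apply(r, 1, function(u) {
    tab <- table(u)
    sum(tab^3 - tab)
  }))
  denom <- n * k * (k + 1) - ties / (k - 1)
  if (denom <= 0) return(0)
  12 * sum((Rj - n * (k + 1) / 2)^2) / denom
}

# all permutations of 1..k (k small)
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    left <- sub[, seq_len(pos - 1L), drop = FALSE]
    right <- if (pos <= k - 1L) {
      sub[, pos:(k - 1L), drop = FALSE]
    } else {
      sub[, 0, drop = FALSE]
    }
    cbind(left, k, right)
  }))
}

#' Within-subject standard deviation of repeated measurement pairs
#'
#' The Bland-Altman repeatability summary for duplicate measurements:
#' `sqrt(sum(d^2) / (2 n))` over the within-pair differences `d`, in the
#' units of the measurement. Identical to the square root of the one-way
#' within-subject ANOVA mean square.
#'
#' @param pairs Two-column matrix or data frame, one row per subject, the
#'   two repeated measurements in the columns.
#' @return Within-subject SD.
#' @examples
#' within_subject_sd(rbind(c(1, 2), c(3, 5))) # sqrt(5/4)
#' @export
within_subject_sd <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 1L) abort("need at least one measurement pair")
  if (ncol(pairs) != 2L) abort("pairs must have exactly two columns")
  if (anyNA(pairs)) abort("pairs contain missing values")
  d <- pairs[, 1] - pairs[, 2]
  sqrt(sum(d^2) / (2 * nrow(pairs)))
}

#' Pool per-group prevalences into an overall percentage
#'
#' Converts per-group percentages back to whole event counts, pools them,
#' and returns the overall percentage rounded half away from zero to the
#' nearest integer — the arithmetic behind pooled artifact-prevalence
#' statements such as "57% of all accelerated stress studies".
#'
#' @param per_group_pct Percentages per group.
#' @param per_group_n Group sizes.
#' @param tol Tolerance for the count-wholeness check. Default 1e-6.
#' @return Pooled prevalence in percent, integer-valued.
#' @examples
#' pooled_prevalence(c(70, 50, 50), c(10, 10, 10)) # 57
#' @export
pooled_prevalence <- function(per_group_pct, per_group_n, tol = 1e-6) {
  if (length(per_group_pct) != length(per_group_n)) {
    abort("percentage and size vectors must have equal length")
  }
  if (any(per_group_n <= 0)) abort("group sizes must be positive")
  counts <- per_group_pct * per_group_n / 100
  if (any(abs(counts - round(counts)) > tol * pmax(per_group_n, 1))) {
    abort("percentages do not correspond to whole counts for these n")
  }
  round_half_away(100 * sum(round(counts)) / sum(per_group_n))
}

#' Repeated-measures ANOVA with Bonferroni pairwise comparisons
#'
#' Routine companion analysis for continuous image metrics compared across
#' sequences within subjects, delegated to `stats::aov` (subject-stratified
#' error) and `stats::pairwise.t.test` (paired, Bonferroni-adjusted).
#'
#' @param grid Numeric matrix/data frame, subjects x conditions.
#' @return A list with the `aov` summary p-value and the pairwise p-value
#'   matrix.
#' @export
rm_anova_bonferroni <- function(grid) {
  grid <- as.matrix(grid)
  if (anyNA(grid)) abort("repeated-measures grid has missing cells")
  long <- tibble(
    subject = factor(rep(seq_len(nrow(grid)), ncol(grid))),
    condition = factor(rep(colnames(grid) %||% seq_len(ncol(grid)),
                           each = nrow(grid))),
    value = as.vector(grid)
  )
  fit <- aov(value ~ condition + Error(subject / condition), data = long)
  s <- summary(fit)
  p_global <- s[["Error: subject:condition"]][[1]][["Pr(>F)"]][1]
  pw <- pairwise.t.test(long$value, long$condition, paired = TRUE,
                        p.adjust.method = "bonferroni")
  list(p_global = p_global, pairwise_p = pw$p.value)
}

#' Write summary report tables
#'
#' Emits the study-shaped CSV outputs from tidy per-subject results: a
#' per-subject long table, a mean image-metric x sequence table
#' (`table2_image_metrics.csv`) and a mean flow/MPR x sequence table
#' (`table6_flows.csv`). Column order follows the preset sequence order
#' (`SENSE`, `kt_high`, `kt_fast`, `kt_hybrid`), then any other sequences
#' alphabetically.
#'
#' @param results Tidy tibble with columns `subject`, `sequence`, `metric`,
#'   `value`, and optionally `units` and `condition` (e.g. stress/rest).
#' @param out_dir Output directory (created if needed).
#' @param flow_metrics Metric names routed to the flow table. Default
#'   `c("stress_mbf", "rest_mbf", "mpr")`.
#' @return Invisibly, a named list of the written tibbles.
#' @export
report_tables <- function(results, out_dir,
                          flow_metrics = c("stress_mbf", "rest_mbf",
                                           "mpr")) {
  need <- c("subject", "sequence", "metric", "value")
  if (!all(need %in% names(results))) {
    abort(paste("results must contain columns:",
                paste(need, collapse = ", ")))
  }
  if ("units" %in% names(results)) {
    bad <- results |>
      group_by(.data$metric) |>
      summarise(k = dplyr::n_distinct(.data$units), .groups = "drop") |>
      filter(.data$k > 1L)
    if (nrow(bad)) {
      abort(paste("mixed units within metric(s):",
                  paste(bad$metric, collapse = ", ")))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  preset_order <- c("SENSE", "kt_high", "kt_fast", "kt_hybrid")
  seqs <- unique(results$sequence)
  seq_levels <- c(intersect(preset_order, seqs),
                  sort(setdiff(seqs, preset_order)))
  group_cols <- intersect(c("metric", "condition"), names(results))

  wide_means <- function(df) {
    df |>
      group_by(across(all_of(c(group_cols, "sequence")))) |>
      summarise(value = mean(.data$value), .groups = "drop") |>
      mutate(sequence = factor(.data$sequence, levels = seq_levels)) |>
      arrange(across(all_of(group_cols)), .data$sequence) |>
      tidyr::pivot_wider(names_from = "sequence", values_from = "value")
  }

  long <- arrange(results,
                  across(all_of(intersect(
                    c("subject", "sequence", "condition", "metric"),
                    names(results)
                  ))))
  image <- wide_means(filter(results, !(.data$metric %in% flow_metrics)))
  flows <- wide_means(filter(results, .data$metric %in% flow_metrics))

  readr::write_csv(long, file.path(out_dir, "per_subject.csv"))
  readr::write_csv(image, file.path(out_dir, "table2_image_metrics.csv"))
  readr::write_csv(flows, file.path(out_dir, "table6_flows.csv"))
  invisible(list(per_subject = long, image_metrics = image, flows = flows))
}
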