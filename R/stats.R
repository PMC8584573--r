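#' Per-cluster summary statistics of a score
#'
#' Mean, sample standard deviation (n - 1 denominator), and median of a
#' score within each cluster. The median of an even-sized group is the
#' midpoint of the two central order statistics. A singleton group has an
#' undefined sample SD; it is reported as 0 and flagged.
#'
#' @param values Numeric vector of scores.
#' @param labels Cluster labels, same length as `values`; `NA` pairs are
#'   dropped.
#' @return A tibble with one row per cluster: `cluster`, `n`, `mean`, `sd`,
#'   `median`, `sd_undefined`.
#' @export
group_summary <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  # fix the cluster set before dropping NA values, so a cluster whose every
  # value is missing is reported as empty rather than silently vanishing
  lab_f <- factor(labels)
  keep <- !is.na(values) & !is.na(labels)
  counts <- table(lab_f[keep])
  if (sum(keep) == 0 || any(counts == 0)) {
    empty <- if (sum(keep) == 0) "all" else
      paste(names(which(counts == 0)), collapse = ", ")
    abort(paste0("empty cluster(s): ", empty), class = "pcd_validation_error")
  }
  values <- values[keep]
  labels <- labels[keep]
  tibble(values = values, cluster = as.character(labels)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$values),
      sd = ifelse(dplyr::n() > 1, sd(.data$values), 0),
      median = median(.data$values),
      sd_undefined = dplyr::n() == 1,
      .groups = "drop"
    )
}

#' Tie-corrected Kruskal-Wallis H test
#'
#' Rank-based comparison of k independent groups. With mid-ranks assigned to
#' ties, the statistic is `H = 12 / (N (N + 1)) * sum(n_i * Rbar_i^2) -
#' 3 (N + 1)`, divided by the tie-correction factor
#' `1 - sum(t^3 - t) / (N^3 - N)` over the tie groups. The p-value is the
#' chi-square upper tail with k - 1 degrees of freedom. When every value is
#' identical the correction factor degenerates to 0 and the test reports
#' `H_corrected = 0`, `p = 1`.
#'
#' @param values Numeric vector.
#' @param labels Group labels, same length; `NA` pairs are dropped.
#' @return An object of class `kruskal_result`: `H`, `H_corrected`,
#'   `correction`, `df`, `p_value`, `n`, `k`.
#' @export
kruskal_wallis <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- factor(labels[keep])
  k <- nlevels(labels)
  n <- length(values)
  if (k < 2 || n < 3) {
    abort("need at least 2 groups and 3 observations",
          class = "pcd_validation_error")
  }
  r <- rank(values)  # mid-ranks for ties
  rbar <- tapply(r, labels, mean)
  ni <- tabulate(labels)
  H <- 12 / (n * (n + 1)) * sum(ni * rbar^2) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction <= 0) {
    H_corrected <- 0
    p <- 1
  } else {
    H_corrected <- H / correction
    p <- pchisq(H_corrected, df = k - 1, lower.tail = FALSE)
  }
  structure(
    list(H = H, H_corrected = H_corrected, correction = correction,
         df = k - 1, p_value = p, n = n, k = k),
    class = "kruskal_result"
  )
}

#' @export
print.kruskal_result <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis H test: H = %.4f (tie-corrected %.4f), df = %d, p = %.3g\n",
    x$H, x$H_corrected, x$df, x$p_value))
  invisible(x)
}

#' @describeIn kruskal_wallis One-row tibble of the test result.
#' @method tidy kruskal_result
#' @param x A `kruskal_result`.
#' @param ... Unused.
#' @export
tidy.kruskal_result <- function(x, ...) {
  tibble(statistic = x$H_corrected, H_uncorrected = x$H,
         correction = x$correction, df = x$df, p.value = x$p_value,
         n = x$n, k = x$k)
}

#' @describeIn kruskal_wallis Alias of `tidy()` for a single-test object.
#' @method glance kruskal_result
#' @export
glance.kruskal_result <- function(x, ...) tidy(x, ...)

#' Cluster-wise score summaries and tests for a cohort
#'
#' For each of the six scores, computes per-cluster [group_summary()]
#' statistics and the [kruskal_wallis()] test between clusters, given a
#' label column.
#'
#' @param cohort A cohort tibble.
#' @param labels Vector of cluster labels aligned with `cohort` rows (or the
#'   name of a label column in `cohort`).
#' @param scores Score columns to summarise (default the five predictors
#'   plus JSD).
#' @return A list with `summary` (tibble: score, cluster, n, mean, sd,
#'   median) and `tests` (tibble: score, H, H_corrected, df, p_value).
#' @export
score_group_stats <- function(cohort, labels,
                              scores = c("metalr", "metasvm", "cadd_phred",
                                         "revel", "condel", "jsd")) {
  if (is.character(labels) && length(labels) == 1 &&
      labels %in% names(cohort)) {
    labels <- cohort[[labels]]
  }
  scores <- intersect(scores, names(cohort))
  summaries <- purrr::map_dfr(scores, function(sc) {
    keep <- !is.na(cohort[[sc]]) & !is.na(labels)
    if (!any(keep)) return(tibble())
    dplyr::mutate(group_summary(cohort[[sc]][keep], labels[keep]),
                  score = sc, .before = 1)
  })
  tests <- purrr::map_dfr(scores, function(sc) {
    keep <- !is.na(cohort[[sc]]) & !is.na(labels)
    if (sum(keep) < 3 || length(unique(labels[keep])) < 2) return(tibble())
    kw <- kruskal_wallis(cohort[[sc]][keep], labels[keep])
    tibble(score = sc, H = kw$H, H_corrected = kw$H_corrected, df = kw$df,
           p_value = kw$p_value)
  })
  list(summary = summaries, tests = tests)
}
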