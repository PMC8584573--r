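#' Run the full variant-triage analysis
#'
#' Orchestrates the end-to-end pipeline on a cohort table: read and validate
#' the table, cluster the complete panels in both views (five-score and
#' REVEL-by-Condel scatter), embed by classical MDS, compute per-cluster
#' score summaries and Kruskal-Wallis tests against both the re-clustered
#' labels and (when present) the published labels, tally genes /
#' consequences / novelty, and attach a shared-variant risk annex. Outputs
#' are written to `output_dir` together with a reproducibility manifest;
#' rerunning with the same configuration reproduces the cluster table
#' byte for byte.
#'
#' @param input Path to a cohort table, or a cohort tibble.
#' @param output_dir Directory for outputs (created if missing); `NULL`
#'   skips writing.
#' @param scaling_mode,space,n_restarts,seed Clustering options (see
#'   [cluster_variants()]).
#' @param risk_k Shared-variant counts for the risk annex (default `0:7`).
#' @param config Optional path to a YAML file whose entries override the
#'   arguments above (keys: `input`, `scaling_mode`, `space`, `n_restarts`,
#'   `seed`, `risk_k`).
#' @return A list (invisibly when writing): `cohort`, `clusters` (both
#'   views), `stats` (per label source), `tallies`, `risk`, `manifest`,
#'   `files`.
#' @export
run_triage <- function(input, output_dir = NULL,
                       scaling_mode = "cadd_div33", space = "scores",
                       n_restarts = 25, seed = 20211030, risk_k = 0:7,
                       config = NULL) {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    for (key in c("input", "scaling_mode", "space", "n_restarts", "seed",
                  "risk_k")) {
      if (!is.null(cfg[[key]])) assign(key, cfg[[key]])
    }
  }
  cohort <- if (is.data.frame(input)) input else read_cohort_table(input)

  clusters <- list(
    mds = cluster_variants(cohort, view = "mds", space = space,
                           scaling_mode = scaling_mode,
                           n_restarts = n_restarts, seed = seed),
    scatter = cluster_variants(cohort, view = "scatter",
                               n_restarts = n_restarts, seed = seed)
  )

  full <- complete_panels(cohort)
  stats_out <- list(
    reclustered = score_group_stats(full, clusters$mds$color)
  )
  has_published <- "mds_label" %in% names(cohort) &&
    any(!is.na(cohort$mds_label))
  if (has_published) {
    stats_out$published <- score_group_stats(cohort, "mds_label")
  }

  tallies <- cohort_tallies(cohort)
  risk <- purrr::map(risk_k, shared_variant_risk)
  names(risk) <- paste0("k", risk_k)

  conc <- if (has_published) {
    concordance(clusters$mds, cohort, published_col = "mds_label")
  }

  manifest <- list(
    seed = seed, scaling_mode = scaling_mode, space = space,
    n_restarts = n_restarts,
    n_variants = nrow(cohort), n_clustered = nrow(clusters$mds),
    eigenvalues = head(attr(clusters$mds, "embedding")$eigenvalues, 2),
    tot_wcss = list(mds = attr(clusters$mds, "kmeans")$tot_wcss,
                    scatter = attr(clusters$scatter, "kmeans")$tot_wcss),
    concordance_ari = if (!is.null(conc)) conc$ari,
    config_hash = rlang::hash(list(scaling_mode, space, n_restarts, seed,
                                   risk_k)),
    package_version = as.character(utils::packageVersion("pcdtriage"))
  )

  result <- list(cohort = cohort, clusters = clusters, stats = stats_out,
                 tallies = tallies, risk = risk, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      clusters = file.path(output_dir, "clusters.tsv"),
      summary = file.path(output_dir, "summary.json"),
      tallies = file.path(output_dir, "tallies.json"),
      manifest = file.path(output_dir, "manifest.json")
    )
    cluster_tbl <- dplyr::bind_rows(
      dplyr::mutate(as_tibble(clusters$mds), view = "mds", .before = 1),
      dplyr::mutate(as_tibble(clusters$scatter), view = "scatter",
                    .before = 1)
    )
    readr::write_tsv(cluster_tbl, files$clusters)
    summary_json <- list(
      group_stats = purrr::map(stats_out, function(s) {
        list(summary = s$summary, tests = s$tests)
      }),
      risk = purrr::map(risk, function(r) {
        list(k = r$k, p_any = r$p_any, pmf = unname(r$pmf))
      })
    )
    jsonlite::write_json(summary_json, files$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    jsonlite::write_json(tallies, files$tallies, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    result$files <- files
    return(invisible(result))
  }
  result
}
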