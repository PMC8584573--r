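#' Assemble the five-score matrix over complete panels
#'
#' Keeps exactly the rows whose five predictor scores are all present, in
#' their original order, and applies the chosen scaling. `cadd_div33`
#' (default) divides the PHRED-scaled CADD score by 33 so that it is
#' comparable with the four unit-range scores; `raw` leaves all scores as
#' read; `zscore` standardises each column.
#'
#' @param cohort A cohort tibble.
#' @param scaling_mode One of `"cadd_div33"`, `"raw"`, `"zscore"`.
#' @return A tibble of class `score_matrix` with key columns (`gene`,
#'   `cdna_change`) and score columns `metalr`, `metasvm`, `cadd_scaled`,
#'   `revel`, `condel`; the scaling mode travels as an attribute.
#' @export
build_score_matrix <- function(cohort,
                               scaling_mode = c("cadd_div33", "raw",
                                                "zscore")) {
  scaling_mode <- match.arg(scaling_mode)
  full <- complete_panels(cohort)
  if (nrow(full) < 3) {
    abort("fewer than 3 complete five-score panels",
          class = "pcd_validation_error")
  }
  out <- dplyr::transmute(
    full,
    gene = .data$gene, cdna_change = .data$cdna_change,
    metalr = .data$metalr, metasvm = .data$metasvm,
    cadd_scaled = .data$cadd_phred, revel = .data$revel,
    condel = .data$condel
  )
  if (scaling_mode == "cadd_div33") {
    out$cadd_scaled <- out$cadd_scaled / 33
  } else if (scaling_mode == "zscore") {
    for (col in c("metalr", "metasvm", "cadd_scaled", "revel", "condel")) {
      out[[col]] <- as.numeric(scale(out[[col]]))
    }
  }
  attr(out, "scaling_mode") <- scaling_mode
  class(out) <- c("score_matrix", class(out))
  out
}

score_cols <- function(x) {
  as.matrix(x[, intersect(c("metalr", "metasvm", "cadd_scaled", "revel",
                            "condel"), names(x))])
}

#' Classical multidimensional scaling of a score matrix
#'
#' Embeds the rows in two dimensions by classical (Torgerson) scaling of the
#' Euclidean distance matrix: double-centre the squared distances and take
#' the top two eigenpairs. Eigenvector sign is arbitrary, so axes are
#' oriented deterministically: when orientation columns are supplied (by
#' default the matrix's `condel` and `revel` columns), each coordinate is
#' flipped so that it correlates negatively with its orientation column,
#' placing pathogenic variants at the lower left of the plot.
#'
#' @param x Numeric matrix, data frame, or a [build_score_matrix()] result.
#' @param orient Optional two-column numeric matrix/data frame used to fix
#'   axis signs; `NULL` disables orientation.
#' @return An object of class `mds_embedding`: `points` (n x 2, centred),
#'   `eigenvalues` (descending), `flipped` (logical per axis).
#' @export
classical_mds <- function(x, orient = NULL) {
  m <- score_cols_or_matrix(x)
  if (nrow(m) < 3) {
    abort("classical MDS needs at least 3 rows",
          class = "pcd_validation_error")
  }
  if (is.null(orient) && inherits(x, "score_matrix")) {
    orient <- cbind(x$condel, x$revel)
  }
  fit <- stats::cmdscale(dist(m), k = 2, eig = TRUE)
  ev <- sort(fit$eig, decreasing = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig)))) {
    warn("negative eigenvalues in classical MDS (non-Euclidean distances)")
  }
  pts <- fit$points
  flipped <- c(FALSE, FALSE)
  if (!is.null(orient)) {
    orient <- as.matrix(orient)
    for (j in 1:2) {
      r <- suppressWarnings(cor(pts[, j], orient[, min(j, ncol(orient))]))
      if (!is.na(r) && r > 0) {
        pts[, j] <- -pts[, j]
        flipped[j] <- TRUE
      }
    }
  }
  colnames(pts) <- c("coord1", "coord2")
  structure(
    list(points = pts, eigenvalues = ev, flipped = flipped),
    class = "mds_embedding"
  )
}

score_cols_or_matrix <- function(x) {
  if (inherits(x, "score_matrix")) return(score_cols(x))
  as.matrix(x)
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding: %d points, leading eigenvalues %.4g, %.4g>\n",
              nrow(x$points), x$eigenvalues[1], x$eigenvalues[2]))
  invisible(x)
}

#' @describeIn classical_mds Coordinates as a tibble.
#' @method tidy mds_embedding
#' @param ... Unused.
#' @export
tidy.mds_embedding <- function(x, ...) {
  dplyr::bind_cols(tibble(row = seq_len(nrow(x$points))),
                   as_tibble(x$points))
}

semantic_labels <- c(pathogenic = "red", uncertain = "blue", benign = "green")

# map arbitrary k-means indices to pathogenic/uncertain/benign by
# descending centroid Condel
label_by_condel <- function(km, condel_center) {
  ord <- order(condel_center, decreasing = TRUE)
  lab <- character(length(ord))
  lab[ord] <- names(semantic_labels)
  factor(lab[km$cluster], levels = names(semantic_labels))
}

#' Cluster variants into pathogenicity classes
#'
#' Runs three-group k-means on the cohort in one of two views. The `"mds"`
#' view clusters the five-score matrix (all predictors; see
#' [build_score_matrix()]), either in raw score space (default) or on the
#' two-dimensional classical MDS embedding (`space = "mds"`). The
#' `"scatter"` view clusters the two-column REVEL-by-Condel matrix over rows
#' where both scores are present. Cluster indices are converted to semantic
#' labels by ordering the centroids by their Condel component, descending:
#' highest Condel is `pathogenic` (plot colour red), lowest `benign`
#' (green), middle `uncertain` (blue).
#'
#' @param cohort A cohort tibble.
#' @param view `"mds"` (five scores, default) or `"scatter"`
#'   (REVEL x Condel).
#' @param space For the `"mds"` view: cluster in `"scores"` space (default)
#'   or on the 2-D `"mds"` embedding.
#' @param scaling_mode Scaling of the five-score matrix (see
#'   [build_score_matrix()]).
#' @inheritParams triage_kmeans
#' @return A tibble of class `triage_clusters`: `gene`, `cdna_change`,
#'   `label` (pathogenic/uncertain/benign), `color` (red/blue/green),
#'   `coord1`, `coord2` (MDS coordinates for the `"mds"` view, REVEL and
#'   Condel for `"scatter"`). The `triage_kmeans` fit and the embedding
#'   travel as attributes `kmeans` and `embedding`.
#' @export
cluster_variants <- function(cohort, view = c("mds", "scatter"),
                             space = c("scores", "mds"),
                             scaling_mode = "cadd_div33",
                             k = 3, n_restarts = 25, seed = 20211030) {
  view <- match.arg(view)
  space <- match.arg(space)
  if (view == "mds") {
    sm <- build_score_matrix(cohort, scaling_mode = scaling_mode)
    emb <- classical_mds(sm)
    cluster_input <- if (space == "scores") score_cols(sm) else emb$points
    km <- triage_kmeans(cluster_input, k = k, n_restarts = n_restarts,
                        seed = seed)
    condel_center <- vapply(seq_len(k), function(cl) {
      mean(sm$condel[km$cluster == cl])
    }, numeric(1))
    labels <- label_by_condel(km, condel_center)
    out <- tibble(
      gene = sm$gene, cdna_change = sm$cdna_change,
      label = labels, color = unname(semantic_labels[as.character(labels)]),
      coord1 = emb$points[, 1], coord2 = emb$points[, 2]
    )
    attr(out, "embedding") <- emb
  } else {
    rows <- cohort[!is.na(cohort$revel) & !is.na(cohort$condel), ]
    mat <- cbind(revel = rows$revel, condel = rows$condel)
    km <- triage_kmeans(mat, k = k, n_restarts = n_restarts, seed = seed)
    labels <- label_by_condel(km, km$centers[, "condel"])
    out <- tibble(
      gene = rows$gene, cdna_change = rows$cdna_change,
      label = labels, color = unname(semantic_labels[as.character(labels)]),
      coord1 = rows$revel, coord2 = rows$condel
    )
  }
  attr(out, "kmeans") <- km
  attr(out, "view") <- view
  attr(out, "space") <- space
  attr(out, "seed") <- seed
  class(out) <- c("triage_clusters", class(out))
  out
}

#' Agreement between a predicted and a published labelling
#'
#' Matches the two labelings on the `(gene, cdna_change)` key and reports
#' the adjusted Rand index together with the per-class confusion counts.
#' Rows without a published label are dropped before comparison.
#'
#' @param predicted A [cluster_variants()] result, or a tibble with `gene`,
#'   `cdna_change` and `color`/`label` columns.
#' @param published A tibble with `gene`, `cdna_change` and a published
#'   label column (default `mds_label`; pass a cohort tibble directly).
#' @param published_col Column of `published` holding the published labels.
#' @return A list of class `concordance`: `ari`, `confusion` (predicted x
#'   published contingency table), `n`.
#' @export
concordance <- function(predicted, published, published_col = "mds_label") {
  pred_lab <- if ("color" %in% names(predicted)) {
    predicted$color
  } else {
    predicted$label
  }
  pred <- tibble(gene = predicted$gene, cdna_change = predicted$cdna_change,
                 .pred = as.character(pred_lab))
  pub <- tibble(gene = published$gene, cdna_change = published$cdna_change,
                .pub = as.character(published[[published_col]]))
  pub <- pub[!is.na(pub$.pub), ]
  key_pred <- paste(pred$gene, pred$cdna_change)
  key_pub <- paste(pub$gene, pub$cdna_change)
  sym_diff <- c(setdiff(key_pred, key_pub), setdiff(key_pub, key_pred))
  if (length(sym_diff) > 0) {
    abort(paste0("variant keys differ between labelings: ",
                 paste(head(sym_diff, 5), collapse = "; ")),
          class = "pcd_validation_error")
  }
  merged <- dplyr::inner_join(pred, pub, by = c("gene", "cdna_change"))
  structure(
    list(
      ari = mclust::adjustedRandIndex(merged$.pred, merged$.pub),
      confusion = table(predicted = merged$.pred, published = merged$.pub),
      n = nrow(merged)
    ),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance: n = %d, adjusted Rand index = %.3f>\n",
              x$n, x$ari))
  print(x$confusion)
  invisible(x)
}

#' Stability of re-clustering against the published labels
#'
#' Re-runs [cluster_variants()] across a sweep of seeds and reports, per
#' seed, the total WCSS and the adjusted Rand index against the published
#' labels. A diagnosis string summarises runs that fall below the
#' concordance threshold (the published analysis does not state its exact
#' scaling or seed, so sub-threshold agreement is reported, not fatal).
#'
#' @param cohort A cohort tibble carrying published labels.
#' @param seeds Integer vector of seeds (default `1:20`).
#' @param threshold ARI threshold used in the diagnosis (default 0.8).
#' @inheritParams cluster_variants
#' @return A tibble with one row per seed (`seed`, `tot_wcss`, `ari`,
#'   `sizes`), with attributes `diagnosis` and `threshold`.
#' @export
reclustering_concordance <- function(cohort, seeds = 1:20,
                                     scaling_mode = "cadd_div33",
                                     space = "scores", n_restarts = 25,
                                     threshold = 0.8) {
  res <- purrr::map_dfr(seeds, function(s) {
    cl <- cluster_variants(cohort, view = "mds", space = space,
                           scaling_mode = scaling_mode,
                           n_restarts = n_restarts, seed = s)
    conc <- concordance(cl, cohort, published_col = "mds_label")
    tibble(
      seed = s,
      tot_wcss = attr(cl, "kmeans")$tot_wcss,
      ari = conc$ari,
      sizes = paste(sort(table(cl$label), decreasing = TRUE),
                    collapse = "/")
    )
  })
  low <- res$seed[res$ari < threshold]
  attr(res, "threshold") <- threshold
  attr(res, "diagnosis") <- if (length(low) == 0) {
    sprintf("all %d seeds reach ARI >= %.2f against the published labels",
            length(seeds), threshold)
  } else {
    sprintf("seeds below ARI %.2f: %s (min ARI %.3f)", threshold,
            paste(low, collapse = ", "), min(res$ari))
  }
  res
}
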