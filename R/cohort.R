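#' Consequence classes recognised in a cohort table
#'
#' @format Character vector of the eight consequence classes.
#' @export
consequence_levels <- c(
  "missense", "nonsense", "frameshift", "synonymous",
  "splice_donor", "splice_acceptor", "inframe_deletion", "duplication"
)

#' Column dialect of a delimited cohort table
#'
#' Describes how the columns of a delimited variant table map onto the
#' canonical cohort fields, which string encodes a missing cell, and the
#' field delimiter. The default dialect is the one used by the packaged
#' PCD cohort table ([pcd_variants()]).
#'
#' @param columns Named character vector mapping file header names to
#'   canonical field names.
#' @param missing String that encodes a missing cell (default `"-"`).
#' @param delim Field delimiter (default tab).
#' @return A list of class `cohort_dialect`.
#' @export
cohort_dialect <- function(columns = NULL, missing = "-", delim = "\t") {
  if (is.null(columns)) {
    columns <- c(
      Gene = "gene", Transcript = "transcript", cDNA = "cdna_change",
      Protein = "protein_change", Consequence = "consequence",
      dbSNP = "dbsnp_id", Frequency = "allele_frequency",
      Homozygote = "homozygote_reported", JSD = "jsd", Conserved = "conserved",
      MetaLR = "metalr", MetaSVM = "metasvm", CADD = "cadd_phred",
      REVEL = "revel", Condel = "condel", Scatter = "scatter_label",
      MDS = "mds_label", ACMG = "acmg", ClinicalAssessment = "clinical"
    )
  }
  structure(list(columns = columns, missing = missing, delim = delim),
            class = "cohort_dialect")
}

score_ranges <- list(
  jsd = c(0, 1), metalr = c(0, 1), metasvm = c(0, 1),
  cadd_phred = c(0, Inf), revel = c(0, 1), condel = c(0, 1)
)
panel_scores <- c("metalr", "metasvm", "cadd_phred", "revel", "condel")

#' Read an annotated variant cohort table
#'
#' Parses a delimited table of annotated variants (one row per variant) into
#' a tidy cohort tibble, validating field values: the consequence must be one
#' of [consequence_levels], allele frequencies and predictor scores must fall
#' in their valid ranges, `(gene, cdna_change)` pairs must be unique, and a
#' row is flagged `novel` exactly when it carries no dbSNP identifier.
#' Malformed numeric cells become `NA` with a warning; row order is preserved.
#'
#' @param path Path to the delimited file.
#' @param dialect A [cohort_dialect()] describing the file layout.
#' @return A tibble with one row per variant and canonical column names
#'   (`gene`, `transcript`, `cdna_change`, `protein_change`, `consequence`,
#'   `dbsnp_id`, `novel`, `allele_frequency`, `homozygote_reported`, the six
#'   scores, `scatter_label`, `mds_label`, and any annotation columns).
#' @seealso [pcd_variants()] for the packaged cohort, [write_cohort_table()]
#'   for the inverse operation.
#' @export
read_cohort_table <- function(path, dialect = cohort_dialect()) {
  if (!file.exists(path)) {
    abort(paste0("cohort table not found: ", path), class = "pcd_io_error")
  }
  raw <- readr::read_delim(
    path, delim = dialect$delim, na = dialect$missing,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  known <- intersect(names(dialect$columns), names(raw))
  if (length(known) == 0) {
    abort("no header names match the configured dialect",
          class = "pcd_validation_error")
  }
  names(raw)[match(known, names(raw))] <- unname(dialect$columns[known])
  out <- as_tibble(raw)

  numeric_cols <- c("allele_frequency", names(score_ranges))
  for (col in intersect(numeric_cols, names(out))) {
    v <- out[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad)) {
      warn(sprintf("%d malformed value(s) in column '%s' set to missing",
                   sum(bad), col))
    }
    out[[col]] <- num
  }
  for (col in intersect(c("homozygote_reported", "conserved"), names(out))) {
    out[[col]] <- !is.na(out[[col]]) & out[[col]] %in% c("yes", "true", "TRUE")
  }
  if ("gene" %in% names(out)) out$gene <- toupper(out$gene)
  if ("dbsnp_id" %in% names(out)) {
    out$novel <- is.na(out$dbsnp_id) | out$dbsnp_id == ""
  }
  validate_cohort(out)
}

validate_cohort <- function(x) {
  if (nrow(x) == 0) return(x)
  if (all(c("gene", "cdna_change") %in% names(x))) {
    key <- paste(x$gene, x$cdna_change)
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      abort(paste0("duplicate (gene, cdna_change) pair(s): ",
                   paste(dup, collapse = "; ")),
            class = "pcd_validation_error")
    }
  }
  if ("consequence" %in% names(x)) {
    bad <- setdiff(unique(x$consequence), c(consequence_levels, NA))
    if (length(bad)) {
      abort(paste0("unknown consequence value(s): ",
                   paste(bad, collapse = ", ")),
            class = "pcd_validation_error")
    }
  }
  for (col in intersect(names(score_ranges), names(x))) {
    rng <- score_ranges[[col]]
    v <- x[[col]]
    if (any(!is.na(v) & (v < rng[1] | v > rng[2]))) {
      abort(sprintf("column '%s' outside [%g, %g]", col, rng[1], rng[2]),
            class = "pcd_validation_error")
    }
  }
  if ("allele_frequency" %in% names(x)) {
    v <- x$allele_frequency
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort("allele_frequency outside [0, 1]", class = "pcd_validation_error")
    }
  }
  x
}

#' Write a cohort table back to disk
#'
#' Inverse of [read_cohort_table()]: missing values are encoded with the
#' dialect's missing string, logical flags as `yes`/`no`, and columns are
#' written under the dialect's header names so that a read/write round trip
#' preserves all field values.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @inheritParams read_cohort_table
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path, dialect = cohort_dialect()) {
  out <- cohort
  for (col in intersect(c("homozygote_reported", "conserved"), names(out))) {
    out[[col]] <- ifelse(out[[col]], "yes", "no")
  }
  out$novel <- NULL
  inv <- names(dialect$columns)
  names(inv) <- unname(dialect$columns)
  keep <- intersect(names(out), names(inv))
  out <- out[, keep]
  names(out) <- inv[keep]
  readr::write_delim(out, path, delim = dialect$delim, na = dialect$missing)
  invisible(path)
}

#' The packaged PCD variant cohort
#'
#' Loads the bundled table of 112 annotated variants in 28 genes linked to
#' primary ciliary dyskinesia, with per-variant predictor scores (MetaLR,
#' MetaSVM, PHRED-scaled CADD, REVEL, Condel), a Jensen-Shannon divergence
#' conservation score where available, gnomAD allele frequency, and the
#' published cluster colours for the two clustering views (`mds_label`,
#' `scatter_label`). See `inst/extdata/README.md` for provenance notes.
#'
#' @return A cohort tibble with 112 rows.
#' @examples
#' cohort <- pcd_variants()
#' tally_by_gene(cohort)
#' @export
pcd_variants <- function() {
  read_cohort_table(
    system.file("extdata", "pcd_variants.tsv", package = "pcdtriage",
                mustWork = TRUE)
  )
}

#' Restrict a cohort to complete five-score panels
#'
#' A panel is complete when MetaLR, MetaSVM, CADD, REVEL and Condel are all
#' present; only complete panels can enter the score matrix for clustering.
#'
#' @param cohort A cohort tibble.
#' @return The subset of rows with all five predictor scores, original order.
#' @export
complete_panels <- function(cohort) {
  ok <- rowSums(is.na(as.matrix(cohort[, panel_scores]))) == 0
  cohort[ok, ]
}

#' Tally variants per gene
#'
#' @param cohort A cohort tibble (non-empty).
#' @return A tibble `(gene, n)` sorted by decreasing count; counts sum to the
#'   number of records.
#' @export
tally_by_gene <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  dplyr::count(cohort, .data$gene, sort = TRUE)
}

#' Tally variants per consequence class
#'
#' @param cohort A cohort tibble (non-empty).
#' @return A tibble `(consequence, n)` sorted by decreasing count.
#' @export
tally_by_consequence <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  dplyr::count(cohort, .data$consequence, sort = TRUE)
}

#' Summary tallies for a cohort
#'
#' Gene, consequence and novelty tallies plus panel completeness, in one
#' list ready for JSON serialisation.
#'
#' @param cohort A cohort tibble.
#' @return A list with elements `n_variants`, `n_genes`, `n_novel`,
#'   `n_complete_panels`, `by_gene`, `by_consequence`.
#' @export
cohort_tallies <- function(cohort) {
  list(
    n_variants = nrow(cohort),
    n_genes = dplyr::n_distinct(cohort$gene),
    n_novel = sum(cohort$novel),
    n_complete_panels = nrow(complete_panels(cohort)),
    by_gene = tally_by_gene(cohort),
    by_consequence = tally_by_consequence(cohort)
  )
}
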