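default_species <- c(
  "Homo_sapiens", "Pan_troglodytes", "Mus_musculus", "Rattus_norvegicus",
  "Canis_lupus_familiaris", "Equus_caballus", "Bos_taurus",
  "Xenopus_tropicalis", "Gallus_gallus", "Danio_rerio"
)

sim_score_names <- c("metalr", "metasvm", "cadd_phred", "revel", "condel")

default_class_means <- rbind(
  pathogenic = c(metalr = 0.75, metasvm = 0.77, cadd_phred = 25.5,
                 revel = 0.71, condel = 0.790),
  uncertain  = c(metalr = 0.32, metasvm = 0.27, cadd_phred = 22.8,
                 revel = 0.38, condel = 0.500),
  benign     = c(metalr = 0.21, metasvm = 0.31, cadd_phred = 13.7,
                 revel = 0.13, condel = 0.070)
)

default_class_sds <- rbind(
  pathogenic = c(metalr = 0.13, metasvm = 0.12, cadd_phred = 3.2,
                 revel = 0.17, condel = 0.186),
  uncertain  = c(metalr = 0.15, metasvm = 0.17, cadd_phred = 3.0,
                 revel = 0.18, condel = 0.225),
  benign     = c(metalr = 0.18, metasvm = 0.12, cadd_phred = 5.8,
                 revel = 0.09, condel = 0.117)
)

default_score_bounds <- cbind(
  lower = c(metalr = 0, metasvm = 0, cadd_phred = 0, revel = 0, condel = 0),
  upper = c(metalr = 1, metasvm = 1, cadd_phred = 60, revel = 1, condel = 1)
)

#' Configuration for the score-table simulator
#'
#' The defaults reproduce the statistical structure of the analysed PCD
#' cohort: three latent pathogenicity classes of sizes 24 (pathogenic), 27
#' (uncertain) and 32 (benign) complete panels, with per-class Condel and
#' CADD means/SDs taken from the published cluster statistics (e.g.
#' pathogenic Condel 0.790 +/- 0.186 and CADD 25.5 +/- 3.2, benign Condel
#' 0.070 +/- 0.117) and the remaining per-class score statistics taken from
#' the bundled cohort table. Scores are drawn from truncated normal
#' distributions within their valid ranges.
#'
#' @param n Named integer vector of class sizes
#'   (`pathogenic`, `uncertain`, `benign`).
#' @param means,sds 3 x 5 matrices (class x score) of truncated-normal
#'   locations and scales; SDs must be non-negative (0 gives a point mass).
#' @param bounds 5 x 2 matrix of per-score `lower`/`upper` truncation
#'   bounds.
#' @param n_noncoding Number of additional non-missense (splice) rows
#'   without latent class.
#' @param missing_rate Probability that each predictor score of a
#'   non-missense row is missing (default 1).
#' @param seed Integer seed.
#' @return A list of class `score_sim_config`.
#' @export
score_sim_config <- function(n = c(pathogenic = 24, uncertain = 27,
                                   benign = 32),
                             means = default_class_means,
                             sds = default_class_sds,
                             bounds = default_score_bounds,
                             n_noncoding = 0, missing_rate = 1,
                             seed = 20211030) {
  stopifnot(all(n >= 1), all(sds >= 0), all(bounds[, "upper"] >
                                              bounds[, "lower"]))
  structure(
    list(n = n, means = means, sds = sds, bounds = bounds,
         n_noncoding = n_noncoding, missing_rate = missing_rate,
         seed = seed),
    class = "score_sim_config"
  )
}

# truncated-normal draws by rejection, so moments stay interpretable
rtruncnorm_rej <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      abort("degenerate truncation: mean outside bounds",
            class = "pcd_validation_error")
    }
    return(rep(mean, n))
  }
  mass <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (mass < 1e-6) {
    abort(sprintf(
      "infeasible truncation: N(%.3g, %.3g) has mass %.2g in [%.3g, %.3g]",
      mean, sd, mass, lower, upper), class = "pcd_validation_error")
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(ceiling((n - length(out)) / mass) + 10, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a cohort score table with known latent classes
#'
#' Draws a cohort of complete five-score panels from a three-class
#' truncated-normal mixture (see [score_sim_config()]), plus optional
#' non-missense rows with missing scores. The latent class labels are
#' returned separately from the cohort table so that cluster-recovery tests
#' cannot leak the truth through the table itself.
#'
#' @param config A [score_sim_config()].
#' @return A list with `cohort` (a cohort tibble) and `truth` (tibble:
#'   `gene`, `cdna_change`, `class`).
#' @export
simulate_score_table <- function(config = score_sim_config()) {
  stopifnot(inherits(config, "score_sim_config"))
  with_local_seed(config$seed, {
    classes <- rep(rownames(config$means), config$n)
    n_total <- length(classes)
    scores <- purrr::map_dfc(sim_score_names, function(sc) {
      v <- numeric(n_total)
      for (cl in rownames(config$means)) {
        idx <- classes == cl
        v[idx] <- rtruncnorm_rej(
          sum(idx), config$means[cl, sc], config$sds[cl, sc],
          config$bounds[sc, "lower"], config$bounds[sc, "upper"]
        )
      }
      tibble(!!sc := v)
    })
    i <- seq_len(n_total)
    cohort <- dplyr::bind_cols(
      tibble(
        gene = sprintf("GENE%02d", (i - 1) %% 20 + 1),
        transcript = sprintf("NM_%06d.1", (i - 1) %% 20 + 1),
        cdna_change = sprintf("c.%dA>G", 3 * i - 2),
        protein_change = sprintf("p.Lys%dArg", i),
        consequence = "missense",
        dbsnp_id = sprintf("rs%d", 10000000 + i),
        novel = FALSE,
        allele_frequency = NA_real_,
        homozygote_reported = FALSE,
        jsd = NA_real_
      ),
      scores
    )
    if (config$n_noncoding > 0) {
      j <- seq_len(config$n_noncoding)
      extra <- tibble(
        gene = sprintf("GENE%02d", (j - 1) %% 20 + 1),
        transcript = sprintf("NM_%06d.1", (j - 1) %% 20 + 1),
        cdna_change = sprintf("c.%d+1G>A", 3 * (n_total + j)),
        protein_change = NA_character_,
        consequence = "splice_donor",
        dbsnp_id = sprintf("rs%d", 20000000 + j),
        novel = FALSE,
        allele_frequency = NA_real_,
        homozygote_reported = FALSE,
        jsd = NA_real_,
        metalr = NA_real_, metasvm = NA_real_, cadd_phred = NA_real_,
        revel = NA_real_, condel = NA_real_
      )
      for (sc in sim_score_names) {
        present <- runif(config$n_noncoding) >= config$missing_rate
        if (any(present)) {
          extra[[sc]][present] <- rtruncnorm_rej(
            sum(present), config$means["uncertain", sc],
            config$sds["uncertain", sc],
            config$bounds[sc, "lower"], config$bounds[sc, "upper"]
          )
        }
      }
      cohort <- dplyr::bind_rows(cohort, extra)
    }
    truth <- tibble(
      gene = cohort$gene[seq_len(n_total)],
      cdna_change = cohort$cdna_change[seq_len(n_total)],
      class = classes
    )
    list(cohort = validate_cohort(cohort), truth = truth)
  })
}

#' Simulate a multi-species protein alignment with known conservation
#'
#' Builds an alignment in which the reference row is ungapped and every
#' other row carries the reference residue at column j with probability
#' `conservation[j]`, otherwise a residue drawn from the background
#' distribution; non-reference rows are gapped independently at `gap_rate`.
#' The per-column conservation truth is returned alongside.
#'
#' @param n_species Number of rows (default 10).
#' @param length Number of columns (ignored when `conservation` is a
#'   vector).
#' @param conservation Per-column probability in \[0, 1\] that a row shows
#'   the reference residue; scalar or length-`length` vector.
#' @param gap_rate Per-cell gap probability for non-reference rows.
#' @param seed Integer seed.
#' @param ids Sequence identifiers (default the ten study species, human
#'   first).
#' @return A list with `alignment` (a [protein_alignment()], reference =
#'   first id) and `truth` (tibble: `column`, `conservation`).
#' @export
simulate_alignment <- function(n_species = 10, length = 100,
                               conservation = 1, gap_rate = 0,
                               seed = 20211030,
                               ids = default_species[seq_len(n_species)]) {
  stopifnot(n_species >= 2, all(conservation >= 0 & conservation <= 1),
            gap_rate >= 0, gap_rate < 1)
  cons <- rep_len(conservation, if (length(conservation) > 1)
    length(conservation) else length)
  L <- base::length(cons)
  bg <- blosum62_frequencies()
  with_local_seed(seed, {
    ref <- sample(names(bg), L, replace = TRUE, prob = bg)
    rows <- matrix("", nrow = n_species, ncol = L)
    rows[1, ] <- ref
    for (s in 2:n_species) {
      keep <- runif(L) < cons
      row <- ifelse(keep, ref, sample(names(bg), L, replace = TRUE,
                                      prob = bg))
      gap <- runif(L) < gap_rate
      row[gap] <- "-"
      rows[s, ] <- row
    }
    seqs <- setNames(apply(rows, 1, paste0, collapse = ""), ids)
    list(
      alignment = protein_alignment(seqs, reference_id = ids[1]),
      truth = tibble(column = seq_len(L), conservation = cons)
    )
  })
}
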