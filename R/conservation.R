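AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Background amino-acid frequencies derived from BLOSUM62
#'
#' Marginal amino-acid frequencies of the BLOSUM62 substitution data,
#' normalised to sum to one. Used as the default background distribution
#' against which column distributions are compared by the Jensen-Shannon
#' divergence scorer.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
blosum62_frequencies <- function() {
  f <- c(0.078, 0.051, 0.041, 0.052, 0.024, 0.034, 0.059, 0.083, 0.025,
         0.062, 0.092, 0.056, 0.024, 0.044, 0.043, 0.059, 0.055, 0.014,
         0.034, 0.072)
  setNames(f / sum(f), AA20)
}

#' Construct a multi-species protein alignment object
#'
#' @param seqs Named character vector of equal-length aligned sequences over
#'   the 20 amino acids plus gap `-` and unknown `X` (case-insensitive).
#' @param reference_id Name of the reference (human) sequence.
#' @return A list of class `protein_alignment` with elements `ids`, `seqs`,
#'   `reference_id`, `length`.
#' @export
protein_alignment <- function(seqs, reference_id) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("sequences must be named", class = "pcd_validation_error")
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    off <- names(seqs)[lens != stats::median(lens)]
    abort(paste0("ragged alignment; offending ids: ",
                 paste(off, collapse = ", ")),
          class = "pcd_validation_error")
  }
  if (length(seqs) < 2) {
    abort("alignment needs at least 2 sequences",
          class = "pcd_validation_error")
  }
  if (!reference_id %in% names(seqs)) {
    abort(paste0("reference id not in alignment: ", reference_id),
          class = "pcd_validation_error")
  }
  structure(
    list(ids = names(seqs), seqs = seqs, reference_id = reference_id,
         length = unname(lens[1])),
    class = "protein_alignment"
  )
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment: %d sequences x %d columns, reference %s>\n",
              length(x$ids), x$length, x$reference_id))
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' @param path Path to an aligned (equal-length) protein FASTA file.
#' @param reference_id Identifier of the reference (human) sequence.
#' @return A [protein_alignment()] object.
#' @export
read_alignment <- function(path, reference_id) {
  aa <- Biostrings::readAAStringSet(path)
  protein_alignment(setNames(as.character(aa), names(aa)), reference_id)
}

#' Write an alignment to FASTA
#'
#' @param alignment A [protein_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(alignment$seqs), path, width = 60
  )
  invisible(path)
}

aln_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$seqs, "", fixed = TRUE))
  rownames(m) <- alignment$ids
  m
}

#' Position-based (Henikoff) sequence weights
#'
#' Down-weights redundant sequences: each column contributes 1/(r * n) to a
#' sequence's weight, where r is the number of distinct symbols in the column
#' and n the number of sequences sharing that sequence's symbol (gap counts
#' as a symbol). Weights are normalised to sum to one.
#'
#' @param alignment A [protein_alignment()].
#' @return Named numeric vector of weights summing to 1.
#' @export
henikoff_weights <- function(alignment) {
  m <- aln_matrix(alignment)
  w <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  setNames(w / sum(w), rownames(m))
}

#' Weighted residue distribution of one alignment column
#'
#' Builds the weighted amino-acid distribution of a column. Gaps (`-`) and
#' unknown residues (`X`) are excluded from the distribution but counted in
#' the gap fraction; a small pseudocount keeps the distribution strictly
#' positive. An all-gap column has no defined distribution and is returned
#' with `gap_fraction = 1` and `all_gap = TRUE`.
#'
#' @param column Character vector of single residues (one per sequence).
#' @param weights Per-sequence weights summing to 1 (default uniform).
#' @param pseudocount Small positive count added to every amino acid
#'   (default `1e-7`).
#' @return List with `p` (named distribution over 20 amino acids, or `NA` for
#'   an all-gap column), `gap_fraction`, and `all_gap`.
#' @export
column_distribution <- function(column,
                                weights = rep(1 / length(column),
                                              length(column)),
                                pseudocount = 1e-7) {
  stopifnot(length(column) == length(weights))
  if (abs(sum(weights) - 1) > 1e-6) {
    abort("weights must sum to 1", class = "pcd_validation_error")
  }
  column <- toupper(column)
  is_gap <- column %in% c("-", "X", ".")
  gap_fraction <- mean(is_gap)
  if (all(is_gap)) {
    return(list(p = setNames(rep(NA_real_, 20), AA20),
                gap_fraction = 1, all_gap = TRUE))
  }
  counts <- setNames(rep(pseudocount, 20), AA20)
  obs <- tapply(weights[!is_gap], factor(column[!is_gap], levels = AA20), sum)
  obs[is.na(obs)] <- 0
  counts <- counts + obs
  list(p = counts / sum(counts), gap_fraction = gap_fraction, all_gap = FALSE)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gap-penalised Jensen-Shannon divergence conservation score
#'
#' Scores one column distribution against a background distribution with the
#' Jensen-Shannon divergence in bits, `JSD(p, q) = H((p+q)/2) - (H(p) +
#' H(q))/2`, multiplied by the gap penalty `1 - gap_fraction`. The score lies
#' in \[0, 1\]: 0 when the column matches the background (or is entirely
#' gapped), approaching 1 for a fully conserved residue that is rare in the
#' background.
#'
#' @param p Column distribution over the 20 amino acids (sums to 1).
#' @param q Background distribution (default [blosum62_frequencies()]).
#' @param gap_fraction Fraction of gapped rows in the column, in \[0, 1\].
#' @return Conservation score in \[0, 1\].
#' @export
jsd_column_score <- function(p, q = blosum62_frequencies(),
                             gap_fraction = 0) {
  if (gap_fraction >= 1) return(0)
  if (anyNA(p)) return(0)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort("distributions must sum to 1", class = "pcd_validation_error")
  }
  m <- (p + q) / 2
  jsd <- shannon_entropy(m) - (shannon_entropy(p) + shannon_entropy(q)) / 2
  (1 - gap_fraction) * max(0, min(1, jsd))
}

#' Window-average smoothing of per-column scores
#'
#' Blends each column's raw score with the mean score of its sequence
#' neighbourhood: `smoothed(i) = (1 - lambda_w) * raw(i) + lambda_w *
#' mean(raw over the window columns on each side, excluding i)`. Windows are
#' truncated at the alignment boundaries; `window = 0` or `lambda_w = 0`
#' returns the input unchanged.
#'
#' @param raw_scores Numeric vector of per-column scores.
#' @param window Non-negative number of columns on each side (default 3).
#' @param lambda_w Blend weight of the neighbourhood mean, in \[0, 1\]
#'   (default 0.5).
#' @return Numeric vector of the same length.
#' @export
window_smooth <- function(raw_scores, window = 3, lambda_w = 0.5) {
  stopifnot(window >= 0, lambda_w >= 0, lambda_w <= 1, all(is.finite(raw_scores)))
  n <- length(raw_scores)
  if (window == 0 || lambda_w == 0 || n < 2) return(raw_scores)
  vapply(seq_len(n), function(i) {
    idx <- setdiff(max(1, i - window):min(n, i + window), i)
    (1 - lambda_w) * raw_scores[i] + lambda_w * mean(raw_scores[idx])
  }, numeric(1))
}

#' Per-column conservation profile of an alignment
#'
#' Computes the gap-penalised Jensen-Shannon divergence conservation score of
#' every alignment column, optionally window-smoothed, together with the
#' mapping from reference (human) residue numbers to alignment columns.
#' Columns with gap fraction above `low_coverage_cutoff` are scored but
#' flagged.
#'
#' @param alignment A [protein_alignment()].
#' @param window,lambda_w Smoothing parameters (see [window_smooth()]);
#'   defaults 3 and 0.5.
#' @param pseudocount Pseudocount for column distributions (default `1e-7`).
#' @param weighting `"henikoff"` (position-based, default) or `"uniform"`.
#' @param background Background distribution (default
#'   [blosum62_frequencies()]).
#' @param low_coverage_cutoff Gap fraction above which a column is flagged
#'   `low_coverage` (default 0.3).
#' @return A tibble of class `conservation_profile`, one row per column:
#'   `column` (1-based), `human_residue` (reference residue number, `NA`
#'   where the reference is gapped), `ref_aa`, `jsd_raw`, `jsd` (smoothed),
#'   `gap_fraction`, `low_coverage`, `all_gap`. The alignment travels as an
#'   attribute for [score_variant_sites()].
#' @export
conservation_profile <- function(alignment, window = 3, lambda_w = 0.5,
                                 pseudocount = 1e-7,
                                 weighting = c("henikoff", "uniform"),
                                 background = blosum62_frequencies(),
                                 low_coverage_cutoff = 0.3) {
  weighting <- match.arg(weighting)
  m <- aln_matrix(alignment)
  w <- if (weighting == "henikoff") {
    unname(henikoff_weights(alignment))
  } else {
    rep(1 / nrow(m), nrow(m))
  }
  cols <- purrr::map(seq_len(ncol(m)), function(j) {
    column_distribution(m[, j], weights = w, pseudocount = pseudocount)
  })
  raw <- purrr::map_dbl(cols, function(cd) {
    jsd_column_score(cd$p, q = background, gap_fraction = cd$gap_fraction)
  })
  smoothed <- window_smooth(raw, window = window, lambda_w = lambda_w)
  ref <- m[alignment$reference_id, ]
  ref_res <- cumsum(ref != "-")
  ref_res[ref == "-"] <- NA_integer_
  out <- tibble(
    column = seq_len(ncol(m)),
    human_residue = as.integer(ref_res),
    ref_aa = ref,
    jsd_raw = raw,
    jsd = smoothed,
    gap_fraction = purrr::map_dbl(cols, "gap_fraction"),
    low_coverage = purrr::map_dbl(cols, "gap_fraction") > low_coverage_cutoff,
    all_gap = purrr::map_lgl(cols, "all_gap")
  )
  attr(out, "alignment") <- alignment
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Report conservation at variant residue positions
#'
#' Looks up the conservation score at a set of reference (human) residue
#' numbers and flags complete conservation: a site is `conserved` if and only
#' if every row of the alignment carries the reference amino acid at that
#' column with no gaps. Residue numbers outside the reference sequence yield
#' a per-site error entry rather than a failure.
#'
#' @param profile A [conservation_profile()].
#' @param sites Integer vector of 1-based reference residue numbers.
#' @return A tibble, one row per site: `residue`, `column`, `ref_aa`, `jsd`,
#'   `gap_fraction`, `conserved`, `note` (`NA` or an error message).
#' @export
score_variant_sites <- function(profile, sites) {
  alignment <- attr(profile, "alignment")
  m <- aln_matrix(alignment)
  purrr::map_dfr(as.integer(sites), function(s) {
    j <- profile$column[!is.na(profile$human_residue) &
                          profile$human_residue == s]
    if (length(j) != 1) {
      return(tibble(residue = s, column = NA_integer_, ref_aa = NA_character_,
                    jsd = NA_real_, gap_fraction = NA_real_,
                    conserved = NA,
                    note = "residue not within the reference sequence"))
    }
    col <- m[, j]
    ref <- m[alignment$reference_id, j]
    tibble(
      residue = s, column = j, ref_aa = ref,
      jsd = profile$jsd[j], gap_fraction = profile$gap_fraction[j],
      conserved = all(col == ref),
      note = NA_character_
    )
  })
}
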