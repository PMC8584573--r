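#' Classify a variant's consequence from its HGVS descriptions
#'
#' Deterministic mapping from the HGVS cDNA (`c.`) and protein (`p.`)
#' strings to one of the eight consequence classes. The protein change, when
#' present, takes precedence: a `Ter`/`*` substitution is nonsense, a `fs`
#' suffix frameshift, a `=` synonymous, a full-codon deletion an in-frame
#' deletion, and any other single-residue substitution missense. Without a
#' protein change the cDNA string decides: an exon-range duplication maps to
#' duplication, an intronic offset to splice_donor (`+` offsets, downstream
#' of a donor site) or splice_acceptor (`-` offsets), and a single-base
#' deletion/duplication in coding sequence to frameshift.
#'
#' Note that printed consequence labels in a curated table may override this
#' inference (e.g. deep-intronic changes annotated as splice variants from
#' functional evidence); [read_cohort_table()] keeps the table's own labels.
#'
#' @param cdna_change HGVS `c.` string(s); `""` or `NA` when absent.
#' @param protein_change HGVS `p.` string(s); `""` or `NA` when absent.
#' @return Character vector of consequence classes (see
#'   [consequence_levels]).
#' @examples
#' classify_consequence("c.5503C>T", "p.Gln1835Ter")  # nonsense
#' classify_consequence("c.11839+1G>A", "")           # splice_donor
#' @export
classify_consequence <- function(cdna_change, protein_change = "") {
  n <- max(length(cdna_change), length(protein_change))
  cdna <- rep_len(ifelse(is.na(cdna_change), "", cdna_change), n)
  prot <- rep_len(ifelse(is.na(protein_change), "", protein_change), n)
  purrr::map2_chr(cdna, prot, classify_one)
}

classify_one <- function(cdna, prot) {
  if (!nzchar(cdna) && !nzchar(prot)) {
    abort("both cdna_change and protein_change are empty",
          class = "pcd_validation_error")
  }
  if (nzchar(prot)) {
    if (!stringr::str_detect(prot, "^p\\.")) {
      abort(paste0("unparseable HGVS protein change: ", prot),
            class = "pcd_parse_error")
    }
    body <- stringr::str_remove(prot, "^p\\.")
    if (stringr::str_detect(body, "(Ter|\\*)$")) return("nonsense")
    if (stringr::str_detect(body, "fs")) return("frameshift")
    if (stringr::str_detect(body, "=$")) return("synonymous")
    if (stringr::str_detect(body, "del$")) return("inframe_deletion")
    if (stringr::str_detect(body, "^[A-Z][a-z]{2}\\d+[A-Z][a-z]{2}$")) {
      return("missense")
    }
    abort(paste0("unparseable HGVS protein change: ", prot),
          class = "pcd_parse_error")
  }
  # cDNA only: duplication spanning exons, intronic offset, or small indel
  if (stringr::str_detect(cdna, "exon") &&
      stringr::str_detect(cdna, "dup")) {
    return("duplication")
  }
  if (!stringr::str_detect(cdna, "^c\\.")) {
    abort(paste0("unparseable HGVS cDNA change: ", cdna),
          class = "pcd_parse_error")
  }
  if (stringr::str_detect(cdna, "\\d\\+\\d")) return("splice_donor")
  if (stringr::str_detect(cdna, "\\d-\\d")) return("splice_acceptor")
  if (stringr::str_detect(cdna, "(del|dup)[ACGT]*$")) return("frameshift")
  abort(paste0("unparseable HGVS cDNA change: ", cdna),
        class = "pcd_parse_error")
}
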