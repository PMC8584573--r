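test_that("the packaged cohort parses with its documented structure", {
  co <- pcd_variants()
  expect_equal(nrow(co), 112)
  expect_equal(dplyr::n_distinct(co$gene), 28)
  expect_equal(sum(co$novel), 13)

  by_gene <- tally_by_gene(co)
  expect_equal(sum(by_gene$n), nrow(co))
  expect_equal(by_gene$n[by_gene$gene == "DNAH11"], 21)

  by_cons <- tally_by_consequence(co)
  expect_equal(sum(by_cons$n), nrow(co))
  counts <- setNames(by_cons$n, by_cons$consequence)
  expect_equal(counts[["missense"]], 83)
  expect_equal(counts[["nonsense"]], 4)
  expect_equal(counts[["frameshift"]], 4)
  expect_equal(counts[["synonymous"]], 6)
  expect_equal(counts[["duplication"]], 1)
  expect_equal(counts[["inframe_deletion"]], 1)
  # intronic splice-site rows, both donor and acceptor sides
  expect_equal(counts[["splice_donor"]] + counts[["splice_acceptor"]], 13)
})

test_that("published cluster labels sit exactly on the complete panels", {
  co <- pcd_variants()
  full <- complete_panels(co)
  expect_equal(nrow(full), 83)
  expect_true(all(!is.na(full$mds_label)))
  expect_true(all(!is.na(full$scatter_label)))
  incomplete <- dplyr::anti_join(co, full, by = c("gene", "cdna_change"))
  expect_true(all(is.na(incomplete$mds_label)))
  # cluster sizes add up to the clustered total
  expect_equal(sort(as.integer(table(full$mds_label))), c(24, 27, 32))
  expect_equal(sort(as.integer(table(full$scatter_label))), c(19, 29, 35))
})

test_that("an empty table with a header yields zero records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(names(cohort_dialect()$columns), collapse = "\t"), path)
  co <- read_cohort_table(path)
  expect_equal(nrow(co), 0)
})

test_that("duplicate (gene, cdna_change) pairs are rejected by name", {
  co <- tiny_cohort()
  co$cdna_change[2] <- co$cdna_change[1]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(co, path)
  expect_error(read_cohort_table(path), "AAA1 c.1A>G",
               class = "pcd_validation_error")
})

test_that("malformed score cells become missing with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(tiny_cohort(), path)
  lines <- readLines(path)
  lines[2] <- sub("0.95", "not_a_number", lines[2], fixed = TRUE)
  writeLines(lines, path)
  expect_warning(co <- read_cohort_table(path), "malformed")
  expect_true(is.na(co$condel[1]))
})

test_that("write then read round-trips all field values", {
  co <- pcd_variants()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(co, path)
  back <- read_cohort_table(path)
  expect_equal(as.data.frame(back), as.data.frame(co))
})

test_that("out-of-range scores fail validation", {
  co <- tiny_cohort()
  co$condel[1] <- 1.7
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(co, path)
  expect_error(read_cohort_table(path), "condel",
               class = "pcd_validation_error")
})
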