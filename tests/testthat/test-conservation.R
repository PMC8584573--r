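test_that("column distributions normalise and account for gaps", {
  # degenerate fully conserved column
  cd <- column_distribution(c("A", "A", "A", "A"), pseudocount = 1e-12)
  expect_equal(unname(cd$p["A"]), 1, tolerance = 1e-9)
  expect_equal(sum(cd$p), 1, tolerance = 1e-9)
  expect_equal(cd$gap_fraction, 0)

  # gaps counted in the gap fraction, excluded from the distribution
  cd <- column_distribution(c("A", "A", "-", "-"))
  expect_equal(cd$gap_fraction, 0.5)
  expect_equal(unname(cd$p["A"]), 1, tolerance = 1e-5)

  # two residues, uniform weights: direct normalisation by hand
  cd <- column_distribution(c("A", "C"), pseudocount = 1e-7)
  expect_equal(unname(cd$p["A"]), 0.5, tolerance = 1e-5)
  expect_equal(unname(cd$p["C"]), 0.5, tolerance = 1e-5)

  # all-gap column is flagged, not scored
  cd <- column_distribution(c("-", "-", "X"))
  expect_true(cd$all_gap)
  expect_equal(cd$gap_fraction, 1)

  expect_error(column_distribution(c("A", "C"), weights = c(0.9, 0.4)),
               class = "pcd_validation_error")
})

test_that("the JSD column score matches an entropy oracle and its bounds", {
  q <- blosum62_frequencies()
  # identical distributions score zero
  expect_equal(jsd_column_score(q, q, gap_fraction = 0), 0)
  # a fully gapped column scores zero whatever its distribution
  expect_equal(jsd_column_score(q, q, gap_fraction = 1), 0)

  # delta distribution on Ala against the background: H(m) - H(q)/2 oracle
  delta <- setNames(rep(0, 20), names(q))
  delta["A"] <- 1
  expected <- oracle_jsd(delta, q)
  expect_equal(jsd_column_score(delta, q, gap_fraction = 0), expected,
               tolerance = 1e-12)
  expect_gt(expected, 0.5)
  expect_lt(expected, 1)

  # gap penalty is multiplicative and monotone decreasing
  gaps <- seq(0, 1, by = 0.25)
  scores <- vapply(gaps, function(g) jsd_column_score(delta, q, g), 0)
  expect_equal(scores, (1 - gaps) * expected, tolerance = 1e-12)

  expect_error(jsd_column_score(delta * 2, q),
               class = "pcd_validation_error")
})

test_that("a conserved column maximises the score over random columns", {
  q <- blosum62_frequencies()
  delta <- setNames(rep(0, 20), names(q))
  delta["W"] <- 1  # rarest background residue
  delta_score <- jsd_column_score(delta, q)
  set.seed(11)
  random_scores <- replicate(1000, {
    col <- sample(names(q), 10, replace = TRUE, prob = q)
    cd <- column_distribution(col, pseudocount = 1e-7)
    jsd_column_score(cd$p, q, cd$gap_fraction)
  })
  expect_true(all(random_scores <= delta_score))
  expect_true(all(random_scores >= 0 & random_scores <= 1))
})

test_that("window smoothing matches a loop oracle and is range-preserving", {
  expect_equal(window_smooth(c(3, 1, 4), window = 0), c(3, 1, 4))
  expect_equal(window_smooth(c(3, 1, 4), window = 2, lambda_w = 0),
               c(3, 1, 4))
  expect_equal(window_smooth(rep(0.7, 9), window = 3), rep(0.7, 9))

  raw <- c(1, 0, 0, 0, 1)
  expect_equal(window_smooth(raw, window = 1, lambda_w = 0.5),
               oracle_window_smooth(raw, 1, 0.5))
  set.seed(5)
  for (i in 1:20) {
    raw <- runif(30)
    w <- sample(0:4, 1)
    l <- runif(1)
    sm <- window_smooth(raw, window = w, lambda_w = l)
    expect_equal(sm, oracle_window_smooth(raw, w, l), tolerance = 1e-12)
    expect_true(all(sm >= min(raw) - 1e-12 & sm <= max(raw) + 1e-12))
  }
})

test_that("alignments validate and round-trip through FASTA", {
  sim <- simulate_alignment(n_species = 3, length = 25, conservation = 0.7,
                            gap_rate = 0.1, seed = 9)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(sim$alignment, path)
  back <- read_alignment(path, reference_id = sim$alignment$reference_id)
  expect_equal(back$seqs, sim$alignment$seqs)

  expect_error(
    protein_alignment(c(a = "ACDEF", b = "ACD"), reference_id = "a"),
    "b", class = "pcd_validation_error"
  )
  expect_error(
    protein_alignment(c(a = "ACDEF", b = "ACDEF"), reference_id = "zz"),
    class = "pcd_validation_error"
  )
  expect_error(protein_alignment(c(a = "ACDEF"), reference_id = "a"),
               class = "pcd_validation_error")
})

test_that("variant-site reports flag complete conservation correctly", {
  seqs <- c(
    HUMAN = "MKWVA",
    CHIMP = "MKWIA",  # differs at residue 4
    MOUSE = "MKWV-"   # gapped at residue 5
  )
  aln <- protein_alignment(seqs, reference_id = "HUMAN")
  prof <- conservation_profile(aln, window = 0, weighting = "uniform")
  rep <- score_variant_sites(prof, sites = c(1, 4, 5, 9))
  expect_true(rep$conserved[rep$residue == 1])
  expect_false(rep$conserved[rep$residue == 4])
  expect_false(rep$conserved[rep$residue == 5])  # gap breaks conservation
  expect_true(is.na(rep$conserved[rep$residue == 9]))
  expect_match(rep$note[rep$residue == 9], "reference")
})

test_that("estimated conservation tracks the generating level", {
  sim1 <- simulate_alignment(n_species = 10, length = 60, conservation = 1,
                             gap_rate = 0, seed = 21)
  sim0 <- simulate_alignment(n_species = 10, length = 60, conservation = 0.1,
                             gap_rate = 0, seed = 21)
  p1 <- conservation_profile(sim1$alignment, window = 0)
  p0 <- conservation_profile(sim0$alignment, window = 0)
  expect_gt(mean(p1$jsd), mean(p0$jsd))
  # fully conserved alignment: every site flagged conserved
  rep <- score_variant_sites(p1, sites = c(1, 30, 60))
  expect_true(all(rep$conserved))
})

test_that("position-based weights down-weight redundant sequences", {
  seqs <- c(s1 = "AAAA", s2 = "AAAA", s3 = "CCCC")
  w <- henikoff_weights(protein_alignment(seqs, reference_id = "s1"))
  expect_equal(sum(w), 1)
  expect_lt(w[["s1"]], w[["s3"]])
  expect_equal(w[["s1"]], w[["s2"]])
})
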