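test_that("the score simulator is deterministic and seed-sensitive", {
  a <- simulate_score_table(score_sim_config(seed = 101))
  b <- simulate_score_table(score_sim_config(seed = 101))
  c <- simulate_score_table(score_sim_config(seed = 102))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("simulated scores honour their class structure and bounds", {
  cfg <- score_sim_config(n = c(pathogenic = 200, uncertain = 200,
                                benign = 200), seed = 31)
  sim <- simulate_score_table(cfg)
  expect_equal(nrow(sim$cohort), 600)
  expect_equal(nrow(complete_panels(sim$cohort)), 600)
  for (sc in c("metalr", "metasvm", "revel", "condel")) {
    expect_true(all(sim$cohort[[sc]] >= 0 & sim$cohort[[sc]] <= 1))
  }
  expect_true(all(sim$cohort$cadd_phred >= 0 & sim$cohort$cadd_phred <= 60))
  # empirical class means within 3 SE of the analytic truncated-normal
  # mean (truncation at the score bounds shifts means, e.g. benign Condel)
  trunc_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  for (cl in c("pathogenic", "uncertain", "benign")) {
    idx <- sim$truth$class == cl
    for (sc in c("condel", "cadd_phred", "revel")) {
      emp <- mean(sim$cohort[[sc]][idx])
      expected <- trunc_mean(cfg$means[cl, sc], cfg$sds[cl, sc],
                             cfg$bounds[sc, "lower"], cfg$bounds[sc, "upper"])
      se <- cfg$sds[cl, sc] / sqrt(sum(idx))  # conservative SE
      expect_lt(abs(emp - expected), 3 * se)
    }
  }
})

test_that("degenerate and infeasible simulator configs behave as specified", {
  zero_sds <- score_sim_config()$sds * 0
  cfg <- score_sim_config(n = c(pathogenic = 1, uncertain = 1, benign = 1),
                          sds = zero_sds, seed = 1)
  sim <- simulate_score_table(cfg)
  expect_equal(sim$cohort$condel, unname(cfg$means[, "condel"]))

  bad_means <- score_sim_config()$means
  bad_means["pathogenic", "condel"] <- 50  # far outside [0, 1]
  expect_error(
    simulate_score_table(score_sim_config(means = bad_means)),
    class = "pcd_validation_error"
  )
})

test_that("non-missense rows carry missing panels at the configured rate", {
  sim <- simulate_score_table(score_sim_config(n_noncoding = 10,
                                               missing_rate = 1, seed = 4))
  extra <- sim$cohort[sim$cohort$consequence != "missense", ]
  expect_equal(nrow(extra), 10)
  expect_true(all(is.na(extra$condel)))
  expect_equal(nrow(complete_panels(sim$cohort)), 83)
  # truth labels only ever describe the scored mixture rows
  expect_equal(nrow(sim$truth), 83)
})

test_that("simulated alignments expose their conservation truth", {
  sim <- simulate_alignment(n_species = 10, length = 50, conservation = 1,
                            gap_rate = 0, seed = 6)
  m <- do.call(rbind, strsplit(sim$alignment$seqs, ""))
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1)))

  # reference row never gapped, other rows gapped near the requested rate
  sim <- simulate_alignment(n_species = 10, length = 400,
                            conservation = 0.5, gap_rate = 0.2, seed = 7)
  m <- do.call(rbind, strsplit(sim$alignment$seqs, ""))
  expect_false(any(m[1, ] == "-"))
  expect_equal(mean(m[-1, ] == "-"), 0.2, tolerance = 0.05)
  expect_identical(
    sim$alignment$seqs,
    simulate_alignment(n_species = 10, length = 400, conservation = 0.5,
                       gap_rate = 0.2, seed = 7)$alignment$seqs
  )
})
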