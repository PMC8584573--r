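test_that("group summaries reproduce hand arithmetic", {
  gs <- group_summary(c(1, 2, 3, 4), rep("a", 4))
  expect_equal(gs$n, 4)
  expect_equal(gs$mean, 2.5)
  expect_equal(gs$median, 2.5)
  expect_equal(gs$sd, sqrt(sum((1:4 - 2.5)^2) / 3), tolerance = 1e-9)

  # singleton group: SD undefined, reported as 0 with a flag
  gs <- group_summary(c(1, 5, 9), c("a", "b", "c"))
  expect_true(all(gs$sd == 0))
  expect_true(all(gs$sd_undefined))

  expect_error(group_summary(c(1, NA), c("a", "b")),
               class = "pcd_validation_error")
})

test_that("group summaries are permutation-invariant within groups", {
  set.seed(2)
  v <- rnorm(30)
  g <- sample(c("x", "y", "z"), 30, replace = TRUE)
  perm <- sample(30)
  expect_equal(group_summary(v, g), group_summary(v[perm], g[perm]))
})

test_that("Kruskal-Wallis matches rank arithmetic and handles degeneracy", {
  # identical groups: no separation at all
  kw <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$H_corrected, 0, tolerance = 1e-12)
  expect_equal(kw$p_value, 1, tolerance = 1e-9)

  # untied groups {1,2},{3,4},{5,6}: H from a first-principles oracle
  v <- 1:6
  g <- rep(c("a", "b", "c"), each = 2)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$H, oracle_kw_h(v, g), tolerance = 1e-12)
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$correction, 1)  # no ties, no correction
  expect_equal(kw$H_corrected, kw$H)

  # all values identical: correction factor degenerates
  kw <- kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(kw$H_corrected, 0)
  expect_equal(kw$p_value, 1)
})

test_that("Kruskal-Wallis agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:10) {
    v <- sample(1:8, 24, replace = TRUE)  # plenty of ties
    g <- sample(c("a", "b", "c"), 24, replace = TRUE)
    if (length(unique(g)) < 3) next
    kw <- kruskal_wallis(v, g)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(kw$H_corrected, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(12)
  v <- rnorm(40)
  g <- sample(c("a", "b", "c"), 40, replace = TRUE)
  base <- kruskal_wallis(v, g)
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) 5 * x - 2, function(x) atan(x))) {
    kw <- kruskal_wallis(f(v), g)
    expect_equal(kw$H_corrected, base$H_corrected, tolerance = 1e-10)
  }
})

test_that("score_group_stats summarises the packaged cohort per label", {
  co <- pcd_variants()
  st <- score_group_stats(co, "mds_label")
  condel <- st$summary[st$summary$score == "condel", ]
  expect_equal(sort(condel$n), c(24, 27, 32))
  expect_true(all(st$tests$p_value[st$tests$score %in%
                                     c("metalr", "metasvm", "cadd_phred",
                                       "revel", "condel")] < 1e-4))
})
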