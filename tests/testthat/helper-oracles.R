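# Independent oracles used across tests. Each is a deliberately naive
# re-derivation (brute force or closed form) kept separate from the
# package's own code paths.

# Shannon entropy in bits, written out directly
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Jensen-Shannon divergence between two distributions, in bits
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  oracle_entropy(m) - (oracle_entropy(p) + oracle_entropy(q)) / 2
}

# window smoothing re-derived as an explicit double loop
oracle_window_smooth <- function(raw, window, lambda) {
  n <- length(raw)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- c()
    for (j in seq(i - window, i + window)) {
      if (j >= 1 && j <= n && j != i) acc <- c(acc, raw[j])
    }
    out[i] <- if (length(acc) == 0) {
      raw[i]
    } else {
      (1 - lambda) * raw[i] + lambda * mean(acc)
    }
  }
  out
}

# exhaustive minimum-WCSS 3-partition of a small point set
oracle_best_partition <- function(x, k = 3) {
  n <- nrow(x)
  stopifnot(n <= 12)
  wcss_of <- function(assign) {
    tot <- 0
    for (cl in unique(assign)) {
      pts <- x[assign == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      tot <- tot + sum(sweep(pts, 2, ctr)^2)
    }
    tot
  }
  best <- NULL
  best_w <- Inf
  # fix the first point's label to 1: partitions are label-invariant
  for (code in 0:(k^(n - 1) - 1)) {
    assign <- c(1L, (code %/% k^(0:(n - 2))) %% k + 1L)
    if (length(unique(assign)) < k) next
    w <- wcss_of(assign)
    if (w < best_w - 1e-12) {
      best_w <- w
      best <- assign
    }
  }
  list(assign = best, wcss = best_w)
}

# partitions-as-sets equality, ignoring label names
same_partition <- function(a, b) {
  identical(
    sort(unname(vapply(split(seq_along(a), a), paste, collapse = ",", ""))),
    sort(unname(vapply(split(seq_along(b), b), paste, collapse = ",", "")))
  )
}

# Kruskal-Wallis H from first principles on untied data
oracle_kw_h <- function(values, labels) {
  n <- length(values)
  r <- rank(values)
  groups <- split(r, labels)
  12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) length(g) * mean(g)^2, 0)) -
    3 * (n + 1)
}

# three well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 20, d = 2, sep = 10, seed = 42) {
  set.seed(seed)
  centers <- diag(sep, nrow = 3, ncol = d)
  x <- do.call(rbind, lapply(1:3, function(i) {
    matrix(rnorm(n_per * d, sd = 1), ncol = d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE)
  }))
  list(x = x, truth = rep(1:3, each = n_per))
}

tiny_cohort <- function() {
  tibble::tibble(
    gene = c("AAA1", "AAA1", "BBB2", "CCC3", "CCC3"),
    transcript = paste0("NM_00000", 1:5, ".1"),
    cdna_change = c("c.1A>G", "c.4C>T", "c.7G>A", "c.10T>C", "c.13A>C"),
    protein_change = c("p.Lys1Glu", "p.Leu2Phe", "p.Ala3Thr", "p.Ser4Pro",
                       "p.Met5Leu"),
    consequence = "missense",
    dbsnp_id = paste0("rs", 1:5),
    novel = FALSE,
    allele_frequency = c(0.001, NA, 0.01, 0.2, NA),
    homozygote_reported = FALSE,
    jsd = c(0.8, 0.7, NA, 0.5, 0.9),
    metalr = c(0.9, 0.8, 0.5, 0.1, NA),
    metasvm = c(0.85, 0.75, 0.45, 0.2, 0.3),
    cadd_phred = c(28, 25, 20, 10, 12),
    revel = c(0.9, 0.85, 0.4, 0.05, 0.1),
    condel = c(0.95, 0.8, 0.5, 0.05, 0.1)
  )
}
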