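#' Lloyd k-means with farthest-point seeding and restarts
#'
#' A small, fully specified k-means: each restart seeds one centroid at a
#' random data point and the remaining centroids greedily at the point
#' farthest from all chosen centroids, then runs Lloyd iterations (assign to
#' nearest centroid, recompute means) to an assignment fixed point or
#' `max_iter`. Should a cluster empty out, its centroid is re-seeded at the
#' point farthest from its assigned centroid. The best of `n_restarts` runs
#' by total within-cluster sum of squares (WCSS) is returned. WCSS is
#' checked to be non-increasing across iterations.
#'
#' @param x Numeric matrix or data frame (rows are observations).
#' @param k Number of clusters (default 3).
#' @param n_restarts Number of random restarts (default 25).
#' @param seed Integer seed controlling restart initialisation
#'   (default 20211030).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @return An object of class `triage_kmeans`: `cluster` (integer
#'   assignments), `centers` (k x d matrix), `wcss` (per-cluster),
#'   `tot_wcss`, `iterations`, `n_restarts`, `seed`.
#' @export
triage_kmeans <- function(x, k = 3, n_restarts = 25, seed = 20211030,
                          max_iter = 300) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    abort("non-finite values in clustering input",
          class = "pcd_validation_error")
  }
  n <- nrow(x)
  if (n < k) {
    abort(sprintf("need at least k = %d rows, got %d", k, n),
          class = "pcd_validation_error")
  }
  best <- NULL
  firsts <- with_local_seed(seed, sample.int(n, n_restarts, replace = TRUE))
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(x, k, first = firsts[r], max_iter = max_iter)
    if (is.null(best) || fit$tot_wcss < best$tot_wcss - 1e-12) best <- fit
  }
  structure(
    c(best, list(n_restarts = n_restarts, seed = seed)),
    class = "triage_kmeans"
  )
}

# squared Euclidean distances from each row of x to each row of centers
sq_dist_to <- function(x, centers) {
  cross <- x %*% t(centers)
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * cross
}

lloyd_once <- function(x, k, first, max_iter) {
  n <- nrow(x)
  # farthest-point seeding from a random first centre
  idx <- first
  d2 <- sq_dist_to(x, x[idx, , drop = FALSE])[, 1]
  while (length(idx) < k) {
    cand <- which.max(d2)
    idx <- c(idx, cand)
    d2 <- pmin(d2, sq_dist_to(x, x[cand, , drop = FALSE])[, 1])
  }
  centers <- x[idx, , drop = FALSE]
  assign <- integer(n)
  prev_wcss <- Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    d <- sq_dist_to(x, centers)
    new_assign <- max.col(-d, ties.method = "first")
    # re-seed empty clusters at the point farthest from its centroid,
    # never stealing the same point twice
    taken <- rep(FALSE, n)
    for (cl in seq_len(k)) {
      if (!any(new_assign == cl)) {
        own <- d[cbind(seq_len(n), new_assign)]
        own[taken] <- -Inf
        far <- which.max(own)
        new_assign[far] <- cl
        taken[far] <- TRUE
      }
    }
    centers <- do.call(rbind, lapply(seq_len(k), function(cl) {
      colMeans(x[new_assign == cl, , drop = FALSE])
    }))
    wcss <- sum((x - centers[new_assign, , drop = FALSE])^2)
    if (wcss > prev_wcss + 1e-8) {
      warn("WCSS increased during a Lloyd iteration (empty-cluster re-seed)")
    }
    converged <- identical(new_assign, assign)
    assign <- new_assign
    prev_wcss <- wcss
    if (converged || iter >= max_iter) break
  }
  per <- vapply(seq_len(k), function(cl) {
    sum((x[assign == cl, , drop = FALSE] -
           matrix(centers[cl, ], sum(assign == cl), ncol(x), byrow = TRUE))^2)
  }, numeric(1))
  list(cluster = assign, centers = centers, wcss = per,
       tot_wcss = sum(per), iterations = iter)
}

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.triage_kmeans <- function(x, ...) {
  cat(sprintf("<triage_kmeans: k = %d, n = %d, total WCSS = %.4g, %d restart(s)>\n",
              nrow(x$centers), length(x$cluster), x$tot_wcss, x$n_restarts))
  invisible(x)
}

#' @describeIn triage_kmeans Tidy the centroids into a long tibble.
#' @method tidy triage_kmeans
#' @param x,object A `triage_kmeans` object.
#' @param ... Unused.
#' @export
tidy.triage_kmeans <- function(x, ...) {
  centers <- as_tibble(x$centers, .name_repair = "minimal")
  dplyr::bind_cols(
    tibble(cluster = seq_len(nrow(x$centers)), size = tabulate(x$cluster),
           wcss = x$wcss),
    centers
  )
}

#' @describeIn triage_kmeans One-row model summary.
#' @method glance triage_kmeans
#' @export
glance.triage_kmeans <- function(x, ...) {
  tibble(k = nrow(x$centers), n = length(x$cluster), tot_wcss = x$tot_wcss,
         iterations = x$iterations, n_restarts = x$n_restarts, seed = x$seed)
}
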