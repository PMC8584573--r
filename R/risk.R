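#' Binomial recessive-disease risk from shared carrier variants
#'
#' For a couple in which both partners carry the same `k` heterozygous
#' variants in autosomal-recessive disease genes, each shared variant
#' independently gives an offspring a `p_per_variant` chance (1/4 for a
#' classical recessive condition with both parents heterozygous) of being
#' affected by that condition. The number of affected conditions is then
#' binomial, and the probability that an offspring is affected by at least
#' one condition is `1 - (1 - p)^k`.
#'
#' @param k Number of shared heterozygous variants (non-negative integer).
#' @param p_per_variant Per-condition risk in \[0, 1\] (default 1/4).
#' @return An object of class `risk_result`: `k`, `p_per_variant`, `p_any`,
#'   and `pmf` (probability of exactly j affected conditions, j = 0..k).
#' @examples
#' shared_variant_risk(2)$p_any  # 0.4375
#' shared_variant_risk(7)$p_any  # 0.8665...
#' @export
shared_variant_risk <- function(k, p_per_variant = 1 / 4) {
  if (length(k) != 1 || is.na(k) || k < 0 || k != round(k)) {
    abort("k must be a single non-negative integer",
          class = "pcd_validation_error")
  }
  if (p_per_variant < 0 || p_per_variant > 1) {
    abort("p_per_variant must lie in [0, 1]", class = "pcd_validation_error")
  }
  k <- as.integer(k)
  pmf <- dbinom(0:k, size = k, prob = p_per_variant)
  structure(
    list(k = k, p_per_variant = p_per_variant,
         p_any = -expm1(k * log1p(-p_per_variant)),
         pmf = setNames(pmf, 0:k)),
    class = "risk_result"
  )
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf(
    "Shared-variant recessive risk: k = %d, per-variant risk = %.4g\n",
    x$k, x$p_per_variant))
  cat(sprintf("P(at least one affected condition) = %.4f\n", x$p_any))
  invisible(x)
}

#' @method tidy risk_result
#' @describeIn shared_variant_risk Probability mass function as a tibble
#'   (`n_conditions`, `probability`).
#' @param x A `risk_result`.
#' @param ... Unused.
#' @export
tidy.risk_result <- function(x, ...) {
  tibble(n_conditions = as.integer(names(x$pmf)),
         probability = unname(x$pmf))
}

#' @method glance risk_result
#' @describeIn shared_variant_risk One-row summary (`k`, `p_per_variant`,
#'   `p_any`).
#' @export
glance.risk_result <- function(x, ...) {
  tibble(k = x$k, p_per_variant = x$p_per_variant, p_any = x$p_any)
}
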