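# Shared numerical helpers.

# Median of the 1-df chi-square distribution, qchisq(0.5, 1), fixed as a
# constant so that lambda estimates are bit-reproducible across platforms.
.chisq1_median <- 0.454936423119573

# p-values are floored here before any -log10 / chi-square transform so that
# extreme associations never underflow to -Inf.
.p_floor <- 1e-300

#' Weighted median
#'
#' Value of `x` at cumulative weight fraction 0.5: sort `x`, accumulate the
#' normalised weights, and return the first value whose cumulative weight
#' reaches one half. With unit weights this is the lower sample median.
#'
#' @param x Numeric vector.
#' @param w Non-negative weights, same length as `x`.
#' @return A single number.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (length(x) == 0L || sum(w) <= 0) {
    abort("weighted_median() needs at least one value with positive weight.")
  }
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Weighted empirical cumulative distribution function
#'
#' Returns the right-continuous step function
#' \eqn{\hat F(x) = \sum_i w_i 1[v_i \le x] / \sum_i w_i}. With equal weights
#' this reduces to the ordinary ecdf. Used throughout the condFDR machinery
#' so that each SNP contributes proportionally to its LD pruning weight.
#'
#' @param values Numeric vector of observations.
#' @param weights Non-negative weights; total weight must be positive.
#' @return A function of one vectorised argument returning values in `[0, 1]`.
#' @examples
#' f <- weighted_ecdf(c(0.1, 0.2), c(1, 0.5))
#' f(0.1)  # 1 / 1.5
#' @export
weighted_ecdf <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights))
  if (any(weights < 0)) abort("weights must be non-negative.")
  tot <- sum(weights)
  if (!(tot > 0)) abort("total weight must be positive.")
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord]) / tot
  function(x) {
    idx <- findInterval(x, v)
    out <- numeric(length(x))
    out[idx > 0] <- cw[idx[idx > 0]]
    out
  }
}

# Weighted lower quantile: smallest value v with F-hat(v) >= prob.
weighted_quantile <- function(values, weights, prob) {
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord]) / sum(weights)
  idx <- vapply(prob, function(p) which(cw >= p - 1e-12)[1L], integer(1))
  v[idx]
}

# Derive a 32-bit-safe stream seed for iteration i of a run seeded with
# `seed`; keeps iterations order-independent.
iter_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1009 * as.numeric(i)) %% 2147483647)
}

# Sort a variant table by genomic coordinates; chromosomes compare
# numerically ("2" before "10", X/Y/MT after autosomes).
chrom_rank <- function(chrom) {
  suppressWarnings(n <- as.numeric(chrom))
  n[is.na(n)] <- 100 + as.numeric(factor(chrom[is.na(n)]))
  n
}

sort_by_position <- function(tbl) {
  dplyr::arrange(tbl, chrom_rank(.data$chrom), .data$pos)
}
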