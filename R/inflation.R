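# Genomic inflation control: LD-weighted lambda estimation and correction.

#' Estimate the genomic inflation factor (lambda)
#'
#' Converts p-values to 1-df chi-square quantiles and takes the ratio of
#' their weighted median to the null chi-square(1) median (0.454936...).
#' The weights are LD pruning weights ([pruning_weights()]), so that clumps
#' of correlated variants do not dominate the median; with unit weights this
#' is classical genomic control. The weighted median is the value at
#' cumulative weight fraction 0.5.
#'
#' @param pvalues Numeric p-values in (0, 1].
#' @param weights Optional `pruning_weights` tibble or numeric vector
#'   aligned with `pvalues`; variants without a weight get weight 1.
#' @param snp_ids Variant ids aligned with `pvalues`, used to match a
#'   `pruning_weights` table.
#' @return A list with `lambda_gc` and `n_effective` (total weight used).
#' @export
estimate_lambda <- function(pvalues, weights = NULL, snp_ids = NULL) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  if (length(pvalues) < 100) {
    warn("estimate_lambda: fewer than 100 variants; lambda will be noisy.")
  }
  w <- if (inherits(weights, "pruning_weights")) {
    if (is.null(snp_ids)) abort("snp_ids needed to align pruning weights.")
    align_weights(weights, snp_ids)
  } else if (is.null(weights)) {
    rep(1, length(pvalues))
  } else {
    as.numeric(weights)
  }
  if (!(sum(w) > 0)) abort("Total weight is zero.", class = "conjfdr_input_error")
  chisq <- qchisq(pmax(pvalues, .p_floor), df = 1, lower.tail = FALSE)
  list(
    lambda_gc = weighted_median(chisq, w) / .chisq1_median,
    n_effective = sum(w)
  )
}

#' Apply genomic control to p-values
#'
#' Divides the implied chi-square statistics by `lambda_gc` and maps them
#' back to upper-tail p-values. Deflation is never applied: when
#' `lambda_gc < 1` the p-values are returned unchanged (with a message), so
#' correction can only make p-values larger. Rank order is preserved.
#'
#' @param pvalues Numeric p-values in (0, 1].
#' @param est A lambda estimate from [estimate_lambda()] (or a number).
#' @return Corrected p-values.
#' @export
apply_genomic_control <- function(pvalues, est) {
  lambda <- if (is.list(est)) est$lambda_gc else est
  stopifnot(is.numeric(lambda), lambda > 0)
  if (lambda < 1) {
    inform(sprintf("apply_genomic_control: lambda = %.3f < 1; no deflation applied.", lambda))
    return(pvalues)
  }
  if (lambda == 1) return(pvalues)
  chisq <- qchisq(pmax(pvalues, .p_floor), df = 1, lower.tail = FALSE)
  pchisq(chisq / lambda, df = 1, lower.tail = FALSE)
}

#' Genomic control for both traits of a harmonized pair
#'
#' Estimates lambda per trait on the pair's p-values with the given pruning
#' weights and replaces `p1`/`p2` by their corrected versions.
#'
#' @param pair Harmonized pair tibble.
#' @param weights `pruning_weights` (or `NULL` for unit weights).
#' @return The pair with corrected `p1`, `p2`, and attributes `lambda1`,
#'   `lambda2`.
#' @export
genomic_control_pair <- function(pair, weights = NULL) {
  w <- align_weights(weights, pair$snp_id)
  est1 <- estimate_lambda(pair$p1, w)
  est2 <- estimate_lambda(pair$p2, w)
  pair$p1 <- apply_genomic_control(pair$p1, est1)
  pair$p2 <- apply_genomic_control(pair$p2, est2)
  attr(pair, "lambda1") <- est1$lambda_gc
  attr(pair, "lambda2") <- est2$lambda_gc
  pair
}
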