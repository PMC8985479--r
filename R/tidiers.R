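# broom-style tidy()/glance() methods for the package's result objects.

#' @method tidy skat_fit
#' @export
tidy.skat_fit <- function(x, ...) {
  tibble::tibble(
    gene = x$gene,
    n_variants = x$n_variants,
    statistic = x$Q,
    p.value = x$pvalue,
    p.permutation = x$p_permutation %||% NA_real_
  )
}

#' @method glance skat_fit
#' @export
glance.skat_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    n_variants = x$n_variants,
    n_eigenvalues = length(x$eigenvalues),
    method = x$method
  )
}

#' @method tidy conjfdr_tbl
#' @export
tidy.conjfdr_tbl <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "conjfdr_tbl")
  attr(out, "grid_1given2") <- NULL
  attr(out, "grid_2given1") <- NULL
  out
}

#' @method glance conjfdr_tbl
#' @export
glance.conjfdr_tbl <- function(x, threshold = 0.05, ...) {
  tibble::tibble(
    n_snps = nrow(x),
    n_significant = sum(x$conjfdr < threshold),
    min_conjfdr = min(x$conjfdr),
    threshold = threshold
  )
}

#' @method tidy loci_tbl
#' @export
tidy.loci_tbl <- function(x, ...) {
  out <- x
  out$n_members <- purrr::map_int(out$members, nrow)
  out$members <- NULL
  if ("genes" %in% names(out)) {
    out$genes <- purrr::map_chr(out$genes, paste, collapse = ",")
  }
  class(out) <- setdiff(class(out), "loci_tbl")
  out
}

#' @method glance pruning_weights
#' @export
glance.pruning_weights <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x),
    n_effective = sum(x$weight),
    n_iterations = attr(x, "n_iterations"),
    r2_threshold = attr(x, "r2_threshold"),
    seed = attr(x, "seed")
  )
}
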