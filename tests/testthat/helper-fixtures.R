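# Shared fixtures and quiet wrappers for the test suite.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

extdata <- function(...) system.file("extdata", ..., package = "conjfdr")

# Minimal ld_ref constructor for hand-built pair lists.
ld_ref_tbl <- function(snp_i, snp_j, r2) {
  structure(tibble::tibble(snp_i = snp_i, snp_j = snp_j, r2 = r2),
            class = c("ld_ref", "tbl_df", "tbl", "data.frame"))
}

# Unit pruning weights over a SNP id vector.
unit_weights <- function(snp_ids) {
  w <- tibble::tibble(snp_id = snp_ids, weight = 1)
  attr(w, "n_iterations") <- 1L
  attr(w, "r2_threshold") <- 0.1
  attr(w, "seed") <- 0L
  class(w) <- c("pruning_weights", class(w))
  w
}

# Hand-built harmonized pair from p-value vectors (valid z for two-sided p).
pair_from_p <- function(p1, p2, chrom = "1", pos = NULL) {
  n <- length(p1)
  tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    pos = if (is.null(pos)) as.integer(seq_len(n) * 1e5) else as.integer(pos),
    allele_effect = "A",
    allele_other = "G",
    z1 = sqrt(qchisq(p1, 1, lower.tail = FALSE)),
    p1 = p1,
    z2 = sqrt(qchisq(p2, 1, lower.tail = FALSE)),
    p2 = p2
  )
}

# Small enriched bundle + downstream products, computed once per test run.
cached_small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- simulate_pair(n_snps = 4000L, n_blocks = 800L, seed = 77L)
      pair <- quiet(apply_exclusion_regions(harmonize_pair(b$sumstats1, b$sumstats2)))
      w <- pruning_weights(b$ld, pair$snp_id, rng_seed = 77L)
      cache <<- list(bundle = b, pair = pair, weights = w)
    }
    cache
  }
})
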