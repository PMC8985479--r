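# End-to-end orchestration: read -> harmonize -> exclude -> weights ->
# genomic control -> conditional QQ -> conjFDR -> clump -> annotate.

#' Run the full cross-trait conjFDR pipeline
#'
#' Executes every stage in order on two summary-statistics inputs and an LD
#' reference, returning all intermediate products plus a machine-readable
#' manifest (parameters, seed, per-stage record counts, package version).
#' Stage outputs are pure functions of (inputs, parameters, seed): re-running
#' with the same arguments reproduces every table bit-for-bit.
#'
#' @param trait1,trait2 Paths to delimited summary-statistics files, or
#'   tibbles already read by [read_sumstats()].
#' @param ld Path to a 3-column LD pair list, or an `ld_ref` tibble.
#' @param genes Optional gene models (path to BED6 or a tibble); when
#'   supplied, loci are annotated with nearby genes.
#' @param column_map Column mapping forwarded to [read_sumstats()].
#' @param exclusion_regions Regions removed before analysis
#'   (default HLA + MAPT, [default_exclusion_regions()]).
#' @param r2_prune LD pruning threshold (default 0.1).
#' @param n_iterations Pruning iterations for the weights (default 100).
#' @param strata Conditional Q-Q thresholds (default `c(1, .1, .01, .001)`).
#' @param conjfdr_threshold Locus significance threshold (default 0.05).
#' @param member_r2 Member-reporting LD threshold (default 0.6).
#' @param gene_window Gene annotation window in bp (default 100,000).
#' @param seed Integer seed for the pruning iterations.
#' @param out_dir Optional directory; when given, all tables and the
#'   manifest (JSON) are written there.
#' @return A list of class `conjfdr_run`: `pair`, `weights`, `lambda1`,
#'   `lambda2`, `qq`, `conjfdr`, `loci`, `manifest`.
#' @export
run_conjfdr <- function(trait1, trait2, ld, genes = NULL,
                        column_map = default_column_map(),
                        exclusion_regions = default_exclusion_regions(),
                        r2_prune = 0.1, n_iterations = 100L,
                        strata = c(1, 0.1, 0.01, 0.001),
                        conjfdr_threshold = 0.05, member_r2 = 0.6,
                        gene_window = 100000L, seed = 1L,
                        out_dir = NULL) {
  s1 <- if (is.data.frame(trait1) && "pvalue" %in% names(trait1)) trait1 else read_sumstats(trait1, column_map)
  s2 <- if (is.data.frame(trait2) && "pvalue" %in% names(trait2)) trait2 else read_sumstats(trait2, column_map)
  ld_ref <- if (inherits(ld, "ld_ref")) ld else read_ld_pairs(ld)
  gene_tbl <- if (is.null(genes) || is.data.frame(genes)) genes else read_genes_bed(genes)

  pair <- harmonize_pair(s1, s2)
  pair <- apply_exclusion_regions(pair, exclusion_regions)

  weights <- pruning_weights(ld_ref, pair$snp_id, n_iterations = n_iterations,
                             r2_threshold = r2_prune, rng_seed = seed)
  pair <- genomic_control_pair(pair, weights)
  qq <- conditional_qq(pair, weights, thresholds = strata)
  conj <- compute_conjfdr(pair, weights)
  loci <- clump_loci(conj, ld_ref, fdr_threshold = conjfdr_threshold,
                     independence_r2 = r2_prune, member_r2 = member_r2)
  if (!is.null(gene_tbl) && nrow(loci) > 0) {
    loci <- annotate_genes(loci, gene_tbl, window_bp = gene_window)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("conjfdr")),
    seed = seed,
    parameters = list(
      r2_prune = r2_prune, n_iterations = n_iterations, strata = strata,
      conjfdr_threshold = conjfdr_threshold, member_r2 = member_r2,
      gene_window = gene_window,
      exclusion_regions = as.data.frame(exclusion_regions %||% data.frame())
    ),
    lambda = list(trait1 = attr(pair, "lambda1"), trait2 = attr(pair, "lambda2")),
    counts = list(
      trait1_input = nrow(s1), trait2_input = nrow(s2),
      harmonized = nrow(pair), qq_points = nrow(qq),
      conjfdr = nrow(conj),
      significant = sum(conj$conjfdr < conjfdr_threshold),
      loci = nrow(loci)
    )
  )

  run <- structure(
    list(pair = pair, weights = weights,
         lambda1 = attr(pair, "lambda1"), lambda2 = attr(pair, "lambda2"),
         qq = qq, conjfdr = conj, loci = loci, manifest = manifest),
    class = "conjfdr_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_harmonized(pair, file.path(out_dir, "harmonized_pair.tsv"),
                     header_lines = c(
                       sprintf("#lambda_trait1=%.6f", run$lambda1),
                       sprintf("#lambda_trait2=%.6f", run$lambda2)
                     ))
    write_pruning_weights(weights, file.path(out_dir, "pruning_weights.tsv"))
    write_qq_curves(qq, file.path(out_dir, "qq_curves.tsv"))
    write_conjfdr(conj, file.path(out_dir, "conjfdr.tsv"))
    write_loci(loci, file.path(out_dir, "loci.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.conjfdr_run <- function(x, ...) {
  cat("Cross-trait conjFDR run\n")
  cat(sprintf("  harmonized variants: %d\n", nrow(x$pair)))
  cat(sprintf("  lambda (trait 1 / trait 2): %.3f / %.3f\n", x$lambda1, x$lambda2))
  cat(sprintf("  significant variants (conjFDR < %g): %d in %d locus/loci\n",
              x$manifest$parameters$conjfdr_threshold,
              x$manifest$counts$significant, nrow(x$loci)))
  invisible(x)
}
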