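# Clumping significant variants into LD-independent loci and annotating genes.

#' Clump significant variants into LD-independent loci
#'
#' Among variants with `conjfdr < fdr_threshold`, iteratively selects the
#' smallest-conjFDR variant as a locus lead (ties broken by smaller `p1`,
#' then by genomic position), assigns to its locus every remaining
#' significant variant in LD with it above `independence_r2`, removes them,
#' and repeats until all significant variants are assigned. Member variants
#' are reported when their LD with the lead exceeds `member_r2` (the lead
#' itself is listed with r2 = 1). Lead variants of distinct loci are
#' pairwise LD-independent by construction, and the result does not depend
#' on input record order.
#'
#' @param table A `conjfdr_tbl` (or tibble with `snp_id`, `chrom`, `pos`,
#'   `p1`, `conjfdr`).
#' @param ld An `ld_ref` pair list.
#' @param fdr_threshold Significance threshold on conjFDR (default 0.05).
#' @param independence_r2 LD threshold defining locus independence
#'   (default 0.1, the pruning threshold).
#' @param member_r2 LD threshold for reporting members (default 0.6).
#' @return A `loci_tbl` tibble, one row per locus: `lead_snp`, `chrom`,
#'   `pos`, `lead_conjfdr`, `lead_p1`, `lead_p2`, `n_snps`, and a `members`
#'   list-column of tibbles (`snp_id`, `r2`).
#' @export
clump_loci <- function(table, ld, fdr_threshold = 0.05,
                       independence_r2 = 0.1, member_r2 = 0.6) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            independence_r2 > 0, independence_r2 < 1)
  sig <- table |>
    # strict flag below 1; a threshold of 1 is vacuous and keeps everything
    dplyr::filter(.data$conjfdr < fdr_threshold | fdr_threshold >= 1) |>
    dplyr::arrange(.data$conjfdr, .data$p1, chrom_rank(.data$chrom), .data$pos)
  empty <- tibble::tibble(
    lead_snp = character(), chrom = character(), pos = integer(),
    lead_conjfdr = numeric(), lead_p1 = numeric(), lead_p2 = numeric(),
    n_snps = integer(), members = list()
  )
  if (nrow(sig) == 0L) {
    class(empty) <- c("loci_tbl", class(empty))
    return(empty)
  }

  # r2 lookup among significant SNPs (symmetric)
  keep <- ld$snp_i %in% sig$snp_id & ld$snp_j %in% sig$snp_id
  edges <- tibble::tibble(
    a = c(ld$snp_i[keep], ld$snp_j[keep]),
    b = c(ld$snp_j[keep], ld$snp_i[keep]),
    r2 = c(ld$r2[keep], ld$r2[keep])
  )

  assigned <- rep(FALSE, nrow(sig))
  loci <- list()
  while (!all(assigned)) {
    lead_i <- which(!assigned)[1L]
    lead <- sig[lead_i, ]
    nb <- edges[edges$a == lead$snp_id & edges$r2 > independence_r2, ]
    member_idx <- which(!assigned & (sig$snp_id %in% nb$b | seq_len(nrow(sig)) == lead_i))
    assigned[member_idx] <- TRUE
    member_ids <- sig$snp_id[member_idx]
    r2_with_lead <- c(1, nb$r2[match(setdiff(member_ids, lead$snp_id), nb$b)])
    members <- tibble::tibble(
      snp_id = c(lead$snp_id, setdiff(member_ids, lead$snp_id)),
      r2 = r2_with_lead
    )
    members <- members[members$r2 > member_r2 | members$snp_id == lead$snp_id, ]
    loci[[length(loci) + 1L]] <- tibble::tibble(
      lead_snp = lead$snp_id,
      chrom = lead$chrom,
      pos = lead$pos,
      lead_conjfdr = lead$conjfdr,
      lead_p1 = lead$p1,
      lead_p2 = if ("p2" %in% names(lead)) lead$p2 else NA_real_,
      n_snps = length(member_idx),
      members = list(members)
    )
  }
  out <- dplyr::bind_rows(loci)
  class(out) <- c("loci_tbl", class(out))
  out
}

#' Read gene models from a BED6 file
#'
#' BED 0-based half-open intervals are converted to 1-based inclusive;
#' column 4 is the gene symbol and column 6 the strand.
#'
#' @param path Path to a BED6 file.
#' @return Tibble `symbol`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes_bed <- function(path) {
  bed <- read_bed_regions(path)
  if (!all(c("name", "strand") %in% names(bed))) {
    abort("Gene BED must have 6 columns (name in 4, strand in 6).",
          class = "conjfdr_config_error")
  }
  tibble::tibble(
    symbol = bed$name, chrom = bed$chrom,
    start = bed$start, end = bed$end, strand = bed$strand
  )
}

#' Annotate loci with nearby genes
#'
#' For each locus lead position, reports all genes whose interval
#' intersects the inclusive window `[pos - window_bp, pos + window_bp]`,
#' the closest gene (distance 0 if the lead lies inside it), and the lead's
#' relation to the closest gene: `inside`, or `upstream`/`downstream`
#' taken relative to the gene's strand (the 5' side is upstream).
#'
#' @param loci A `loci_tbl` from [clump_loci()].
#' @param genes Gene models (`symbol`, `chrom`, `start`, `end`, `strand`),
#'   e.g. from [read_genes_bed()].
#' @param window_bp Window half-width in base pairs (default 100,000).
#' @return The loci table with added `genes` (list of symbols),
#'   `closest_gene`, `relation` columns.
#' @export
annotate_genes <- function(loci, genes, window_bp = 100000L) {
  ann <- purrr::map(seq_len(nrow(loci)), function(i) {
    g <- genes[genes$chrom == loci$chrom[i], ]
    if (nrow(g) == 0L) {
      inform(sprintf("annotate_genes: no gene on chromosome %s for locus %s.",
                     loci$chrom[i], loci$lead_snp[i]))
      return(list(genes = character(), closest_gene = NA_character_,
                  relation = NA_character_))
    }
    pos <- loci$pos[i]
    hit <- g$end >= pos - window_bp & g$start <= pos + window_bp
    dist <- pmax(0, pmax(g$start - pos, pos - g$end))
    k <- which.min(dist)
    relation <- if (dist[k] == 0) {
      "inside"
    } else {
      five_prime_side <- if (g$strand[k] == "-") pos > g$end[k] else pos < g$start[k]
      if (five_prime_side) "upstream" else "downstream"
    }
    list(genes = g$symbol[hit], closest_gene = g$symbol[k], relation = relation)
  })
  loci$genes <- purrr::map(ann, "genes")
  loci$closest_gene <- purrr::map_chr(ann, "closest_gene")
  loci$relation <- purrr::map_chr(ann, "relation")
  loci
}

#' Write a loci report as TSV
#'
#' One row per locus, member variants and gene lists comma-collapsed.
#'
#' @param loci An annotated `loci_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  flat <- loci |>
    dplyr::mutate(
      members = purrr::map_chr(.data$members, function(m) {
        paste(sprintf("%s(%.2f)", m$snp_id, m$r2), collapse = ",")
      }),
      genes = if ("genes" %in% names(loci)) {
        purrr::map_chr(.data$genes, paste, collapse = ",")
      } else NA_character_
    )
  readr::write_tsv(flat, path)
  invisible(path)
}
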