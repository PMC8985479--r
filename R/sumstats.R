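# Reading, validation and harmonization of GWAS summary statistics.

default_column_map <- function() {
  c(
    snp_id = "SNP", chrom = "CHR", pos = "BP",
    allele_effect = "A1", allele_other = "A2",
    beta = "BETA", se = "SE", z = "Z", pvalue = "P"
  )
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited text file with a header row and
#' returns a validated per-variant tibble with standard column names
#' (`snp_id`, `chrom`, `pos`, `allele_effect`, `allele_other`, `z`, `beta`,
#' `se`, `pvalue`). Records failing validation are dropped and counted in a
#' message:
#' * missing or non-numeric p, or p outside the half-open interval (0, 1]
#' * alleles that are not single A/C/G/T characters
#' * duplicate (chrom, pos) positions: the record with the smallest p wins.
#'
#' A z-score column is required unless both `beta` and `se` are mapped, in
#' which case `z = beta / se` is derived.
#'
#' @param path Path to a delimited text file, or a data frame already in
#'   memory (with source column names).
#' @param column_map Named character vector mapping standard field names to
#'   source column names. Defaults to
#'   `c(snp_id = "SNP", chrom = "CHR", pos = "BP", allele_effect = "A1",
#'   allele_other = "A2", beta = "BETA", se = "SE", z = "Z", pvalue = "P")`.
#'   Entries for columns absent from the file may be dropped from the map.
#' @return A tibble sorted by (chrom, pos), one row per retained variant.
#' @export
read_sumstats <- function(path, column_map = default_column_map()) {
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    tibble::as_tibble(read.table(path, header = TRUE, colClasses = NA,
                                 stringsAsFactors = FALSE,
                                 check.names = FALSE))
  }

  needed <- c("snp_id", "chrom", "pos", "allele_effect", "allele_other", "pvalue")
  map <- column_map[column_map %in% names(raw)]
  missing_mand <- setdiff(needed, names(map))
  if (length(missing_mand) > 0) {
    abort(paste0(
      "Mandatory column(s) not found in input: ",
      paste(column_map[missing_mand], collapse = ", ")
    ), class = "conjfdr_config_error")
  }
  has_z <- "z" %in% names(map)
  has_beta_se <- all(c("beta", "se") %in% names(map))
  if (!has_z && !has_beta_se) {
    abort("Need either a z column or both beta and se columns.",
          class = "conjfdr_config_error")
  }

  tbl <- tibble::tibble(
    snp_id = as.character(raw[[map[["snp_id"]]]]),
    chrom = sub("^chr", "", as.character(raw[[map[["chrom"]]]])),
    pos = suppressWarnings(as.integer(raw[[map[["pos"]]]])),
    allele_effect = toupper(as.character(raw[[map[["allele_effect"]]]])),
    allele_other = toupper(as.character(raw[[map[["allele_other"]]]])),
    beta = if ("beta" %in% names(map)) as.numeric(raw[[map[["beta"]]]]) else NA_real_,
    se = if ("se" %in% names(map)) as.numeric(raw[[map[["se"]]]]) else NA_real_,
    z = if (has_z) suppressWarnings(as.numeric(raw[[map[["z"]]]])) else NA_real_,
    pvalue = suppressWarnings(as.numeric(raw[[map[["pvalue"]]]]))
  )
  tbl$z <- dplyr::if_else(is.na(tbl$z) & !is.na(tbl$beta) & !is.na(tbl$se) & tbl$se > 0,
                          tbl$beta / tbl$se, tbl$z)

  n0 <- nrow(tbl)
  ok_p <- !is.na(tbl$pvalue) & tbl$pvalue > 0 & tbl$pvalue <= 1
  if (any(!ok_p)) inform(sprintf("read_sumstats: dropped %d record(s) with invalid p-value.", sum(!ok_p)))
  tbl <- tbl[ok_p, ]

  ok_allele <- tbl$allele_effect %in% c("A", "C", "G", "T") &
    tbl$allele_other %in% c("A", "C", "G", "T") &
    tbl$allele_effect != tbl$allele_other
  if (any(!ok_allele)) inform(sprintf("read_sumstats: dropped %d record(s) with non-ACGT or degenerate alleles.", sum(!ok_allele)))
  tbl <- tbl[ok_allele, ]

  ok_core <- !is.na(tbl$pos) & !is.na(tbl$z)
  if (any(!ok_core)) inform(sprintf("read_sumstats: dropped %d record(s) with missing position or z.", sum(!ok_core)))
  tbl <- tbl[ok_core, ]

  # duplicate positions: keep the most significant record
  tbl <- tbl |>
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos, .data$pvalue) |>
    dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  if (nrow(tbl) < sum(ok_core)) {
    inform(sprintf("read_sumstats: collapsed %d duplicate position(s), keeping smallest p.",
                   sum(ok_core) - nrow(tbl)))
  }

  if (nrow(tbl) == 0L) {
    abort("No valid summary-statistics records after filtering.",
          class = "conjfdr_input_error")
  }
  tbl
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize two summary-statistics tables into a paired table
#'
#' Inner-joins two validated tables on (chrom, pos) — not on variant id,
#' because id dialects differ across GWAS releases — and aligns the second
#' trait's z-score to the first trait's effect-allele orientation:
#' * identical allele labels: `z2` kept as-is;
#' * effect/other alleles swapped in `b` relative to `a`: `z2` sign-flipped;
#' * any other allele combination: record dropped as a mismatch.
#'
#' Strand-ambiguous (A/T and C/G) variants are dropped because their
#' orientation cannot be verified across studies. Drop counts are reported.
#'
#' @param a,b Tibbles from [read_sumstats()]; `a` is trait 1 (primary),
#'   `b` is trait 2 (conditional).
#' @return A tibble sorted by (chrom, pos) with columns `snp_id`, `chrom`,
#'   `pos`, `allele_effect`, `allele_other`, `z1`, `p1`, `z2`, `p2`.
#' @export
harmonize_pair <- function(a, b) {
  j <- dplyr::inner_join(
    dplyr::select(a, "snp_id", "chrom", "pos", "allele_effect", "allele_other",
                  z1 = "z", p1 = "pvalue"),
    dplyr::select(b, "chrom", "pos", b_a1 = "allele_effect", b_a2 = "allele_other",
                  z2 = "z", p2 = "pvalue"),
    by = c("chrom", "pos")
  )
  if (nrow(j) == 0L) {
    abort("No variants shared between the two tables.", class = "conjfdr_input_error")
  }

  ambiguous <- is_strand_ambiguous(j$allele_effect, j$allele_other)
  same <- j$allele_effect == j$b_a1 & j$allele_other == j$b_a2
  swapped <- j$allele_effect == j$b_a2 & j$allele_other == j$b_a1
  mismatch <- !same & !swapped

  if (any(ambiguous)) inform(sprintf("harmonize_pair: dropped %d strand-ambiguous (A/T, C/G) variant(s).", sum(ambiguous)))
  if (any(mismatch & !ambiguous)) inform(sprintf("harmonize_pair: dropped %d allele-mismatched variant(s).", sum(mismatch & !ambiguous)))

  j <- j[!ambiguous & !mismatch, ]
  flip <- j$allele_effect == j$b_a2
  j$z2[flip] <- -j$z2[flip]

  j |>
    dplyr::select("snp_id", "chrom", "pos", "allele_effect", "allele_other",
                  "z1", "p1", "z2", "p2") |>
    sort_by_position()
}

#' Default excluded regions: extended HLA and MAPT (GRCh37)
#'
#' The major-histocompatibility-complex region on chromosome 6 and the
#' microtubule-associated-protein-tau inversion region on chromosome 17
#' carry long-range LD that distorts empirical FDR estimation, so variants
#' inside them are removed before any downstream analysis.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive).
#' @export
default_exclusion_regions <- function() {
  tibble::tibble(
    chrom = c("6", "17"),
    start = c(25119106L, 40000000L),
    end = c(33854733L, 47000000L)
  )
}

#' Remove variants inside excluded genomic regions
#'
#' @param pair A harmonized pair (or any tibble with `chrom` and `pos`).
#' @param regions Tibble of regions (`chrom`, `start`, `end`, 1-based
#'   inclusive); defaults to the HLA and MAPT regions
#'   ([default_exclusion_regions()]). An empty region list is a no-op.
#' @return The input without records falling inside any region; idempotent.
#' @export
apply_exclusion_regions <- function(pair, regions = default_exclusion_regions()) {
  if (is.null(regions) || nrow(regions) == 0L) return(pair)
  stopifnot(all(regions$start <= regions$end))
  drop <- rep(FALSE, nrow(pair))
  for (i in seq_len(nrow(regions))) {
    drop <- drop | (pair$chrom == regions$chrom[i] &
                      pair$pos >= regions$start[i] &
                      pair$pos <= regions$end[i])
  }
  if (any(drop)) inform(sprintf("apply_exclusion_regions: removed %d variant(s).", sum(drop)))
  pair[!drop, ]
}

#' Read genomic regions from a BED file
#'
#' BED is 0-based half-open; coordinates are converted to the 1-based
#' inclusive convention used throughout the package.
#'
#' @param path Path to a BED file (at least 3 columns, no header).
#' @return Tibble with `chrom`, `start`, `end` (plus `name`, `strand` when
#'   present as BED columns 4 and 6).
#' @export
read_bed_regions <- function(path) {
  bed <- tibble::as_tibble(read.table(path, header = FALSE, sep = "",
                                      stringsAsFactors = FALSE))
  out <- tibble::tibble(
    chrom = sub("^chr", "", as.character(bed[[1]])),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]])
  )
  if (ncol(bed) >= 4) out$name <- as.character(bed[[4]])
  if (ncol(bed) >= 6) out$strand <- as.character(bed[[6]])
  stopifnot(all(out$start <= out$end))
  out
}

#' Write a harmonized pair as tab-separated text
#'
#' Fixed column order: snp_id, chrom, pos, a1, a2, z1, p1, z2, p2.
#'
#' @param pair Harmonized pair tibble.
#' @param path Output path.
#' @param header_lines Optional character vector of `#`-prefixed provenance
#'   lines written before the header.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(pair, path, header_lines = character()) {
  out <- dplyr::select(pair, "snp_id", "chrom", "pos",
                       a1 = "allele_effect", a2 = "allele_other",
                       "z1", "p1", "z2", "p2")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines(paste(names(out), collapse = "\t"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
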