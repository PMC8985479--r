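# Genotype panels: additive dosage matrices with a variant map.

#' Construct a genotype panel
#'
#' @param dosage Samples x variants numeric matrix of additive dosages
#'   (0/1/2, `NA` allowed); column names are variant ids.
#' @param map Tibble with `snp_id`, `chrom`, `pos` in the column order of
#'   `dosage`.
#' @return A `genotype_panel` list.
#' @export
genotype_panel <- function(dosage, map) {
  stopifnot(is.matrix(dosage), identical(colnames(dosage), map$snp_id))
  structure(list(dosage = dosage, map = tibble::as_tibble(map)),
            class = "genotype_panel")
}

#' Read a PLINK-style additive text panel
#'
#' Expects a whitespace/tab-delimited file in `.raw` style: a header row of
#' variant ids (any leading sample-metadata columns are matched by name
#' against `map$snp_id` and non-matching columns ignored), one sample per
#' line, dosages 0/1/2 with `NA` for missing.
#'
#' @param path Path to the text panel.
#' @param map Tibble `snp_id`, `chrom`, `pos` describing variant positions.
#' @return A `genotype_panel`.
#' @export
read_raw_genotypes <- function(path, map) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  cols <- intersect(map$snp_id, names(raw))
  if (length(cols) == 0) {
    abort("No variant columns from `map` found in the panel header.",
          class = "conjfdr_input_error")
  }
  m <- as.matrix(raw[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  genotype_panel(m, map[match(cols, map$snp_id), ])
}

#' Read a genotype panel from VCF
#'
#' Converts GT fields to additive dosages (count of ALT alleles); requires
#' the `vcfR` package. Multi-allelic records are skipped.
#'
#' @param path Path to a VCF file.
#' @return A `genotype_panel`.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Package 'vcfR' is required to read VCF genotype panels.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix$ALT)
  fix <- fix[biallelic, ]
  gt <- gt[biallelic, , drop = FALSE]
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  m <- t(dose)
  colnames(m) <- ids
  genotype_panel(m, tibble::tibble(
    snp_id = ids,
    chrom = sub("^chr", "", fix$CHROM),
    pos = as.integer(fix$POS)
  ))
}
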