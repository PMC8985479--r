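# Published reference values shipped with the package.

#' Reported shared loci between MSA and IBD/CD
#'
#' The three lead variants reported as shared between multiple system
#' atrophy (MSA) and inflammatory bowel disease (IBD) / Crohn's disease
#' (CD), with their published conjFDR values against each immune trait
#' (GRCh37 positions). Useful as a reference input for significance-flag
#' logic: at conjFDR < 0.05, three loci are significant against CD and two
#' against IBD.
#'
#' @return Tibble `lead_snp`, `chr_region`, `pos`, `conjfdr_cd`,
#'   `conjfdr_ibd`, `closest_gene`, `relation`.
#' @export
reported_shared_loci <- function() {
  path <- system.file("extdata", "reported_shared_loci.tsv",
                      package = "conjfdr", mustWork = TRUE)
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = c(pos = "integer")))
}
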