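two_cluster_table <- function(shuffle = FALSE) {
  tbl <- tibble::tibble(
    snp_id = paste0("s", 1:6),
    chrom = c("1", "1", "1", "2", "2", "2"),
    pos = as.integer(c(1e6, 1.1e6, 1.2e6, 5e6, 5.1e6, 5.2e6)),
    p1 = c(1e-5, 2e-5, 3e-5, 4e-6, 5e-5, 6e-5),
    p2 = c(1e-4, 2e-4, 3e-4, 4e-4, 5e-4, 6e-4),
    conjfdr = c(0.02, 0.03, 0.04, 0.01, 0.035, 0.045)
  )
  if (shuffle) tbl <- tbl[c(5, 2, 6, 1, 4, 3), ]
  tbl
}

two_cluster_ld <- function() {
  ld_ref_tbl(
    c("s1", "s1", "s2", "s4", "s4", "s5"),
    c("s2", "s3", "s3", "s5", "s6", "s6"),
    rep(0.8, 6)
  )
}

test_that("clumping returns an empty table when nothing is significant", {
  out <- clump_loci(two_cluster_table(), two_cluster_ld(), fdr_threshold = 0.001)
  expect_equal(nrow(out), 0L)
})

test_that("two unlinked clusters give two loci with per-cluster minima as leads", {
  for (shuffle in c(FALSE, TRUE)) {
    out <- clump_loci(two_cluster_table(shuffle), two_cluster_ld())
    expect_equal(nrow(out), 2L)
    expect_setequal(out$lead_snp, c("s4", "s1"))   # cluster minima
    expect_equal(out$lead_snp[1], "s4")            # smallest conjFDR first
    expect_equal(sum(out$n_snps), 6L)              # every significant SNP assigned
    # members tagged at r2 > 0.6 with the lead
    m <- out$members[[which(out$lead_snp == "s1")]]
    expect_setequal(m$snp_id, c("s1", "s2", "s3"))
    expect_true(all(m$r2[m$snp_id != "s1"] > 0.6))
  }
})

test_that("locus leads are pairwise LD-independent and ties break deterministically", {
  tbl <- two_cluster_table()
  tbl$conjfdr <- rep(0.02, 6)          # all tied: fall back to p1 then position
  out <- clump_loci(tbl, two_cluster_ld())
  expect_equal(out$lead_snp[1], "s4")  # smallest p1
  ld <- two_cluster_ld()
  lead_pairs <- ld$snp_i %in% out$lead_snp & ld$snp_j %in% out$lead_snp
  expect_false(any(ld$r2[lead_pairs] > 0.1))
})

test_that("weakly linked significant SNPs become their own locus", {
  tbl <- two_cluster_table()[1:2, ]
  ld <- ld_ref_tbl("s1", "s2", 0.05)   # below independence threshold
  out <- clump_loci(tbl, ld)
  expect_equal(nrow(out), 2L)
})

test_that("gene annotation classifies inside/upstream/downstream by strand", {
  genes <- tibble::tibble(
    symbol = c("GINSIDE", "GPLUS", "GMINUS", "GFAR"),
    chrom = "1",
    start = c(950000L, 1080000L, 800000L, 5000000L),
    end = c(1050000L, 1150000L, 900000L, 5100000L),
    strand = c("+", "+", "-", "+")
  )
  loci <- clump_loci(two_cluster_table()[1:3, ], two_cluster_ld())
  ann <- annotate_genes(loci, genes)
  expect_setequal(ann$genes[[1]], c("GINSIDE", "GPLUS", "GMINUS"))
  expect_equal(ann$closest_gene, "GINSIDE")
  expect_equal(ann$relation, "inside")

  # 5 kb from the 3' end of a minus-strand gene: lead at 1e6, gene ends 995000
  genes2 <- tibble::tibble(symbol = "GM", chrom = "1", start = 900000L,
                           end = 995000L, strand = "-")
  ann2 <- annotate_genes(loci, genes2)
  expect_equal(ann2$relation, "upstream")     # 5' side of a minus-strand gene
  genes3 <- dplyr::mutate(genes2, strand = "+")
  expect_equal(annotate_genes(loci, genes3)$relation, "downstream")
})

test_that("the 100 kb gene window is inclusive at its boundary", {
  loci <- clump_loci(two_cluster_table()[1:3, ], two_cluster_ld())
  # lead at 1,000,000; gene starting exactly 100,000 bp away is included
  genes <- tibble::tibble(symbol = c("EDGE", "OUT"), chrom = "1",
                          start = c(1100000L, 1100001L),
                          end = c(1150000L, 1150001L), strand = "+")
  ann <- annotate_genes(loci, genes)
  expect_true("EDGE" %in% ann$genes[[1]])
  expect_false("OUT" %in% ann$genes[[1]])
})

test_that("annotation handles chromosomes without genes", {
  loci <- clump_loci(two_cluster_table(), two_cluster_ld())
  genes <- tibble::tibble(symbol = "G1", chrom = "1", start = 990000L,
                          end = 1010000L, strand = "+")
  ann <- quiet(annotate_genes(loci, genes))
  chr2 <- which(ann$chrom == "2")
  expect_length(ann$genes[[chr2]], 0L)
  expect_true(is.na(ann$relation[chr2]))
})

test_that("reported shared-locus conjFDR values flag 3 CD and 2 IBD loci", {
  rep_loci <- reported_shared_loci()
  expect_equal(nrow(rep_loci), 3L)
  expect_equal(sum(rep_loci$conjfdr_cd < 0.05), 3L)
  expect_equal(sum(rep_loci$conjfdr_ibd < 0.05), 2L)
  expect_equal(
    rep_loci$lead_snp[rep_loci$conjfdr_cd < 0.05],
    c("rs12740041", "rs4957144", "rs116843836")
  )
})

test_that("BED6 gene files convert to 1-based inclusive intervals", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tGENE1\t0\t-", path)
  g <- read_genes_bed(path)
  expect_equal(g$start, 1000L)
  expect_equal(g$end, 2000L)
  expect_equal(g$strand, "-")
})
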