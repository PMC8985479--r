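test_that("read_sumstats validates p-values and alleles", {
  df <- data.frame(SNP = c("a", "b", "c"), CHR = 1, BP = 1:3 * 1000,
                   A1 = "A", A2 = "G", Z = 1, P = c(0.5, 1.0, 0.01))
  expect_equal(nrow(quiet(read_sumstats(df))), 3L)

  df_bad <- rbind(df, data.frame(SNP = "d", CHR = 1, BP = 4000,
                                 A1 = "A", A2 = "G", Z = 1, P = 0))
  expect_message(out <- read_sumstats(df_bad), "1 record")
  expect_equal(nrow(out), 3L)

  # packaged fixture: 10 records, 2 with non-ACGT alleles
  fx <- quiet(read_sumstats(extdata("demo_trait1.tsv")))
  expect_equal(nrow(fx), 8L)
  expect_false(any(fx$snp_id %in% c("rs003", "rs007")))

  # duplicate positions keep the smaller p
  df_dup <- data.frame(SNP = c("x", "y"), CHR = 1, BP = 1000,
                       A1 = "A", A2 = "G", Z = c(1, 2), P = c(0.3, 0.05))
  out <- quiet(read_sumstats(df_dup))
  expect_equal(out$snp_id, "y")
})

test_that("read_sumstats errors on missing columns and empty tables", {
  df <- data.frame(SNP = "a", CHR = 1, BP = 1000, A1 = "A", A2 = "G", Z = 1)
  expect_error(read_sumstats(df), class = "conjfdr_config_error")
  df2 <- data.frame(SNP = "a", CHR = 1, BP = 1000, A1 = "A", A2 = "G",
                    Z = 1, P = 0)
  expect_error(quiet(read_sumstats(df2)), class = "conjfdr_input_error")
})

test_that("read_sumstats derives z from beta and se", {
  df <- data.frame(SNP = "a", CHR = 1, BP = 1000, A1 = "A", A2 = "G",
                   BETA = 0.4, SE = 0.2, P = 0.05)
  out <- quiet(read_sumstats(df))
  expect_equal(out$z, 2)
})

test_that("harmonize_pair aligns alleles and drops ambiguous/mismatched", {
  a <- quiet(read_sumstats(extdata("harm_trait_a.tsv")))
  b <- quiet(read_sumstats(extdata("harm_trait_b.tsv")))
  h <- quiet(harmonize_pair(a, b))
  expect_equal(nrow(h), 8L)                      # 1 A/T + 1 mismatch dropped
  expect_false("rsa03" %in% h$snp_id)            # strand-ambiguous
  expect_false("rsa06" %in% h$snp_id)            # allele mismatch
  # identical labels: z2 unchanged; swapped labels: z2 sign-flipped
  expect_equal(h$z2[h$snp_id == "rsa01"], 0.9)
  expect_equal(h$z2[h$snp_id == "rsa02"], -1.7)
})

test_that("harmonization is symmetric up to trait-role swap", {
  a <- quiet(read_sumstats(extdata("harm_trait_a.tsv")))
  b <- quiet(read_sumstats(extdata("harm_trait_b.tsv")))
  ab <- quiet(harmonize_pair(a, b))
  ba <- quiet(harmonize_pair(b, a))
  m <- match(paste(ab$chrom, ab$pos), paste(ba$chrom, ba$pos))
  expect_false(anyNA(m))
  # z magnitudes swap roles; signs agree after re-orienting to a's alleles
  flip <- ab$allele_effect != ba$allele_effect[m]
  expect_equal(ab$z1, ifelse(flip, -1, 1) * ba$z2[m])
  expect_equal(ab$p1, ba$p2[m])
  expect_equal(ab$p2, ba$p1[m])
})

test_that("harmonize_pair errors on empty intersection", {
  a <- quiet(read_sumstats(data.frame(SNP = "a", CHR = 1, BP = 1000,
                                      A1 = "A", A2 = "G", Z = 1, P = 0.5)))
  b <- quiet(read_sumstats(data.frame(SNP = "b", CHR = 2, BP = 9000,
                                      A1 = "A", A2 = "G", Z = 1, P = 0.5)))
  expect_error(harmonize_pair(a, b), class = "conjfdr_input_error")
})

test_that("exclusion regions remove HLA/MAPT variants with inclusive bounds", {
  pair <- pair_from_p(rep(0.5, 4), rep(0.5, 4),
                      chrom = c("6", "17", "6", "2"),
                      pos = c(30000000L, 41000000L, 25119105L, 30000000L))
  out <- quiet(apply_exclusion_regions(pair))
  expect_equal(nrow(out), 2L)
  expect_true(all(c(25119105L, 30000000L) %in% out$pos))
  expect_true("2" %in% out$chrom)          # other chromosome untouched
  expect_true("6" %in% out$chrom)          # one below inclusive start retained
  # idempotent; empty region list is a no-op
  expect_identical(quiet(apply_exclusion_regions(out)), out)
  expect_identical(apply_exclusion_regions(pair, regions = NULL), pair)
})

test_that("operations preserve (chrom, pos) sort order", {
  run <- cached_small_run()
  pos_key <- order(conjfdr:::chrom_rank(run$pair$chrom), run$pair$pos)
  expect_identical(pos_key, seq_len(nrow(run$pair)))
})

test_that("harmonized pairs round-trip through the TSV writer", {
  pair <- pair_from_p(c(0.1, 0.2), c(0.3, 0.4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(pair, path, header_lines = "#lambda_trait1=1.0")
  txt <- readLines(path)
  expect_match(txt[1], "^#lambda")
  reread <- read.table(path, header = TRUE, comment.char = "#")
  expect_equal(reread$p1, pair$p1)
  expect_equal(reread$z2, pair$z2)
})
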