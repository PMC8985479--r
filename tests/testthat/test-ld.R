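make_panel <- function(dosages, pos = NULL, chrom = "1") {
  m <- do.call(cbind, dosages)
  colnames(m) <- names(dosages)
  genotype_panel(m, tibble::tibble(
    snp_id = names(dosages),
    chrom = rep_len(chrom, length(dosages)),
    pos = if (is.null(pos)) as.integer(seq_along(dosages) * 1000) else as.integer(pos)
  ))
}

test_that("compute_r2 matches direct Pearson correlation", {
  panel <- make_panel(list(
    v1 = c(0, 1, 2, 0),
    v2 = c(0, 1, 2, 0),
    v3 = c(2, 1, 0, 2)
  ))
  ld <- compute_r2(panel)
  get <- function(i, j) ld$r2[(ld$snp_i == i & ld$snp_j == j) |
                                (ld$snp_i == j & ld$snp_j == i)]
  expect_equal(get("v1", "v2"), 1.0)         # identical vectors
  expect_equal(get("v1", "v3"), 1.0)         # anti-correlation squares to 1

  panel6 <- make_panel(list(
    a = c(0, 1, 2, 1, 0, 2),
    b = c(0, 0, 2, 2, 1, 1)
  ))
  ld6 <- compute_r2(panel6)
  expect_equal(ld6$r2, cor(c(0, 1, 2, 1, 0, 2), c(0, 0, 2, 2, 1, 1))^2,
               tolerance = 1e-12)
})

test_that("compute_r2 honours the window and omits monomorphic variants", {
  panel <- make_panel(list(
    near1 = c(0, 1, 2, 0, 1),
    near2 = c(0, 1, 2, 0, 2),
    far = c(0, 1, 2, 1, 0),
    mono = c(1, 1, 1, 1, 1)
  ), pos = c(1e6, 1.5e6, 9e7, 1.6e6))
  ld <- quiet(compute_r2(panel, window_bp = 2e7))
  expect_false("far" %in% c(ld$snp_i, ld$snp_j))   # beyond the window
  expect_false("mono" %in% c(ld$snp_i, ld$snp_j))  # undefined correlation
  expect_true(nrow(ld) >= 1)
})

test_that("random_prune implements the greedy seeded independent-set rule", {
  # no pair above threshold: everything retained
  ld0 <- ld_ref_tbl(character(), character(), numeric())
  expect_setequal(random_prune(ld0, c("a", "b", "c"), rng_seed = 1), c("a", "b", "c"))

  # a linked pair: exactly one survivor, and it tags the other
  ld2 <- ld_ref_tbl("a", "b", 0.9)
  kept <- random_prune(ld2, c("a", "b"), rng_seed = 5)
  expect_length(kept, 1L)

  # 5-SNP chain: replay the greedy rule independently for the seeded order
  snps <- paste0("s", 1:5)
  ld5 <- ld_ref_tbl(c("s1", "s2", "s3"), c("s2", "s3", "s4"), c(0.5, 0.5, 0.05))
  for (seed in 1:10) {
    kept <- random_prune(ld5, snps, r2_threshold = 0.1, rng_seed = seed)
    ord <- withr::with_seed(seed, sample.int(5))
    linked <- list(s1 = "s2", s2 = c("s1", "s3"), s3 = "s2", s4 = character(), s5 = character())
    retained <- character()
    for (i in ord) {
      s <- snps[i]
      if (!any(linked[[s]] %in% retained)) retained <- c(retained, s)
    }
    expect_setequal(kept, retained)
    # maximality: every dropped SNP is linked to a retained one
    for (s in setdiff(snps, kept)) expect_true(any(linked[[s]] %in% kept))
  }
})

test_that("pruning weights match enumeration expectations", {
  # LD-independent SNPs always retained
  ld0 <- ld_ref_tbl("a", "b", 0.05)
  w0 <- pruning_weights(ld0, c("a", "b", "c"), n_iterations = 50, rng_seed = 2)
  expect_equal(w0$weight, c(1, 1, 1))

  # fully linked pair: each retained in half the iterations (se ~ 0.016 at 1000)
  ld2 <- ld_ref_tbl("a", "b", 1.0)
  w2 <- pruning_weights(ld2, c("a", "b"), n_iterations = 1000, rng_seed = 3)
  expect_lt(max(abs(w2$weight - 0.5)), 3 * sqrt(0.25 / 1000))
  expect_equal(sum(w2$weight), 1)          # exactly one survivor per iteration

  # 3-clique: equally likely visit orders give expectation 1/3 each
  ld3 <- ld_ref_tbl(c("a", "a", "b"), c("b", "c", "c"), c(0.9, 0.9, 0.9))
  w3 <- pruning_weights(ld3, c("a", "b", "c"), n_iterations = 2000, rng_seed = 4)
  expect_lt(max(abs(w3$weight - 1 / 3)), 3 * sqrt((1 / 3) * (2 / 3) / 2000))
  expect_equal(sum(w3$weight), 1)
})

test_that("pruning weights are deterministic and threshold-monotone on cliques", {
  ld <- ld_ref_tbl(c("a", "b"), c("b", "c"), c(0.3, 0.15))
  w1 <- pruning_weights(ld, c("a", "b", "c"), n_iterations = 500, rng_seed = 9)
  w2 <- pruning_weights(ld, c("a", "b", "c"), n_iterations = 500, rng_seed = 9)
  expect_identical(w1$weight, w2$weight)

  # on a clique, raising the threshold above an edge removes conflicts and
  # every weight rises (this does not hold on arbitrary graphs: dropping a
  # chain edge can promote a middle SNP and suppress its neighbour)
  ld3 <- ld_ref_tbl(c("a", "a", "b"), c("b", "c", "c"), c(0.9, 0.9, 0.9))
  w_lo <- pruning_weights(ld3, c("a", "b", "c"), n_iterations = 500,
                          r2_threshold = 0.1, rng_seed = 9)
  w_hi <- pruning_weights(ld3, c("a", "b", "c"), n_iterations = 500,
                          r2_threshold = 0.95, rng_seed = 9)
  expect_true(all(w_hi$weight >= w_lo$weight))
  expect_equal(w_hi$weight, rep(1, 3))
})

test_that("weights TSV round-trips with provenance header", {
  ld <- ld_ref_tbl("a", "b", 0.9)
  w <- pruning_weights(ld, c("a", "b"), n_iterations = 100, rng_seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pruning_weights(w, path)
  txt <- readLines(path)
  expect_match(txt[1], "#n_iterations=100")
  reread <- read.table(path, header = TRUE, comment.char = "#", sep = "\t")
  expect_equal(reread$weight, w$weight)
})

test_that("ld pair lists read from text with and without header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_i\tsnp_j\tr2", "a\tb\t0.8"), path)
  expect_equal(read_ld_pairs(path)$r2, 0.8)
  writeLines("a\tb\t0.8", path)
  expect_equal(read_ld_pairs(path)$r2, 0.8)
})
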