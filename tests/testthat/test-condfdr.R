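test_that("weighted_ecdf follows its defining formula", {
  f <- weighted_ecdf(c(0.1, 0.2), c(1, 0.5))
  expect_equal(f(0.1), 1 / 1.5)
  expect_equal(f(0.2), 1)
  expect_equal(f(0.05), 0)                      # below the minimum
  f_eq <- weighted_ecdf(c(3, 1, 2))
  expect_equal(f_eq(c(1, 2, 3)), c(1, 2, 3) / 3) # reduces to ordinary ecdf
  expect_error(weighted_ecdf(1:3, c(0, 0, 0)))
})

test_that("condFDR matches brute-force counting on small strata", {
  # 5 equally weighted SNPs in the conditioning stratum
  pair <- pair_from_p(c(0.001, 0.02, 0.3, 0.5, 0.9), rep(0.05, 5))
  expect_equal(condfdr_at(pair, 0.02, cut = 0.1), 0.02 / (2 / 5))
  # a single SNP below the query in a stratum of total weight 5
  pair2 <- pair_from_p(c(1e-6, 0.3, 0.5, 0.7, 0.9), rep(0.05, 5))
  expect_equal(condfdr_at(pair2, 1e-6, cut = 0.1), 1e-6 / (1 / 5))
})

test_that("the condFDR grid is monotone, bounded, and 1 at p1 = 1", {
  run <- cached_small_run()
  g <- quiet(build_condfdr_grid(run$pair, run$weights))
  expect_true(all(g$values > 0 & g$values <= 1))
  expect_true(all(g$values[length(g$p1), ] == 1))          # p1 = 1 row
  expect_true(all(apply(g$values, 2, function(v) all(diff(v) >= 0))))
  # stricter conditioning never increases the estimate
  expect_true(all(apply(g$values, 1, function(v) all(diff(v) >= 0))))
})

test_that("grid values are ~1 under independent uniform traits", {
  set.seed(42)
  pair <- pair_from_p(runif(5000), runif(5000))
  g <- quiet(build_condfdr_grid(pair, NULL))
  # in well-populated strata (>= ~500 variants) and away from the sparse
  # tail, the estimate sits near 1; sparsely conditioned columns are
  # noisier and the cross-cut running minimum makes them conservative
  sel_p1 <- g$p1 > 0.01
  sel_cut <- g$cuts >= 0.1
  expect_gt(stats::median(g$values[sel_p1, sel_cut]), 0.8)
  expect_true(all(g$values[sel_p1, sel_cut] > 0.2))
})

test_that("lookup interpolates log-linearly and clamps at boundaries", {
  g <- structure(list(
    p1 = c(0.001, 0.01, 0.1, 1),
    cuts = c(0.1, 1),
    values = matrix(c(0.001, 0.01, 0.04, 1, 0.001, 0.01, 0.04, 1), ncol = 2),
    values_raw = NULL, orientation = "1given2"
  ), class = "condfdr_grid")
  # exact node
  expect_equal(lookup_condfdr(g, 0.01, 0.1), 0.01)
  expect_equal(lookup_condfdr(g, 1, 1), 1)
  # log-midpoint between nodes with values 0.01 and 0.04 -> 0.02
  mid <- 10^mean(log10(c(0.01, 0.1)))
  expect_equal(lookup_condfdr(g, mid, 0.1), sqrt(0.01 * 0.04))
  # clamping outside the grid
  expect_equal(lookup_condfdr(g, 1e-9, 0.1), 0.001)
})

test_that("worked fixture reproduces hand-computed condFDR values", {
  wf <- make_worked_fixture()
  expect_equal(nrow(wf$pair), 10L)
  # direct counting at each SNP's own (p1, p2) equals the frozen sidecar
  direct12 <- vapply(seq_len(10), function(i) {
    condfdr_at(wf$pair, wf$pair$p1[i], wf$pair$p2[i], wf$weights)
  }, numeric(1))
  expect_equal(direct12, wf$expected$cfdr_1given2, tolerance = 1e-12)
  # headline example
  expect_equal(condfdr_at(wf$pair, 0.02, 0.1, wf$weights), 0.05, tolerance = 1e-12)
  # packaged fixture files round-trip with zero drops
  s1 <- read_sumstats(extdata("worked_fixture_trait1.tsv"))
  s2 <- read_sumstats(extdata("worked_fixture_trait2.tsv"))
  expect_equal(nrow(s1), 10L)
  expect_equal(harmonize_pair(s1, s2)$p1, wf$pair$p1)
  frozen <- read.table(extdata("worked_fixture_expected.tsv"), header = TRUE, sep = "\t")
  expect_equal(frozen$conjfdr, wf$expected$conjfdr, tolerance = 1e-12)
})

test_that("grid construction equals a naive double-loop oracle", {
  wf <- make_worked_fixture()
  p1g <- sort(unique(wf$pair$p1))
  p2c <- sort(unique(wf$pair$p2))
  g <- quiet(build_condfdr_grid(wf$pair, wf$weights, p1g, p2c))

  # naive oracle: direct counting, then the same two monotone passes
  # written as explicit loops
  raw <- matrix(NA_real_, length(p1g), length(p2c))
  for (j in seq_along(p2c)) {
    stratum <- wf$pair$p1[wf$pair$p2 <= p2c[j]]
    for (i in seq_along(p1g)) {
      Fhat <- max(sum(stratum <= p1g[i]), 1) / length(stratum)
      raw[i, j] <- min(1, p1g[i] / Fhat)
    }
  }
  expect_equal(g$values_raw, raw, tolerance = 1e-12)
  mono <- raw
  for (j in seq_along(p2c)) for (i in seq_along(p1g)[-1]) {
    mono[i, j] <- max(mono[i, j], mono[i - 1, j])
  }
  for (i in seq_along(p1g)) for (j in rev(seq_along(p2c))[-1]) {
    mono[i, j] <- min(mono[i, j], mono[i, j + 1])
  }
  expect_equal(g$values, mono, tolerance = 1e-12)
})

test_that("conjFDR is the max of the two orientations and role-symmetric", {
  run <- cached_small_run()
  cj <- quiet(compute_conjfdr(run$pair, run$weights))
  expect_equal(cj$conjfdr, pmax(cj$cfdr_1given2, cj$cfdr_2given1))
  expect_true(all(cj$conjfdr > 0 & cj$conjfdr <= 1))

  # swapping trait roles leaves conjfdr unchanged
  swapped <- run$pair
  names(swapped)[match(c("z1", "p1", "z2", "p2"), names(swapped))] <-
    c("z2", "p2", "z1", "p1")
  cj_sw <- quiet(compute_conjfdr(swapped, run$weights))
  expect_equal(cj_sw$conjfdr, cj$conjfdr, tolerance = 1e-12)

  # determinism: identical inputs give identical tables
  cj2 <- quiet(compute_conjfdr(run$pair, run$weights))
  expect_identical(tidy(cj), tidy(cj2))
})
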