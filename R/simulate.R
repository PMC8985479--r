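# Synthetic bivariate GWAS data: blockwise-LD summary statistics with
# trait-specific and shared causal variants, genotype panels, gene models,
# and SKAT case-control fixtures.

#' Simulate a paired bivariate GWAS summary-statistics bundle
#'
#' Variants are laid out in `n_blocks` equal blocks with exchangeable
#' within-block LD (every intra-block pair has squared correlation
#' `block_r2`). Each variant is independently labelled `null`,
#' `trait1`-specific, `trait2`-specific or `shared` with probabilities
#' `(1 - pi1 - pi2 - pi12, pi1, pi2, pi12)`. Causal effects are normal with
#' the trait's effect variance; shared variants draw a bivariate-normal
#' effect pair with correlation `rho_shared`. Marginal z-scores follow the
#' standard summary-statistic model per block,
#' \deqn{z = \sqrt{N}\, R\beta + \epsilon,\quad \epsilon \sim N(0, R),}
#' with `R` the block's exchangeable correlation matrix, optionally scaled
#' by `sqrt(lambda_inject)` to emulate genome-wide inflation. Two-sided
#' normal-tail p-values are emitted; the `beta` column is `z / sqrt(N)` and
#' `se = 1 / sqrt(N)`.
#'
#' Defaults emulate the scale of the motivating application: a small
#' neurodegenerative-disease GWAS (trait 1, N ~ 4.8k) conditioned on a
#' large immune-disease GWAS (trait 2, N ~ 60k), with modest trait-1
#' polygenicity, a sizeable shared component, and strong trait-2 hits.
#'
#' @param n_snps Number of variants (default 10,000).
#' @param n_blocks Number of LD blocks (default 2,000; 5 variants/block).
#' @param block_r2 Within-block squared correlation in `[0, 1)`
#'   (default 0.8).
#' @param pi1,pi2,pi12 Trait-1-specific, trait-2-specific and shared causal
#'   fractions (defaults 0.002, 0.005, 0.01); must sum to at most 1.
#' @param sigma_beta1_sq,sigma_beta2_sq Causal effect variances per trait
#'   (defaults 1.7e-3 and 4e-4, giving per-variant non-centralities of
#'   about 8 and 24 at the default sample sizes).
#' @param rho_shared Correlation of shared effect pairs (default 0.8).
#' @param n1,n2 GWAS sample sizes (defaults 4782 and 59957).
#' @param lambda_inject Inflation factor applied to z^2 (default 1, none).
#' @param seed Integer seed; same seed gives byte-identical output.
#' @return A `synthetic_bundle` list: `sumstats1`, `sumstats2` (valid
#'   summary-statistics tibbles), `ld` (`ld_ref` of within-block pairs at
#'   the theoretical `block_r2`), `labels` (tibble `snp_id`, `label`),
#'   `genes` (gene models tiling the layout), and `config`.
#' @export
simulate_pair <- function(n_snps = 10000L, n_blocks = 2000L, block_r2 = 0.8,
                          pi1 = 0.002, pi2 = 0.005, pi12 = 0.01,
                          sigma_beta1_sq = 1.7e-3, sigma_beta2_sq = 4e-4,
                          rho_shared = 0.8, n1 = 4782, n2 = 59957,
                          lambda_inject = 1, seed = 1L) {
  if (pi1 + pi2 + pi12 > 1 || min(pi1, pi2, pi12) < 0) {
    abort("Causal fractions must be non-negative and sum to at most 1.",
          class = "conjfdr_config_error")
  }
  if (block_r2 < 0 || block_r2 >= 1 || sigma_beta1_sq < 0 ||
      sigma_beta2_sq < 0 || abs(rho_shared) > 1 || lambda_inject < 1) {
    abort("Invalid simulation configuration.", class = "conjfdr_config_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  block <- rep(seq_len(n_blocks), length.out = n_snps)
  block <- sort(block)
  layout <- snp_layout(n_snps, block)

  labels <- sample(c("null", "trait1", "trait2", "shared"), n_snps,
                   replace = TRUE,
                   prob = c(1 - pi1 - pi2 - pi12, pi1, pi2, pi12))
  beta1 <- numeric(n_snps)
  beta2 <- numeric(n_snps)
  is1 <- labels %in% c("trait1", "shared")
  is2 <- labels %in% c("trait2", "shared")
  beta1[is1] <- rnorm(sum(is1), 0, sqrt(sigma_beta1_sq))
  sh <- labels == "shared"
  # shared effects: beta2 | beta1 bivariate normal with correlation rho
  beta2[labels == "trait2"] <- rnorm(sum(labels == "trait2"), 0, sqrt(sigma_beta2_sq))
  beta2[sh] <- rho_shared * sqrt(sigma_beta2_sq / sigma_beta1_sq) * beta1[sh] +
    sqrt(1 - rho_shared^2) * rnorm(sum(sh), 0, sqrt(sigma_beta2_sq))

  r <- sqrt(block_r2)
  z1 <- blockwise_z(beta1, block, r, n1)
  z2 <- blockwise_z(beta2, block, r, n2)
  if (lambda_inject > 1) {
    z1 <- z1 * sqrt(lambda_inject)
    z2 <- z2 * sqrt(lambda_inject)
  }

  sumstats <- function(z, n) {
    tibble::tibble(
      snp_id = layout$snp_id,
      chrom = layout$chrom,
      pos = layout$pos,
      allele_effect = layout$a1,
      allele_other = layout$a2,
      beta = z / sqrt(n),
      se = 1 / sqrt(n),
      z = z,
      pvalue = pmax(2 * pnorm(-abs(z)), .p_floor)
    )
  }

  ld <- block_ld_pairs(layout$snp_id, block, block_r2)

  structure(
    list(
      sumstats1 = sumstats(z1, n1),
      sumstats2 = sumstats(z2, n2),
      ld = ld,
      labels = tibble::tibble(snp_id = layout$snp_id, label = labels),
      genes = tile_genes(layout),
      config = list(
        n_snps = n_snps, n_blocks = n_blocks, block_r2 = block_r2,
        pi1 = pi1, pi2 = pi2, pi12 = pi12,
        sigma_beta1_sq = sigma_beta1_sq, sigma_beta2_sq = sigma_beta2_sq,
        rho_shared = rho_shared, n1 = n1, n2 = n2,
        lambda_inject = lambda_inject, seed = seed
      )
    ),
    class = "synthetic_bundle"
  )
}

# Genomic layout: blocks tiled across autosomes 1..22, 5 kb SNP spacing,
# 100 kb gaps between blocks; non-ambiguous allele pairs so harmonization
# retains every variant.
snp_layout <- function(n_snps, block) {
  n_blocks <- max(block)
  block_chrom <- rep(as.character(1:22), length.out = n_blocks)
  within <- stats::ave(seq_len(n_snps), block, FUN = seq_along)
  block_on_chrom <- stats::ave(seq_len(n_blocks),
                               block_chrom[seq_len(n_blocks)], FUN = seq_along)
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4, n_snps, replace = TRUE)
  tibble::tibble(
    snp_id = sprintf("snp%06d", seq_len(n_snps)),
    chrom = block_chrom[block],
    pos = as.integer(block_on_chrom[block] * 100000L + within * 5000L),
    a1 = pairs[pick, 1],
    a2 = pairs[pick, 2],
    block = block
  )
}

# z = sqrt(N) R beta + eps with exchangeable R = (1-r) I + r J per block;
# eps sampled as sqrt(1-r) xi + sqrt(r) eta with eta shared per block.
blockwise_z <- function(beta, block, r, n) {
  s <- stats::ave(beta, block, FUN = sum)
  mean_part <- sqrt(n) * ((1 - r) * beta + r * s)
  eta <- rnorm(max(block))
  xi <- rnorm(length(beta))
  mean_part + sqrt(1 - r) * xi + sqrt(r) * eta[block]
}

block_ld_pairs <- function(snp_id, block, block_r2, r2_floor = 0.05) {
  if (block_r2 < r2_floor) {
    return(new_ld_ref(tibble::tibble(snp_i = character(),
                                     snp_j = character(), r2 = numeric())))
  }
  per_block <- split(snp_id, block)
  pairs <- purrr::map(per_block, function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    tibble::tibble(snp_i = cmb[1, ], snp_j = cmb[2, ], r2 = block_r2)
  })
  new_ld_ref(dplyr::bind_rows(pairs))
}

# One gene per other LD block, 40 kb wide, alternating strand.
tile_genes <- function(layout) {
  blocks <- layout |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$pos),
                     end = max(.data$pos), .groups = "drop")
  g <- blocks[seq(1, nrow(blocks), by = 2), ]
  tibble::tibble(
    symbol = sprintf("GENE%04d", seq_len(nrow(g))),
    chrom = g$chrom,
    start = pmax(1L, as.integer(g$start - 10000L)),
    end = as.integer(g$end + 10000L),
    strand = rep(c("+", "-"), length.out = nrow(g))
  )
}

#' Simulate a correlated genotype panel for the bundle layout
#'
#' Haplotypes within an LD block share alleles through a copy mechanism
#' calibrated so the expected pairwise dosage r-squared equals `block_r2`:
#' each haplotype copies the block's seed haplotype with probability
#' `block_r2^(1/4)` and otherwise draws independently at the same allele
#' frequency.
#'
#' @param layout_map Tibble `snp_id`, `chrom`, `pos`, `block` (e.g.
#'   `snp_layout()` columns of a bundle, or any map with a `block` column).
#' @param block_r2 Target within-block dosage r-squared.
#' @param n_samples Number of diploid samples.
#' @param maf_range Allele-frequency range, uniform per block
#'   (default `c(0.1, 0.5)`).
#' @param seed Integer seed.
#' @return A `genotype_panel`.
#' @export
simulate_genotype_panel <- function(layout_map, block_r2, n_samples,
                                    maf_range = c(0.1, 0.5), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  a <- block_r2^(1 / 4)
  blocks <- split(seq_len(nrow(layout_map)), layout_map$block)
  dosage <- matrix(0, n_samples, nrow(layout_map))
  colnames(dosage) <- layout_map$snp_id
  for (idx in blocks) {
    f <- runif(1, maf_range[1], maf_range[2])
    for (hap in 1:2) {
      seed_hap <- rbinom(n_samples, 1, f)
      for (j in idx) {
        copy <- runif(n_samples) < a
        allele <- ifelse(copy, seed_hap, rbinom(n_samples, 1, f))
        dosage[, j] <- dosage[, j] + allele
      }
    }
  }
  genotype_panel(dosage, layout_map[, c("snp_id", "chrom", "pos")])
}

#' Simulate a SKAT case-control fixture
#'
#' Genotypes are binomial(2, MAF) with per-variant MAF uniform on
#' `[0.005, 0.3]`; the binary phenotype follows a logistic model with
#' log-odds `effect_size` per allele on a random causal subset of the
#' variants (centred so prevalence is near one half). `effect_size = 0`
#' gives the global null.
#'
#' @param n_samples Number of samples (at least 20).
#' @param n_variants Number of variants.
#' @param effect_size Per-allele log-odds ratio on causal variants.
#' @param seed Integer seed.
#' @param n_causal Number of causal variants (default 60% of variants,
#'   at least 1; ignored when `effect_size = 0`).
#' @return List with `G` (genotype matrix), `y` (phenotype), `maf`,
#'   `causal` (causal variant indices).
#' @export
simulate_skat_fixture <- function(n_samples, n_variants, effect_size = 0,
                                  seed = 1L,
                                  n_causal = max(1L, round(0.6 * n_variants))) {
  stopifnot(n_samples >= 20)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  maf <- runif(n_variants, 0.005, 0.3)
  G <- vapply(maf, function(f) rbinom(n_samples, 2, f), numeric(n_samples))
  colnames(G) <- sprintf("var%03d", seq_len(n_variants))
  causal <- sort(sample.int(n_variants, min(n_causal, n_variants)))
  lp <- if (effect_size == 0) {
    rep(0, n_samples)
  } else {
    eta <- G[, causal, drop = FALSE] %*% rep(effect_size, length(causal))
    drop(eta) - mean(eta)
  }
  y <- rbinom(n_samples, 1, stats::plogis(lp))
  # guarantee both classes (tiny samples can draw one class by chance)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(G = G, y = y, maf = maf, causal = causal)
}

#' The 10-variant worked example fixture
#'
#' A tiny harmonized pair with unit weights and hand-set p-value pairs,
#' built so the conditional-FDR arithmetic can be audited by direct
#' counting. In the stratum `p2 <= 0.1` (the first five variants), the
#' primary p-values are {0.001, 0.02, 0.3, 0.5, 0.9}, so
#' `F-hat(0.02) = 2/5` and `cFDR(0.02 | p2 <= 0.1) = 0.02 / 0.4 = 0.05`.
#' The sidecar `expected` table freezes the hand-computed condFDR values
#' for every variant at its own (p1, p2).
#'
#' @return List with `sumstats1`, `sumstats2` (valid summary-statistics
#'   tibbles over the same 10 variants), `pair` (their harmonization),
#'   `weights` (unit `pruning_weights`), and `expected` (tibble `snp_id`,
#'   `cfdr_1given2`, `cfdr_2given1`, `conjfdr` by direct counting).
#' @export
make_worked_fixture <- function() {
  p1 <- c(0.001, 0.02, 0.3, 0.5, 0.9, 0.35, 0.45, 0.55, 0.65, 0.75)
  p2 <- c(0.001, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.45, 0.7, 0.9)
  base <- tibble::tibble(
    snp_id = sprintf("wf%02d", 1:10),
    chrom = "1",
    pos = as.integer(seq(1e6, by = 1e5, length.out = 10)),
    allele_effect = "A",
    allele_other = "G"
  )
  s1 <- dplyr::mutate(base,
                      z = qchisq(p1, 1, lower.tail = FALSE)^0.5,
                      beta = .data$z, se = 1, pvalue = p1)
  s2 <- dplyr::mutate(base,
                      z = qchisq(p2, 1, lower.tail = FALSE)^0.5,
                      beta = .data$z, se = 1, pvalue = p2)
  pair <- harmonize_pair(s1, s2)
  weights <- tibble::tibble(snp_id = base$snp_id, weight = 1)
  attr(weights, "n_iterations") <- 1L
  attr(weights, "r2_threshold") <- 0.1
  attr(weights, "seed") <- 0L
  class(weights) <- c("pruning_weights", class(weights))
  expected <- worked_fixture_expected(p1, p2, base$snp_id)
  list(sumstats1 = s1, sumstats2 = s2, pair = pair, weights = weights,
       expected = expected)
}

# Direct-counting condFDR for each fixture variant at its own (p1, p2):
# cfdr_1given2(i) = p1_i / F-hat(p1_i | p2 <= p2_i), unit weights.
worked_fixture_expected <- function(p1, p2, snp_id) {
  direct <- function(pp, pc) {
    vapply(seq_along(pp), function(i) {
      sel <- pc <= pc[i]
      min(1, pp[i] / (sum(pp[sel] <= pp[i]) / sum(sel)))
    }, numeric(1))
  }
  c12 <- direct(p1, p2)
  c21 <- direct(p2, p1)
  tibble::tibble(
    snp_id = snp_id,
    cfdr_1given2 = c12,
    cfdr_2given1 = c21,
    conjfdr = pmax(c12, c21)
  )
}

#' Write a synthetic bundle to a directory
#'
#' Emits the two summary-statistics tables and the LD pair list as TSV, the
#' truth labels as TSV, gene models as BED6, and (when the `yaml` package
#' is available) the configuration echo as YAML.
#'
#' @param bundle A `synthetic_bundle` from [simulate_pair()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sumstats_cols <- function(s) {
    dplyr::select(s, SNP = "snp_id", CHR = "chrom", BP = "pos",
                  A1 = "allele_effect", A2 = "allele_other",
                  BETA = "beta", SE = "se", Z = "z", P = "pvalue")
  }
  paths <- c(
    sumstats1 = file.path(dir, "trait1_sumstats.tsv"),
    sumstats2 = file.path(dir, "trait2_sumstats.tsv"),
    ld = file.path(dir, "ld_pairs.tsv"),
    labels = file.path(dir, "truth_labels.tsv"),
    genes = file.path(dir, "genes.bed")
  )
  readr::write_tsv(sumstats_cols(bundle$sumstats1), paths[["sumstats1"]])
  readr::write_tsv(sumstats_cols(bundle$sumstats2), paths[["sumstats2"]])
  readr::write_tsv(bundle$ld, paths[["ld"]])
  readr::write_tsv(bundle$labels, paths[["labels"]])
  bed <- tibble::tibble(
    chrom = bundle$genes$chrom,
    start = bundle$genes$start - 1L,
    end = bundle$genes$end,
    name = bundle$genes$symbol,
    score = 0L,
    strand = bundle$genes$strand
  )
  utils::write.table(bed, paths[["genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- file.path(dir, "config.yaml")
    yaml::write_yaml(bundle$config, cfg)
    paths <- c(paths, config = cfg)
  }
  invisible(paths)
}
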