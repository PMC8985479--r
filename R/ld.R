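# Pairwise LD (r2) estimation, random pruning, and per-SNP pruning weights.

new_ld_ref <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("snp_i", "snp_j", "r2") %in% names(pairs)))
  stopifnot(all(pairs$r2 >= 0 & pairs$r2 <= 1))
  class(pairs) <- c("ld_ref", class(pairs))
  pairs
}

#' Read a precomputed pairwise-LD list
#'
#' Three-column whitespace/tab text: snp_i, snp_j, r2. A header row is
#' detected automatically. Each unordered pair needs to appear once;
#' symmetry is implied.
#'
#' @param path Path to the pair list.
#' @return An `ld_ref` tibble (`snp_i`, `snp_j`, `r2`).
#' @export
read_ld_pairs <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", strsplit(trimws(first), "\\s+")[[1]][3])
  tbl <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  names(tbl)[1:3] <- c("snp_i", "snp_j", "r2")
  new_ld_ref(tibble::tibble(
    snp_i = as.character(tbl$snp_i),
    snp_j = as.character(tbl$snp_j),
    r2 = as.numeric(tbl$r2)
  ))
}

#' Pairwise r-squared from a genotype panel
#'
#' Squared Pearson correlation of additive dosages (0/1/2, missing allowed),
#' pairwise-complete, restricted to intra-chromosome pairs within
#' `window_bp` of each other. Pairs involving a monomorphic variant, or with
#' fewer than `min_obs` complete observations, are omitted (and counted in a
#' message). Pairs below `r2_floor` are not stored; the floor must not
#' exceed any downstream pruning/clumping threshold.
#'
#' @param panel A genotype panel: list with `dosage` (samples x variants
#'   matrix, column names = variant ids) and `map` (tibble `snp_id`,
#'   `chrom`, `pos`), as returned by [read_raw_genotypes()],
#'   [read_vcf_genotypes()] or [simulate_genotype_panel()].
#' @param window_bp Maximum pair distance in base pairs (default 20 Mb).
#' @param r2_floor Storage floor (default 0.05).
#' @param min_obs Minimum complete observations per pair (default 3).
#' @return An `ld_ref` tibble.
#' @export
compute_r2 <- function(panel, window_bp = 2e7, r2_floor = 0.05, min_obs = 3) {
  stopifnot(is.matrix(panel$dosage), nrow(panel$dosage) >= 2)
  map <- panel$map
  stopifnot(identical(colnames(panel$dosage), map$snp_id))
  dropped <- 0L
  res <- purrr::map(unique(map$chrom), function(cc) {
    idx <- which(map$chrom == cc)
    if (length(idx) < 2) return(NULL)
    g <- panel$dosage[, idx, drop = FALSE]
    pos <- map$pos[idx]
    cm <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))
    nobs <- crossprod(!is.na(g))
    r2 <- cm^2
    ut <- upper.tri(r2)
    keepable <- ut & is.finite(r2) & nobs >= min_obs
    dropped <<- dropped + sum(ut & !(is.finite(r2) & nobs >= min_obs))
    close_enough <- ut & abs(outer(pos, pos, "-")) <= window_bp
    sel <- which(keepable & close_enough & r2 >= r2_floor, arr.ind = TRUE)
    if (nrow(sel) == 0) return(NULL)
    tibble::tibble(
      snp_i = map$snp_id[idx[sel[, 1]]],
      snp_j = map$snp_id[idx[sel[, 2]]],
      r2 = r2[sel]
    )
  })
  if (dropped > 0) {
    inform(sprintf("compute_r2: %d pair(s) omitted (monomorphic or < %d complete observations).",
                   dropped, min_obs))
  }
  new_ld_ref(dplyr::bind_rows(res))
}

# Adjacency list over `snps` for pairs with r2 > threshold; integer indices.
ld_adjacency <- function(ld, snps, r2_threshold) {
  n <- length(snps)
  adj <- vector("list", n)
  keep <- ld$r2 > r2_threshold & ld$snp_i %in% snps & ld$snp_j %in% snps
  if (any(keep)) {
    i <- match(ld$snp_i[keep], snps)
    j <- match(ld$snp_j[keep], snps)
    self <- i == j
    i <- i[!self]; j <- j[!self]
    adj_from <- split(c(j, i), c(i, j))
    for (k in names(adj_from)) adj[[as.integer(k)]] <- unique(adj_from[[k]])
  }
  adj
}

greedy_prune_order <- function(adj, ord) {
  n <- length(adj)
  blocked <- logical(n)
  retained <- logical(n)
  for (i in ord) {
    if (!blocked[i]) {
      retained[i] <- TRUE
      nb <- adj[[i]]
      if (length(nb)) blocked[nb] <- TRUE
    }
  }
  retained
}

#' One round of random LD pruning
#'
#' Greedy maximal independent set: variants are visited in a seeded random
#' order; a variant is retained iff no already-retained variant is in LD
#' with it above `r2_threshold`. Every non-retained variant is therefore
#' linked (r2 > threshold) to at least one retained variant — the
#' "one random SNP per LD clump" rule of PLINK-style pruning.
#'
#' @param ld An `ld_ref` pair list.
#' @param snps Character vector of variant ids to prune.
#' @param r2_threshold LD threshold in (0, 1); default 0.1.
#' @param rng_seed Integer seed for the visit order.
#' @return Character vector of retained variant ids.
#' @export
random_prune <- function(ld, snps, r2_threshold = 0.1, rng_seed = 1L) {
  stopifnot(r2_threshold > 0, r2_threshold < 1)
  adj <- ld_adjacency(ld, snps, r2_threshold)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  ord <- sample.int(length(snps))
  snps[greedy_prune_order(adj, ord)]
}

#' Per-SNP random-pruning weights
#'
#' Runs `n_iterations` rounds of [random_prune()] with per-iteration seeds
#' derived from `(rng_seed, iteration)` and returns, for each variant, the
#' fraction of iterations in which it was retained. These weights
#' de-correlate contributions to empirical distributions: a variant with no
#' LD neighbour has weight exactly 1, while a fully linked clump of k
#' variants shares total weight ~1 (expected weight 1/k each).
#'
#' @inheritParams random_prune
#' @param n_iterations Number of pruning rounds (default 100).
#' @return A `pruning_weights` tibble (`snp_id`, `weight`) with attributes
#'   `n_iterations`, `r2_threshold`, `seed`.
#' @export
pruning_weights <- function(ld, snps, n_iterations = 100L, r2_threshold = 0.1,
                            rng_seed = 1L) {
  stopifnot(n_iterations >= 1, r2_threshold > 0, r2_threshold < 1)
  adj <- ld_adjacency(ld, snps, r2_threshold)
  n <- length(snps)
  counts <- integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (it in seq_len(n_iterations)) {
    set.seed(iter_seed(rng_seed, it))
    ord <- sample.int(n)
    counts <- counts + greedy_prune_order(adj, ord)
  }
  out <- tibble::tibble(snp_id = snps, weight = counts / n_iterations)
  attr(out, "n_iterations") <- as.integer(n_iterations)
  attr(out, "r2_threshold") <- r2_threshold
  attr(out, "seed") <- as.integer(rng_seed)
  class(out) <- c("pruning_weights", class(out))
  out
}

#' Write pruning weights as TSV with a provenance header
#'
#' @param weights A `pruning_weights` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pruning_weights <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#n_iterations=%d", attr(weights, "n_iterations")),
    sprintf("#r2_threshold=%g", attr(weights, "r2_threshold")),
    sprintf("#seed=%d", attr(weights, "seed")),
    "snp_id\tweight"
  ), con)
  utils::write.table(weights[, c("snp_id", "weight")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Align weights to a SNP id vector; missing ids get weight 1 with a message.
align_weights <- function(weights, snp_ids) {
  if (is.null(weights)) return(rep(1, length(snp_ids)))
  w <- weights$weight[match(snp_ids, weights$snp_id)]
  if (anyNA(w)) {
    inform(sprintf("%d variant(s) missing from pruning weights; assigned weight 1.",
                   sum(is.na(w))))
    w[is.na(w)] <- 1
  }
  w
}
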