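# Conditional/conjunctional FDR estimation on a weighted empirical grid.

default_p1_grid <- function() 10^seq(-12, 0, length.out = 200)
default_p2_cuts <- function() 10^seq(-8, 0, length.out = 40)

#' Build a conditional-FDR lookup grid
#'
#' For each conditioning cut `c` in `p2_cuts` and each node of `p1_grid`,
#' estimates
#' \deqn{cFDR(p_1 \mid p_2 \le c) = \min(1,\; p_1 / \hat F(p_1 \mid p_2 \le c))}
#' where \eqn{\hat F} is the weighted empirical cdf of the primary trait's
#' p-values restricted to variants with conditional p-value at most `c`
#' (the null proportion is conservatively fixed at 1). Below the stratum's
#' smallest observed p-value, \eqn{\hat F} is floored at its first step so
#' the estimate keeps decaying with `p1` instead of jumping to 1.
#'
#' Two monotonicity passes are then enforced: a running maximum along
#' increasing `p1` within each column (cFDR cannot decrease as significance
#' weakens), followed by a running minimum from lenient toward stricter
#' conditioning (stronger conditioning cannot hurt).
#'
#' Empty conditioning strata inherit the nearest populated (more lenient)
#' column, with a message.
#'
#' @param pair Harmonized pair tibble (`p1`, `p2`, `snp_id`).
#' @param weights `pruning_weights` or `NULL` (unit weights).
#' @param p1_grid Primary p-value nodes (default 200 log-spaced in
#'   `[1e-12, 1]`).
#' @param p2_cuts Conditioning cutpoints (default 40 log-spaced in
#'   `[1e-8, 1]`).
#' @param orientation `"1given2"` (condition trait 1 on trait 2) or
#'   `"2given1"`.
#' @return A `condfdr_grid` object: list with `p1`, `cuts`, `values`
#'   (matrix nodes x cuts, values in (0, 1]), `orientation`.
#' @export
build_condfdr_grid <- function(pair, weights = NULL,
                               p1_grid = default_p1_grid(),
                               p2_cuts = default_p2_cuts(),
                               orientation = c("1given2", "2given1")) {
  orientation <- match.arg(orientation)
  if (nrow(pair) < 1000) {
    warn("build_condfdr_grid: fewer than 1,000 variants; cFDR estimates will be coarse.")
  }
  pp <- if (orientation == "1given2") pair$p1 else pair$p2
  pc <- if (orientation == "1given2") pair$p2 else pair$p1
  w <- align_weights(weights, pair$snp_id)

  p1_grid <- sort(unique(p1_grid))
  p2_cuts <- sort(unique(p2_cuts))
  stopifnot(all(p1_grid > 0 & p1_grid <= 1), all(p2_cuts > 0 & p2_cuts <= 1))

  ord <- order(pp)
  pp_s <- pp[ord]
  w_s <- w[ord]
  pc_s <- pc[ord]

  n_nodes <- length(p1_grid)
  n_cuts <- length(p2_cuts)
  vals <- matrix(NA_real_, n_nodes, n_cuts)
  empty <- logical(n_cuts)

  for (j in seq_len(n_cuts)) {
    sel <- pc_s <= p2_cuts[j]
    wj <- w_s[sel]
    tot <- sum(wj)
    if (!(tot > 0)) {
      empty[j] <- TRUE
      next
    }
    cw <- cumsum(wj) / tot
    idx <- findInterval(p1_grid, pp_s[sel])
    Fhat <- ifelse(idx > 0, cw[pmax(idx, 1)], 0)
    # floor below the first observed value at the first step height
    Fhat <- pmax(Fhat, cw[1])
    vals[, j] <- pmin(1, p1_grid / Fhat)
  }

  if (any(empty)) {
    inform(sprintf("build_condfdr_grid: %d empty conditioning stratum(-a) filled from nearest populated cut.",
                   sum(empty)))
    populated <- which(!empty)
    if (length(populated) == 0) {
      abort("All conditioning strata are empty.", class = "conjfdr_input_error")
    }
    for (j in which(empty)) {
      nearest <- populated[which.min(abs(populated - j))]
      vals[, j] <- vals[, nearest]
    }
  }

  raw <- vals
  # monotone along p1 (running max toward p1 -> 1)
  vals <- apply(vals, 2, cummax)
  # monotone along cuts (running min toward stricter conditioning)
  if (n_cuts > 1) {
    for (j in seq(n_cuts - 1, 1)) {
      vals[, j] <- pmin(vals[, j], vals[, j + 1])
    }
  }

  structure(
    list(p1 = p1_grid, cuts = p2_cuts, values = vals, values_raw = raw,
         orientation = orientation),
    class = "condfdr_grid"
  )
}

#' Evaluate a condFDR grid at arbitrary (p1, p2)
#'
#' Bilinear interpolation in (log10 p1, log10 p2) space, log-linear in the
#' cFDR value; queries outside the grid clamp to the boundary. The
#' conditioning coordinate `p2` is interpreted as the cut `c = p2`.
#'
#' @param grid A `condfdr_grid`.
#' @param p1,p2 Numeric vectors (recycled to a common length).
#' @return cFDR values in (0, 1].
#' @export
lookup_condfdr <- function(grid, p1, p2) {
  n <- max(length(p1), length(p2))
  p1 <- rep_len(pmax(p1, .p_floor), n)
  p2 <- rep_len(pmax(p2, .p_floor), n)

  lx <- log10(pmin(pmax(p1, min(grid$p1)), max(grid$p1)))
  ly <- log10(pmin(pmax(p2, min(grid$cuts)), max(grid$cuts)))
  gx <- log10(grid$p1)
  gy <- log10(grid$cuts)
  lv <- log10(grid$values)

  ix <- pmin(pmax(findInterval(lx, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(ly, gy), 1L), length(gy) - 1L)
  tx <- (lx - gx[ix]) / (gx[ix + 1L] - gx[ix])
  ty <- (ly - gy[iy]) / (gy[iy + 1L] - gy[iy])
  tx <- pmin(pmax(tx, 0), 1)
  ty <- pmin(pmax(ty, 0), 1)

  v00 <- lv[cbind(ix, iy)]
  v10 <- lv[cbind(ix + 1L, iy)]
  v01 <- lv[cbind(ix, iy + 1L)]
  v11 <- lv[cbind(ix + 1L, iy + 1L)]
  out <- 10^((1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
               (1 - tx) * ty * v01 + tx * ty * v11)
  pmin(pmax(out, .p_floor), 1)
}

#' Direct (oracle-style) conditional FDR at a single query
#'
#' Computes `min(1, p1 / F-hat(p1 | p2 <= cut))` by direct weighted counting,
#' without grid or monotone enforcement. Mainly useful for verification on
#' small tables.
#'
#' @param pair Harmonized pair tibble.
#' @param p1,cut Query primary p-value and conditioning cut.
#' @param weights Optional `pruning_weights`.
#' @return A single cFDR value, or `NA` if the stratum is empty.
#' @export
condfdr_at <- function(pair, p1, cut, weights = NULL) {
  w <- align_weights(weights, pair$snp_id)
  sel <- pair$p2 <= cut
  if (!any(sel)) return(NA_real_)
  f <- weighted_ecdf(pair$p1[sel], w[sel])
  Fhat <- f(p1)
  if (Fhat <= 0) Fhat <- min(w[sel][pair$p1[sel] == min(pair$p1[sel])]) / sum(w[sel])
  min(1, p1 / Fhat)
}

#' Per-variant conjunctional FDR
#'
#' Builds both grid orientations (trait 1 conditioned on trait 2 and vice
#' versa), evaluates each variant's two condFDRs at its own (p1, p2), and
#' sets the conjunctional FDR to their maximum — an upper bound on the FDR
#' for association with both traits simultaneously.
#'
#' @inheritParams build_condfdr_grid
#' @return A `conjfdr_tbl` tibble: `snp_id`, `chrom`, `pos`, `p1`, `p2`,
#'   `cfdr_1given2`, `cfdr_2given1`, `conjfdr`; the two grids are attached
#'   as attributes `grid_1given2` and `grid_2given1`.
#' @export
compute_conjfdr <- function(pair, weights = NULL,
                            p1_grid = default_p1_grid(),
                            p2_cuts = default_p2_cuts()) {
  g12 <- build_condfdr_grid(pair, weights, p1_grid, p2_cuts, "1given2")
  g21 <- build_condfdr_grid(pair, weights, p1_grid, p2_cuts, "2given1")
  cfdr12 <- lookup_condfdr(g12, pair$p1, pair$p2)
  cfdr21 <- lookup_condfdr(g21, pair$p2, pair$p1)
  out <- tibble::tibble(
    snp_id = pair$snp_id,
    chrom = pair$chrom,
    pos = pair$pos,
    p1 = pair$p1,
    p2 = pair$p2,
    cfdr_1given2 = cfdr12,
    cfdr_2given1 = cfdr21,
    conjfdr = pmax(cfdr12, cfdr21)
  )
  attr(out, "grid_1given2") <- g12
  attr(out, "grid_2given1") <- g21
  class(out) <- c("conjfdr_tbl", class(out))
  out
}

#' Write a conjFDR table as TSV
#'
#' @param tbl A `conjfdr_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conjfdr <- function(tbl, path) {
  readr::write_tsv(
    dplyr::select(tbl, "snp_id", "chrom", "pos", "p1", "p2",
                  cfdr12 = "cfdr_1given2", cfdr21 = "cfdr_2given1", "conjfdr"),
    path
  )
  invisible(path)
}
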