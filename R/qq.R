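# Conditional Q-Q curves and enrichment summaries.

#' Conditional Q-Q curves
#'
#' For each conditioning stratum (variants whose conditional-trait p-value
#' `p2` falls below a threshold; the threshold-1 stratum contains all
#' variants), pairs expected quantiles of the standard uniform with observed
#' weighted quantiles of the primary-trait p-values, both on the -log10
#' scale. Polygenic overlap shows as successive leftward/upward deflection
#' of the curves as the conditioning threshold tightens.
#'
#' @param pair Harmonized pair tibble.
#' @param weights `pruning_weights` or `NULL` (unit weights).
#' @param thresholds Descending conditioning thresholds, first = 1
#'   (default `c(1, 0.1, 0.01, 0.001)`).
#' @param expected_max Largest expected -log10 p on the curve (default 6).
#' @param n_points Number of curve points (default 240).
#' @param min_stratum_weight Strata whose total weight falls below this
#'   floor are omitted with a warning (default 50).
#' @return A `qq_curves` tibble: `stratum_threshold`, `expected`,
#'   `observed`, `effective_n`.
#' @export
conditional_qq <- function(pair, weights = NULL,
                           thresholds = c(1, 0.1, 0.01, 0.001),
                           expected_max = 6, n_points = 240,
                           min_stratum_weight = 50) {
  stopifnot(nrow(pair) > 0)
  if (is.unsorted(rev(thresholds)) || thresholds[1] != 1) {
    abort("thresholds must be descending with first element 1.",
          class = "conjfdr_config_error")
  }
  w <- align_weights(weights, pair$snp_id)
  expected <- seq(0, expected_max, length.out = n_points)
  q <- 10^(-expected)

  curves <- purrr::map(thresholds, function(thr) {
    sel <- if (thr >= 1) rep(TRUE, nrow(pair)) else pair$p2 < thr
    tot <- sum(w[sel])
    if (tot < min_stratum_weight) {
      warn(sprintf("conditional_qq: stratum p2 < %g has total weight %.1f < %g; omitted.",
                   thr, tot, min_stratum_weight))
      return(NULL)
    }
    obs_p <- weighted_quantile(pmax(pair$p1[sel], .p_floor), w[sel], q)
    tibble::tibble(
      stratum_threshold = thr,
      expected = expected,
      observed = -log10(obs_p),
      effective_n = tot
    )
  })
  out <- dplyr::bind_rows(curves)
  class(out) <- c("qq_curves", class(out))
  out
}

#' Q-Q deflection statistic per stratum
#'
#' One-number enrichment summary per conditioning stratum: the mean of
#' (observed - expected) -log10 p over the expected range `[from, to]`.
#' Averaging over the well-supported part of the curve, rather than reading
#' a single extreme-tail point, keeps the statistic informative for small
#' strata, whose curves saturate at the stratum's minimum p-value in the
#' far tail.
#'
#' @param curves A `qq_curves` tibble.
#' @param from,to Expected -log10 p range to average over (defaults 0-2).
#' @return Tibble `stratum_threshold`, `effective_n`, `deflection`, in
#'   decreasing threshold order (all-SNP stratum first).
#' @export
qq_deflection <- function(curves, from = 0, to = 2) {
  curves |>
    dplyr::filter(.data$expected >= from, .data$expected <= to) |>
    dplyr::group_by(.data$stratum_threshold) |>
    dplyr::summarise(
      effective_n = .data$effective_n[1],
      deflection = mean(.data$observed - .data$expected),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$stratum_threshold))
}

#' Monte-Carlo null band for the deflection statistic
#'
#' Simulates `n_sims` sets of `n_eff` independent uniform p-values, computes
#' the deflection statistic ([qq_deflection()]) of each unconditioned Q-Q
#' curve over `[from, to]`, and returns the central `level` quantile band.
#' The effective (weight-summed) stratum size stands in for an independent
#' sample size.
#'
#' @param n_eff Effective number of independent variants in the stratum.
#' @param from,to Expected -log10 p averaging range (as in
#'   [qq_deflection()]).
#' @param level Coverage (default 0.95).
#' @param n_sims Number of null simulations (default 200).
#' @param seed Integer seed.
#' @return Named numeric `c(lower, upper)`.
#' @export
qq_deflection_null_band <- function(n_eff, from = 0, to = 2, level = 0.95,
                                    n_sims = 200, seed = 1L) {
  n <- max(2L, round(n_eff))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expected <- seq(from, to, length.out = 50)
  q <- 10^(-expected)
  defl <- vapply(seq_len(n_sims), function(i) {
    p <- sort(runif(n))
    k <- pmax(1L, ceiling(q * n))
    mean(-log10(p[k]) - expected)
  }, numeric(1))
  alpha <- (1 - level) / 2
  stats::setNames(quantile(defl, c(alpha, 1 - alpha), names = FALSE),
                  c("lower", "upper"))
}

#' Pointwise null band for a Q-Q curve
#'
#' Under the global null, the observed p-value at cumulative fraction
#' `q = 10^-expected` of `n_eff` independent uniform draws is approximately
#' the k-th order statistic, Beta(k, n_eff - k + 1) with
#' `k = max(1, ceiling(q * n_eff))`. Returns the central `level` band on
#' the -log10 scale; effective (weighted) counts stand in for independent
#' counts.
#'
#' @param n_eff Effective number of independent variants.
#' @param expected Vector of expected -log10 p positions.
#' @param level Coverage (default 0.95).
#' @return Tibble `expected`, `lower`, `upper` (-log10 observed bounds).
#' @export
qq_null_band <- function(n_eff, expected, level = 0.95) {
  q <- 10^(-expected)
  k <- pmax(1, ceiling(q * n_eff))
  alpha <- (1 - level) / 2
  tibble::tibble(
    expected = expected,
    lower = -log10(qbeta(1 - alpha, k, pmax(n_eff - k + 1, 1))),
    upper = -log10(qbeta(alpha, k, pmax(n_eff - k + 1, 1)))
  )
}

#' Write Q-Q curves as TSV
#'
#' @param curves A `qq_curves` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qq_curves <- function(curves, path) {
  readr::write_tsv(
    dplyr::select(curves, stratum = "stratum_threshold", "expected",
                  "observed", "effective_n"),
    path
  )
  invisible(path)
}
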