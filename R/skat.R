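# SKAT variance-component score test for gene-level case-control burden.

# Imhof (1961) tail probability P(sum_k lambda_k chi2_1k > q) by numerical
# inversion of the characteristic function. Returns NA when integration
# fails; callers fall back to the Liu moment-matched approximation.
imhof_tail <- function(q, lambda) {
  integrand <- function(u) {
    vapply(u, function(uu) {
      if (uu == 0) return(sum(lambda) / 2 - q / 2) # limit of sin(theta)/(u*rho)
      theta <- 0.5 * sum(atan(lambda * uu)) - 0.5 * q * uu
      rho <- exp(0.25 * sum(log1p((lambda * uu)^2)))
      sin(theta) / (uu * rho)
    }, numeric(1))
  }
  res <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
              subdivisions = 2000L, stop.on.error = FALSE),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value)) return(NA_real_)
  0.5 + res$value / pi
}

# Liu-Tang-Zhang moment-matched non-central chi-square approximation.
liu_tail <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    d <- 0
  }
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  mu_x <- l + d
  sigma_x <- sqrt(2) * sqrt(l + 2 * d)
  pchisq((q - mu_q) / sigma_q * sigma_x + mu_x, df = l, ncp = d,
         lower.tail = FALSE)
}

mixture_chisq_tail <- function(q, lambda) {
  if (length(lambda) == 1L) {
    # one eigenvalue: the mixture law is exactly lambda * chi2_1
    return(list(p = pchisq(q / lambda, df = 1, lower.tail = FALSE),
                method = "exact"))
  }
  p <- imhof_tail(q, lambda)
  method <- "imhof"
  if (is.na(p) || p <= 0 || p > 1) {
    p <- liu_tail(q, lambda)
    method <- "liu"
  }
  list(p = min(max(p, .p_floor), 1), method = method)
}

#' Default SKAT variant weights
#'
#' The canonical Beta(1, 25) density evaluated at the folded minor allele
#' frequency, up-weighting rare variants.
#'
#' @param maf Minor allele frequencies in `[0, 0.5]`.
#' @return Non-negative weights.
#' @export
skat_beta_weights <- function(maf) dbeta(maf, 1, 25)

#' SKAT variance-component test
#'
#' Score test for association between a set of variants and a binary
#' phenotype. With null fitted probabilities \eqn{\hat\mu} from a logistic
#' regression of `y` on covariates (intercept always included), the
#' statistic is the weighted quadratic form
#' \deqn{Q = (y - \hat\mu)^T G W^2 G^T (y - \hat\mu)}
#' and its null distribution is the mixture \eqn{\sum_k \xi_k \chi^2_{1}}
#' with \eqn{\xi_k} the eigenvalues of \eqn{W G^T P_0 G W}, where
#' \eqn{P_0 = V - V X (X^T V X)^{-1} X^T V} is the null projection with
#' \eqn{V = diag(\hat\mu(1-\hat\mu))}. The tail probability is evaluated by
#' numerical inversion of the characteristic function (Imhof), with a
#' moment-matched non-central chi-square fallback when inversion fails.
#'
#' Missing genotypes are imputed to the variant mean; monomorphic variants
#' carry no information and are dropped. No minor-allele-frequency
#' threshold is applied.
#'
#' @param G Samples x variants matrix of additive dosages (0/1/2,
#'   `NA` allowed).
#' @param y Binary phenotype vector (0/1); both classes must be present.
#' @param X Optional covariate matrix (samples x k); an intercept is always
#'   added.
#' @param weights Per-variant weights; default Beta(1, 25) density at the
#'   folded MAF ([skat_beta_weights()]). Use `rep(1, ncol(G))` for flat
#'   weights.
#' @param gene Gene label carried into the result.
#' @param n_perm If positive, additionally computes a permutation p-value
#'   by permuting the phenotype `n_perm` times (only valid without
#'   covariates).
#' @param perm_seed Seed for the permutation draw.
#' @return A `skat_fit` object with elements `gene`, `Q`, `pvalue`,
#'   `eigenvalues`, `n_variants`, `n_samples`, `method`, and optionally
#'   `p_permutation`.
#' @export
skat_test <- function(G, y, X = NULL, weights = NULL, gene = "gene",
                      n_perm = 0L, perm_seed = 1L) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(G) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) {
    abort("Phenotype must contain both classes.", class = "conjfdr_input_error")
  }
  if (!is.null(X) && n_perm > 0) {
    abort("Permutation p-values are only supported without covariates.")
  }

  # mean-impute missing dosages per variant
  if (anyNA(G)) {
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) G[nas, j] <- mean(G[!nas, j])
    }
  }

  poly <- apply(G, 2, function(g) stats::var(g) > 0)
  if (!all(poly)) {
    inform(sprintf("skat_test: dropped %d monomorphic variant(s).", sum(!poly)))
  }
  G <- G[, poly, drop = FALSE]

  Xmat <- cbind(`(Intercept)` = rep(1, length(y)), X)
  fit <- glm.fit(Xmat, y, family = binomial())
  if (!fit$converged) abort("Null logistic model did not converge.")
  mu <- fit$fitted.values
  v <- mu * (1 - mu)
  r <- y - mu

  if (ncol(G) == 0L) {
    return(new_skat_fit(gene, Q = 0, pvalue = 1, eigenvalues = numeric(),
                        n_variants = 0L, n_samples = length(y),
                        method = "degenerate"))
  }

  freq <- colMeans(G) / 2
  maf <- pmin(freq, 1 - freq)
  w <- if (is.null(weights)) skat_beta_weights(maf) else as.numeric(weights)[poly]
  stopifnot(length(w) == ncol(G), all(w >= 0))

  wG <- sweep(G, 2, w, `*`)
  score <- drop(crossprod(wG, r))
  Q <- sum(score^2)

  # K = W G' P0 G W without forming the n x n projection
  VG <- wG * v
  VX <- Xmat * v
  XtVX <- crossprod(Xmat, VX)
  B <- crossprod(Xmat, VG)               # k x m
  K <- crossprod(wG, VG) - t(B) %*% solve(XtVX, B)
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-10]

  if (length(ev) == 0L || Q <= 0) {
    fit_out <- new_skat_fit(gene, Q = Q, pvalue = 1, eigenvalues = ev,
                            n_variants = ncol(G), n_samples = length(y),
                            method = "degenerate")
  } else {
    tail <- mixture_chisq_tail(Q, ev)
    fit_out <- new_skat_fit(gene, Q = Q, pvalue = tail$p, eigenvalues = ev,
                            n_variants = ncol(G), n_samples = length(y),
                            method = tail$method)
  }

  if (n_perm > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(perm_seed)
    Kn <- tcrossprod(wG)                  # n x n kernel
    Rp <- vapply(seq_len(n_perm), function(i) r[sample.int(length(r))],
                 numeric(length(r)))
    Qp <- colSums(Rp * (Kn %*% Rp))
    fit_out$p_permutation <- (1 + sum(Qp >= Q)) / (n_perm + 1)
  }
  fit_out
}

new_skat_fit <- function(gene, Q, pvalue, eigenvalues, n_variants, n_samples,
                         method) {
  structure(
    list(gene = gene, Q = Q, pvalue = pvalue, eigenvalues = eigenvalues,
         n_variants = n_variants, n_samples = n_samples, method = method,
         p_permutation = NULL),
    class = "skat_fit"
  )
}

#' @export
print.skat_fit <- function(x, ...) {
  cat(sprintf("SKAT test for %s: Q = %.4g, p = %.3g (%s; %d variants, %d samples)\n",
              x$gene, x$Q, x$pvalue, x$method, x$n_variants, x$n_samples))
  if (!is.null(x$p_permutation)) {
    cat(sprintf("  permutation p = %.3g\n", x$p_permutation))
  }
  invisible(x)
}

#' Bonferroni correction for a set of gene tests
#'
#' @param pvalues Named numeric vector of per-gene p-values.
#' @param n_tests Number of tests corrected for; must be at least
#'   `length(pvalues)` (defaults to it).
#' @return Adjusted p-values `min(1, p * n_tests)`, names preserved.
#' @export
bonferroni <- function(pvalues, n_tests = length(pvalues)) {
  stopifnot(n_tests >= length(pvalues))
  setNames(p.adjust(pvalues, method = "bonferroni", n = n_tests),
           names(pvalues))
}
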