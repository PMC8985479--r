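---
title: "Cross-trait conditional and conjunctional FDR: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait conditional and conjunctional FDR: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjfdr)
```

## The problem

Two genome-wide association studies (GWAS) of different traits — in the
motivating setting, a small neurodegenerative-disease GWAS such as multiple
system atrophy (MSA) and a large immune-disease GWAS such as inflammatory
bowel disease (IBD) — may share part of their genetic architecture even
when neither study alone localises the shared variants. Conditioning one
trait's test statistics on the other's borrows power: a variant with a
modestly small p-value in both traits is far more surprising under the
joint null than either marginal p-value suggests.

`conjfdr` implements this cross-trait analysis end to end on summary
statistics: harmonization, LD-aware genomic inflation control, conditional
Q-Q enrichment diagnostics, conditional/conjunctional false discovery rate
(condFDR/conjFDR) estimation, clumping of significant variants into
LD-independent loci with gene annotation, and a SKAT variance-component
test for gene-level follow-up in genotype-level case-control cohorts.

## The condFDR/conjFDR model

For a variant with p-values $(p_1, p_2)$ in the primary and conditional
trait, the conditional FDR is estimated as

$$\widehat{\mathrm{cFDR}}(p_1 \mid p_2 \le c) \;=\;
\min\!\Big(1,\; \frac{p_1}{\hat F(p_1 \mid p_2 \le c)}\Big),$$

where $\hat F$ is the weighted empirical cdf of $p_1$ over variants whose
conditional p-value is at most $c$. This is the conservative standard
construction with the null proportion $\pi_0$ fixed at 1; any true signal
only makes the estimate an upper bound. The conjunctional FDR swaps the
trait roles and takes the maximum of the two estimates, upper-bounding the
FDR for association with *both* traits.

Everything empirical is weighted: each variant contributes its random
pruning weight (below) so that large LD clumps do not dominate $\hat F$.

### Grid, interpolation and monotonicity

Estimates are computed on a grid — 200 log-spaced $p_1$ nodes on
$[10^{-12}, 1]$ by 40 log-spaced conditioning cuts on $[10^{-8}, 1]$ —
and queried by bilinear interpolation in $(\log_{10} p_1, \log_{10} p_2)$,
log-linear in the estimate. Within a flat stretch of $\hat F$ the
log-linear rule is exact, since $\log \mathrm{cFDR} = \log p_1 - \log \hat F$
is linear in $\log p_1$.

Two monotone passes are enforced after raw counting: a running maximum
along increasing $p_1$ within each conditioning column (weaker evidence
cannot get a smaller FDR), then a running minimum from lenient toward
stricter cuts (more conditioning cannot hurt). Below the stratum's
smallest observed $p_1$, $\hat F$ is floored at its first step height so
the estimate keeps decaying instead of jumping to 1. Ties in p-values
count fully in $\hat F$ ($\le$ comparisons), making results deterministic.
Empty conditioning strata inherit the nearest populated column. p-values
are floored at $10^{-300}$ before any log transform.

On small tables with unit weights the raw grid values at the data points
reproduce direct counting to machine precision; the tests verify this
against an independently coded double-loop oracle, and verify the grids on
the packaged 10-variant worked fixture whose condFDR values were computed
by hand.

## LD pruning weights and genomic control

LD makes neighbouring variants redundant. Following PLINK-style pruning
semantics, one round of random pruning visits variants in a seeded random
order and retains a variant iff no already-retained variant has
$r^2 > 0.1$ with it (a greedy maximal independent set — not connected
components, which would under-count weakly linked variants). Averaging the
retention indicator over 100 iterations (per-iteration RNG streams derived
from the seed, so iterations are order-independent) gives each variant a
weight in $[0,1]$: an isolated variant gets exactly 1, a fully linked
clump of $k$ shares total weight $\approx 1$.

The genomic inflation factor is the weighted median of the implied 1-df
chi-square statistics divided by the null median $0.454936$, with the
pruning weights as the de-correlation device; correction divides all
chi-square statistics by $\hat\lambda$ and maps back to p-values.
Deflation is never applied ($\hat\lambda < 1$ is reported but not used),
so correction can only be conservative and always preserves p-value ranks.
The median constant is fixed to 15 digits so $\hat\lambda$ is
bit-reproducible.

Default LD handling parameters: $\pm 20$ Mb window for $r^2$ estimation,
pruning threshold $r^2 = 0.1$, 100 iterations; pairs with $r^2 < 0.05$ are
not stored (the storage floor must not exceed any analysis threshold).
The extended HLA (chr6:25,119,106–33,854,733) and MAPT
(chr17:40,000,000–47,000,000) regions (GRCh37) are excluded from all
analyses by default — their long-range LD otherwise distorts the empirical
cdfs.

## Conditional Q-Q curves and the deflection statistic

Conditional Q-Q curves plot observed weighted quantiles of $-\log_{10} p_1$
against expected uniform quantiles within strata of increasingly
significant conditional p-values ($p_2 < 1, 0.1, 0.01, 0.001$). Cross-trait
enrichment appears as successive upward deflection with stricter
conditioning.

The one-number summary, `qq_deflection()`, is the mean of (observed −
expected) over expected $-\log_{10} p \in [0, 2]$. We deliberately average
over the well-supported part of the curve rather than reading a single
far-tail point: a stratum with a few dozen effective variants saturates at
its minimum p-value beyond expected $\approx 2$, so a point statistic
there degenerates to $-\log_{10}(\min p_1)$ and ties between neighbouring
strata. The companion null band (`qq_deflection_null_band()`) is a
Monte-Carlo band for the same statistic computed from independent uniform
draws at the stratum's effective size.

When the primary trait is itself polygenic, every stratum — including the
unconditioned one — deflects upward; cross-trait enrichment is the
*excess* of a conditioned stratum's deflection over the all-SNP curve,
and that excess is what the null band should be applied to.

Strata whose total weight falls below 50 are omitted from the curves:
below that, even the averaged deflection is dominated by a handful of
order statistics.

## Harmonization conventions

Tables merge on (chromosome, position) — variant-id dialects differ across
GWAS releases — keeping the smaller-$p_1$ record at duplicated positions.
The second trait's z-score is sign-flipped when its alleles are recorded
in the opposite orientation; strand-ambiguous A/T and C/G variants are
dropped because their orientation cannot be verified across studies, and
allele-mismatched records are dropped. All coordinates are 1-based
inclusive GRCh37; BED inputs (0-based half-open) are converted on read.

## Loci

Significant variants (conjFDR < 0.05) are clumped greedily: the
smallest-conjFDR variant seeds a locus and absorbs all significant
variants with $r^2 > 0.1$ with it (ties broken by smaller $p_1$, then
position — so the output is invariant to input order). Members are
*reported* at the stricter display threshold $r^2 > 0.6$ with the lead.
Genes are annotated within an inclusive ±100 kb window of the lead;
the lead's relation to the closest gene is classified at gene-interval
level as inside/upstream/downstream, with upstream meaning the 5' side
under the gene's strand. Finer intron/exon classification would require
transcript models and is out of scope.

## SKAT

For gene-level follow-up in case-control genotype data, the SKAT statistic
$Q = (y-\hat\mu)^\top G W^2 G^\top (y-\hat\mu)$ is computed from a
logistic null model (intercept plus optional covariates), with default
variant weights $w_v = \mathrm{Beta}(\mathrm{MAF}_v; 1, 25)$ density (flat
weights optional) and no minor-allele-frequency threshold; monomorphic
variants carry no information and are dropped, missing genotypes are
mean-imputed. The null distribution $\sum_k \xi_k \chi^2_{1,k}$ uses the
eigenvalues of $W G^\top P_0 G W$; its tail is evaluated by Imhof's
characteristic-function inversion (exact chi-square when a single
eigenvalue remains, moment-matched non-central chi-square fallback if the
integration fails). A phenotype-permutation oracle is available for
verification in covariate-free models. Small-sample moment corrections
for binary traits are not implemented; at moderate case counts the
large-sample null is slightly conservative, which the type-I simulations
show. Bonferroni correction across candidate genes uses
$\min(1, p \times n)$.

## The synthetic generator

`simulate_pair()` is the package's study-condition generator, not a test
dial. Variants sit in equal LD blocks with exchangeable within-block
correlation ($r^2$ = 0.8 by default, 5 variants per block) — chosen over
realistic LD decay so the relation between pruning weights and block size
stays analytically checkable (expected weight $\approx 1/k$ in a fully
linked $k$-block). Causal labels are drawn per variant
(trait-1-specific $\pi_1 = 0.002$, trait-2-specific $\pi_2 = 0.005$,
shared $\pi_{12} = 0.01$), shared effects are bivariate normal with
correlation 0.8, and marginal z-scores follow
$z = \sqrt{N} R\beta + \epsilon$, $\epsilon \sim N(0, R)$ per block,
optionally scaled by $\sqrt{\lambda}$ to inject inflation. The default
sample sizes (4,782 and 59,957) and effect variances (giving per-variant
non-centralities of roughly 8 and 24) emulate a small primary GWAS
conditioned on a well-powered secondary GWAS, where hundreds of secondary
loci reach genome-wide significance but primary hits are scarce — the
regime in which conditional FDR is useful. Effects propagate to block
neighbours through $R\beta$, so "null-labelled" variants inside causal
blocks are genuinely associated tags, not false positives.

What the generator does *not* emulate: realistic LD decay with distance,
allele-frequency-dependent effect sizes, sample overlap between the two
GWAS (the pipeline deliberately does not correct for overlap and shares
this limitation with its defaults; the configuration documents where such
a correction would enter), and liability-threshold case-control phenotypes.
Passing tests therefore demonstrate correctness of the estimators under a
clean polygenic-overlap model, not robustness to every property of real
GWAS. One consequence worth knowing: marginally uniform null p-values are
*dependent* within blocks, so whole-set uniformity tests (e.g.
Kolmogorov–Smirnov over all variants) over-reject; uniformity holds, and
is tested, on LD-pruned subsets.

## Problem sizes used in the checks

The packaged statistical checks run the generator at 10,000 variants in
2,000 blocks (the worked condFDR fixture has 10 variants); calibration
uses 50–100 replicates, enrichment monotonicity 25–50 seeds, SKAT type-I
error 500 replicates at 200 samples, pruning-weight expectations 10,000
iterations, and the SKAT permutation oracle 20,000 permutations at 50
samples. These sizes give Monte-Carlo standard errors comfortably inside
the asserted tolerances (three binomial standard errors throughout).

## Known limitations

* No sample-overlap correction between the two GWAS; with shared controls
  the conjFDR is anti-conservative to an unquantified degree.
* $\pi_0 = 1$ makes condFDR conservative when true signal is abundant.
* The condFDR grid resolution (200 × 40 log-spaced nodes) limits accuracy
  for p-values below $10^{-12}$, which are clamped.
* Gene relation labels are interval-level only.
* SKAT uses the large-sample null for binary traits; for very small or
  very unbalanced cohorts prefer the permutation p-value.
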