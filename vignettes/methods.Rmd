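---
title: "Integrating differential expression and splicing in gene set enrichment analysis"
author: "splicegsea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating differential expression and splicing in gene set enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicegsea)
```

## The problem

In a two-group RNA-seq comparison a gene's transcript output can change in
two distinct ways: the total amount of RNA produced (differential
expression, DE) and the relative usage of the gene's parts through
alternative splicing (differential splicing, DS). Conventional gene set
enrichment analysis ranks genes by a DE statistic only, so gene sets whose
regulation is predominantly splicing-driven are invisible to it.
`splicegsea` scores both aspects per gene from the same sub-exon count
table, places them on a common scale, combines them with a tunable weight,
and tests gene sets with a cutoff-free, permutation-calibrated enrichment
statistic. The package is aimed at case/control designs with a moderate
number of biological replicates per group (roughly five or more), which the
sample-permutation significance scheme requires.

## Counting units: sub-exons

Exon-level counts are insensitive to alternative 3'/5' splice sites when
exons are taken as annotated. `flatten_gene()` therefore splits the union
of a gene's exons (over all isoforms) at **every** distinct exon start and
end, producing disjoint, contiguous fragments called sub-exons; any
annotated splice boundary starts a new fragment. Internally the package
uses 0-based half-open coordinates (GTF input, 1-based closed, is converted
on import), implemented with `IRanges::disjoin()`. Sub-exons are defined
per gene independently: territory shared by overlapping genes appears in
both gene models, and strand is recorded but plays no role in boundary
placement. Obtaining counts from alignments is out of scope; the package
consumes a sub-exon count table.

With $X_{ij}^{(g)}$ the read count of sub-exon $i$ in gene $g$ for sample
$j$, the gene total is $Y_j^{(g)} = \sum_i X_{ij}^{(g)}$. DE analysis uses
the $Y$ matrix; DS analysis uses the $X_{ij}$ given the totals.

## Count model and per-gene scores

Counts are modelled as negative binomial,
$Y_j^{(g)} \sim NB(\mu_{gj}, \sigma^2_{gj})$ with
$\mu_{gj} = s_j\, q_{g,\rho(j)}$ and $\sigma^2 = \mu + \phi\mu^2$, where
$s_j$ is a per-sample size factor (DESeq-style median-of-ratios on gene
totals, computed once from the observed data and held fixed under label
permutation, since sequencing depth is a sample property), $q$ the expected
normalized expression in the sample's group $\rho(j)$, and $\phi$ the
dispersion.

**DE score.** Each group is estimated on its own samples only — no
information sharing across groups, so that group labels can be permuted
freely. Per gene and group: $\hat q$ is the mean of $Y_j/s_j$; $\hat\phi$
is a method-of-moments estimate on normalized counts, floored at zero; and
$\hat V(\hat q) = m^{-2}\sum_j(\hat q/s_j + \hat\phi\hat q^2)$ propagates
the NB variance. The score is
$$S_{DE}(g) = \frac{(\hat q_{g,A}-\hat q_{g,B})^2}
{\hat V(q_{g,A})+\hat V(q_{g,B})}.$$
No shrinkage of dispersions across genes is attempted: per-group moment
estimation keeps the estimator simple, unbiased and easy to validate, at
the cost of noisier dispersions than trended empirical-Bayes methods —
acceptable here because scores are always judged against their own
permutation background rather than a parametric null.

**DS score.** Within each group the expected read-count fraction of
sub-exon $i$ is the pooled estimate
$\hat p_i = \sum_j X_{ij} / \sum_j Y_j$ (a $Y_j$-weighted mean of the
per-sample fractions $f_{ij}=X_{ij}/Y_j$; samples with $Y_j=0$ are dropped,
not imputed). Its variance is taken as the **maximum** of a delta-method NB
variance of the pooled fraction and the empirical between-sample variance
of the $f_{ij}$ divided by the number of contributing samples; the maximum
guards the denominator against occasional under-dispersion of either
component. The score averages over the gene's sub-exons:
$$S_{DS}(g) = \frac{1}{N^{(g)}}\sum_{i=1}^{N^{(g)}}
\frac{(\hat p_{i,A}-\hat p_{i,B})^2}
{\hat V(\hat p_{i,A})+\hat V(\hat p_{i,B})}.$$
Sub-exons are weighted equally in the average. Genes with one usable
sub-exon score 0 (`single-subexon`), genes with no reads in a group score 0
(`DS-undefined`); sub-exons removed by the low-count filter leave both the
numerator and the $N^{(g)}$ divisor, while gene totals always keep all
reads.

Both scores are squared differences over variance sums: non-negative and
direction-free by construction. Discarding direction is deliberate — a
splicing change has no natural sign, and taking magnitudes lets
reciprocally regulated genes (e.g. feedback partners) reinforce rather
than cancel within a set.

**Degenerate denominators.** The defining equations leave 0/0 open for
genes that are flat in both groups. Both-zero genes score 0 by rule first;
everything else receives an `eps = 1e-8` denominator stabilizer, small
enough to be invisible against any real variance estimate.

## Normalization and integration

DE and DS scores live on incomparable scales, so each is divided by its
own mean over class-label permutations,
$S_{\cdot,norm}(g) = S_\cdot(g) / \bar T_\cdot^{(g)}$: after this step
every gene's mean normalized permutation score is exactly 1 (an identity
the tests assert). Genes with $\bar T^{(g)} = 0$ are kept with normalized
score 0 rather than dropped, so effective gene-set sizes do not depend on
the integration weight.

Two integration strategies produce the per-gene score $S(g)$ at weight
$\alpha \in [0,1]$:

* **linear**: $S(g) = \alpha S_{DE,norm} + (1-\alpha) S_{DS,norm}$;
* **rank-based**: with ascending ranks $\gamma_{DE}, \gamma_{DS}$
  (mid-ranks on ties — order-independent where the data give no ordering),
  $$S(g) = \frac{\alpha\gamma_{DE}S_{DE,norm} +
  (1-\alpha)\gamma_{DS}S_{DS,norm}}
  {\alpha\gamma_{DE} + (1-\alpha)\gamma_{DS}},$$
  so whichever component ranks higher for a gene dominates automatically.
  Permutation columns are ranked either globally (observed-data ranks
  reused; `rank-glb`) or per permutation (`rank-sp`).

$\alpha = 1$ reduces to DE-only and $\alpha = 0$ to DS-only analysis; the
implementation returns the input vectors unchanged at the extremes so the
degeneracy is exact to the bit, not merely to rounding. Quadratic and
higher-order combinations behave like the linear one and are not
implemented.

## Enrichment testing

Genes are sorted by $S(g)$ in decreasing order and a running sum gains
$|S(g)|^{w}/N_R$ at gene-set members ($N_R$ the sum of member weights) and
loses $1/(N-N_H)$ at non-members; the enrichment score ES is the maximum
of this sum. The default exponent $w=1$ weights hits by score; $w=0$ gives
the classic equal-increment statistic. Testing is one-sided: scores are
non-negative, so only concentration at the top of the ranking is
meaningful. If every member scores 0, increments fall back to $1/N_H$.

Significance comes from the same class-label permutations used for
normalization (default 1000; small designs fall back to enumerating all
distinct assignments with a warning). The *entire* pipeline — per-group
estimation, scoring, normalization, integration, ES — is recomputed under
each permuted labelling, and the label shuffles plus raw DE/DS permutation
scores are shared across every strategy and weight. Per set:
$p_{emp} = (1+\#\{ES_{perm}\ge ES_{obs}\})/(P+1)$ (never 0 by
construction); $NES = ES/\overline{ES^{+}_{perm}}$; and a one-tailed FDR,
the pooled permutation-NES tail fraction over the observed-NES tail
fraction, clipped to $[0,1]$ and made monotone non-increasing in NES by a
running minimum from the least significant set (the BH-style step that
keeps stronger sets from carrying larger FDRs than weaker ones).
Gene sets are read from GMT, intersected with the scored genes, and skipped
outside the default size bounds $[5, 1000]$ (a gene set equal to the whole
universe has no misses and no defined ES).

## Weight scan and saturation

No prior knowledge fixes the relative contribution of expression and
splicing in a given gene set, so the recommended practice is to scan a
grid of weights — 11 weights $\{0, 0.1, \ldots, 1\}$ by default — and keep
the union of sets significant at any weight. `saturation_analysis()`
verifies the grid is wide enough: adding weights in the order
$1, 0, 0.5, 0.1, 0.9, 0.3, 0.7, 0.2, 0.4, 0.6, 0.8, 0.05, \ldots$
(extremes first, then midpoints) yields a cumulative count of unique
significant sets that is monotone by construction; a plateau before the
grid is exhausted indicates saturation.

## Default parameters

| parameter | default | why |
|---|---|---|
| `min_gene_total` | 10 reads (summed over samples) | NB moment estimates are unstable on near-zero rows |
| `min_subexon_total` | 5 reads | same, for fraction estimates; affects DS only |
| `eps` | 1e-8 | 0/0 guard, negligible against any real variance |
| `n_perm` | 1000 | permutation resolution of $p_{emp} \ge 1/1001$ |
| `weight_exp` | 1 | score-weighted running sum; set 0 for the classic statistic |
| `alphas` | $\{0,0.1,\ldots,1\}$ | the 11-weight grid that saturation analysis generally supports |
| `min_size`, `max_size` | 5, 1000 | conventional gene-set bounds |
| `fdr_cutoff` | 0.05 | reporting threshold for the scan |

## The synthetic-data generator

`simulate_dataset()` generates datasets under exactly the model the method
assumes: per-gene log-normal baseline expression $q$ (default
$\log q \sim N(\log 150, 1)$ — moderately deep coverage), NB gene totals
with dispersion $\phi$ (default 0.1, typical for biological replicates;
$\phi = 0$ gives the Poisson limit), uniform size factors on $[0.7, 1.4]$,
and sub-exon counts multinomially thinned from the totals with per-group
Dirichlet proportions (concentration 5 over 2–8 sub-exons). Drawing totals
first and thinning second enforces $Y=\sum_i X_i$ exactly and separates
the two truth layers: DE genes have their group-B expectation multiplied
by `de_fold` (direction random), DS genes have `ds_shift` proportion mass
moved between two random sub-exons in group B with totals untouched — the
two effects are orthogonal by construction, and the DE and DS gene pools
are disjoint. Planted gene sets draw 80–90% of members from the matching
effect pool; null sets draw from unaffected genes.

What the generator does **not** emulate: positional/GC bias, correlated
genes, batch effects, outlier samples, or annotation errors. Passing the
package's validation on this generator therefore demonstrates internal
correctness and calibration under the stated model, not robustness to
real-data artifacts such as batch structure (which would need explicit
covariate adjustment, currently out of scope).

## Validation study conditions

The shipped tests and `scripts/acceptance.R` run two fixed studies chosen
to be informative yet desk-sized: a **null study** (1000 genes, 5 vs 5,
$\phi=0.1$, no effects, 200 permutations, 200 null sets of 10–30 genes)
checking that empirical p-values are uniform and FDR calls are rare; and a
**planted study** (1000 genes, 10 vs 10, 10% DE genes at 4-fold, 10% DS
genes at 0.3 proportion shift, one DE-driven and one DS-driven set among
50 null sets, 200 permutations, 21-weight grid) checking that the weight
scan's union recovers both planted sets while each extreme weight alone
misses the other mechanism's set, and that the saturation curve plateaus
early. Enrichment scores are additionally verified against a brute-force
running-sum oracle to $10^{-12}$, and estimators against their generating
parameters (expression within 3 SE; dispersion within $\pm 0.05$ at 2000
genes via a $1/\hat\mu^4$-weighted mean–variance regression — the
weighting matters, because the sampling variance of a sample variance
grows with $\mu^4$ and an unweighted fit is dominated by a handful of
highly expressed genes).

## Known limitations

* Two groups only; no paired designs, covariates or batch adjustment.
* Per-gene moment dispersions are noisy for very small groups; with fewer
  than ~4 replicates per group the permutation space is also tiny and
  enumeration caps the attainable significance.
* The DS variance construction (delta-method vs. empirical maximum) is a
  conservative design choice; alternatives could be sharper for very deep
  counts.
* Read counting from alignments, isoform-level inference and leading-edge
  reporting are out of scope.
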