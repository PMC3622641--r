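# splicegsea

Gene set enrichment analysis of two-group RNA-seq count data that
integrates **differential expression** (DE — changes in a gene's overall
transcript abundance) with **differential splicing** (DS — changes in the
relative usage of the gene's parts). Standard GSEA ranks genes by a DE
statistic alone, so pathways regulated predominantly through alternative
splicing never surface; `splicegsea` scores both mechanisms per gene from
one sub-exon count table and tests gene sets against a combined ranking.

It is aimed at case/control transcriptome studies — human disease cohorts
in particular — with a moderate number of biological replicates per group,
where permutation of sample labels provides honest significance despite
large biological variability.

## Method in brief

Sub-exons are disjoint exon fragments obtained by splitting a gene's exon
union at every annotated splice boundary. With $X_{ij}^{(g)}$ the count of
sub-exon $i$ in sample $j$ and $Y_j^{(g)} = \sum_i X_{ij}^{(g)}$, counts
are modelled as negative binomial, $Y_j \sim NB(\mu_j, \sigma_j^2)$,
$\mu_j = s_j q_{\rho(j)}$, $\sigma^2 = \mu + \phi\mu^2$. Per gene:

$$S_{DE}(g) = \frac{(\hat q_A-\hat q_B)^2}{\hat V(q_A)+\hat V(q_B)},
\qquad
S_{DS}(g) = \frac{1}{N^{(g)}}\sum_i
\frac{(\hat p_{i,A}-\hat p_{i,B})^2}{\hat V(\hat p_{i,A})+\hat V(\hat p_{i,B})},$$

where $\hat p_i$ is the expected read-count fraction of sub-exon $i$.
Each score is normalized by its mean over class-label permutations and the
two are combined at weight $\alpha \in [0,1]$, either linearly,
$S = \alpha S_{DE,norm} + (1-\alpha) S_{DS,norm}$, or rank-weighted
(`rank-sp` / `rank-glb`). Gene sets are tested with a weighted
Kolmogorov–Smirnov-like running-sum enrichment score over the
score-ranked genes, with empirical p-values and FDRs from the same label
permutations. $\alpha=1$ degenerates to DE-only analysis, $\alpha=0$ to
DS-only; scanning an 11-weight grid and keeping the union recovers sets
driven by either mechanism, and a saturation analysis checks that the
grid is wide enough. Details are in `vignettes/methods.Rmd`.

## Worked example

A synthetic dataset with known truth: 500 genes, 5 vs 5 samples, 10% of
genes 4-fold DE, a disjoint 10% with a 0.3 proportion shift between two
sub-exons, one gene set enriched in DE genes, one in DS genes, 20 null
sets.

```r
library(splicegsea)

cfg <- sim_config(n_genes = 500, m_a = 5, m_b = 5,
                  de_fraction = 0.1, de_fold = 4,
                  ds_fraction = 0.1, ds_shift = 0.3,
                  genesets = list(n_null = 20, n_de = 1, n_ds = 1,
                                  size_range = c(15, 25)),
                  seed = 7)
sim <- simulate_dataset(cfg)
cd  <- filter_low_expression(sim$counts)
#> count_data: 500 genes, 2493 sub-exons, 10 samples (A: 5, B: 5)

run  <- run_gsea(cd, sim$gene_sets, strategies = "linear",
                 alphas = seq(0, 1, by = 0.1), n_perm = 200, seed = 8)
scan <- weight_scan(run, fdr_cutoff = 0.05)

subset(run$results, alpha %in% c(0, 0.5, 1) &
       set_name %in% c("de_set_001", "ds_set_001"))
#>    set_name alpha        ES       NES       p_emp       FDR
#>  de_set_001   0.0 0.7497089 2.0258014 0.009950249 0.0400000
#>  ds_set_001   0.0 0.8506534 2.5969317 0.009950249 0.0050000
#>  de_set_001   0.5 0.8262822 2.4114802 0.009950249 0.0050000
#>  ds_set_001   0.5 0.7415808 1.8270082 0.009950249 0.0475000
#>  de_set_001   1.0 0.9191188 1.8797043 0.009950249 0.0050000
#>  ds_set_001   1.0 0.5431444 0.9217687 0.691542289 0.9927273
```

Reading the table: `ES` is the running-sum enrichment score of the set at
that weight, `NES` its value normalized by the permutation mean, `p_emp`
the add-one empirical p-value (200 permutations, so it is floored at
1/201 ≈ 0.005), and `FDR` the one-tailed permutation FDR. The
splicing-driven set is invisible to the DE-only analysis (`alpha = 1`:
NES 0.92, FDR 0.99) but strongly significant once DS contributes
(`alpha = 0`: NES 2.60, FDR 0.005); the union over the 11-weight scan
contains both planted sets:

```r
scan$union
#> $linear
#> [1] "de_set_001" "ds_set_001"

saturation_analysis(scan)
#>  n_weights weight_added cumulative_sets
#>          1          1.0               1
#>          2          0.0               2
#>          3          0.5               2
#>          ...        ...             ...
#>         11          0.8               2
```

The saturation curve plateaus at two weights here — after the DE-only and
DS-only extremes nothing new is detected — indicating the grid is ample
for this dataset.

A one-call pipeline (`run_pipeline(config, out_dir)`) writes score
tables, enrichment results, the scan membership table, the saturation
curve and a JSON run manifest; `inst/cli/splicegsea.R` exposes `flatten`,
`simulate`, `run` and `saturate` subcommands for shell use.

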