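# markeval

Integrative evaluation of disease candidate genes from curated
literature evidence, pathway annotation and independent case/control
expression data.

Literature-curated candidate pools for complex diseases are large and
noisy: typically half the genes are supported by a single unreplicated
study. `markeval` scores every candidate on four complementary axes and
validates any resulting ranking against expression data:

* **RScore** — number of distinct references supporting the gene–disease
  relationship (publication frequency).
* **AScore** — age in years of the earliest supporting publication,
  `max_i [(current_date − pub_date_i) + 1] / 365.25`; small values flag
  recently reported genes (the default novelty filter keeps
  AScore ≤ 2).
* **PScore** — number of significantly enriched candidate pathways
  containing the gene, with significance decided by a one-sided Fisher
  exact test (`P(X ≥ overlap)`, hypergeometric tail over an explicit
  annotation universe) combined with Benjamini–Hochberg FDR control
  (defaults: p < 1e-10 and q = 0.001).
* **SScore** — generalized weighted-degree centrality
  `C_i = deg_i (strength_i / deg_i)^α` (α = 0.5, i.e.
  `sqrt(deg · strength)`) in the gene–gene interaction network whose
  edge weights count shared significant pathways, normalized as
  `N · C_i / Σ_j C_j` so the mean over all scored genes is 1.

A ranking is validated by a nearest-centroid leave-one-out
classification sweep over the top-*n* genes (n = 1, 2, …) on a
case/control expression matrix, followed by a permutation test: the
p-value is the fraction of equally sized random gene subsets reaching a
classification ratio (CR) at least as high as the observed one.

A seeded synthetic-data module generates relation tables with
long-tailed reference counts, overlapping gene-set collections with an
enriched candidate pool, and expression matrices with planted
case/control shifts — so the whole pipeline runs and is tested without
any downloads.

## Worked example

```r
library(markeval)

spec <- synthetic_spec(seed = 42)          # 535 genes, 45/50 samples
fx   <- end_to_end_fixture(spec)           # relations, gene sets, expression
cfg  <- analysis_config(current_date = "2016-10-01", rng_seed = 42)

fit <- marker_metrics(fx$relations, fx$disease_id, fx$pathways,
                      disease_sets = fx$disease_sets, config = cfg)
print(fit)
#> Marker metrics for disease D001: 535 genes scored
#>   significant pathways: 117 of 120; network edges: 107615 (0 isolated genes)
#>   top genes by sscore:
#>   gene rscore   ascore pscore   sscore
#>  G0023     32 14.42300     54 2.343160
#>  G0002     32 16.33949     57 2.335159
#>  G0006     37 16.19165     51 2.313116
#>  G0016     35 15.80835     52 2.309968
#>  G0004     32 16.26557     53 2.302892

sw <- ranked_subset_sweep(fx$expression, metric_ranking(fit, "sscore"),
                          metric_name = "sscore")
pt <- permutation_test(fx$expression, sw$argmax_n, sw$max_cr,
                       runs = 500, seed = 42)
print(sw); print(pt)
#> Ranked-subset sweep (sscore): 535 subset sizes
#>   max CR 89.47% at n = 29 genes
#> Permutation test: observed CR 89.47%, mean permuted CR 54.35% (500 runs)
#>   p-value = 0 (0 run(s) with CR >= observed)
```

Reading: the 29 most central genes classify the 95 samples at 89.5%
accuracy under leave-one-out cross-validation, while random 29-gene
subsets average 54.4%; none of 500 random subsets matched the observed
CR. The planted informative genes of the fixture dominate the top of
every metric ranking, which is exactly what the generator arranges.

The same pipeline runs from the shell via the thin CLI in
`inst/cli/markeval.R` (subcommands `simulate`, `literature`, `enrich`,
`network`, `score`, `sweep`, `permute`, `crossmetrics`, `run-all`), and
`run_full_pipeline()` drives everything from a JSON config, writing a
metric table, enrichment tables, the network edge list, sweep summaries
and a run manifest.

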