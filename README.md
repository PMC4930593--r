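# mitonet

Tumours with high mitotic activity over-express a coordinated network of
mitotic-apparatus genes, and that network — not any single gene — predicts
outcome and drug response. `mitonet` is an R package for transcriptomics /
systems-biology analysts that implements the full analysis around this
idea:

* **Relevance-network discovery**: find all genes whose expression
  correlates with the seed kinases *PLK1*, *CENPE* and *AURKB* beyond a
  permutation-null threshold (pooled null over probes × seeds ×
  permutations; default 1000 permutations, α = 2.5×10⁻⁵), and keep the
  genes that stay connected in every cohort (`build_relevance_network()`,
  `conserve_across_datasets()`).
* **MNAI scoring**: the mitotic network activity index of a sample is the
  sum of the collapsed log2 expression of the conserved genes,
  MNAI_s = Σ_g x_gs, with quality-aware probe→gene collapsing
  (perfect/good averaged; bad probes only when nothing else exists) and
  tertile stratification (`collapse_probes()`, `compute_mnai()`,
  `assign_tertiles()`).
* **Survival**: Kaplan-Meier, upper- vs lower-tertile log-rank, and Cox
  models on continuous standardized MNAI (via the `survival` package,
  Breslow ties).
* **Copy-number association**: greedy merging of adjacent CNA probes into
  regions, gain/loss/amp calls, and a one-at-a-time ANOVA scan of region
  states against each network gene's expression with tiered p-values
  (`merge_regions()`, `call_states()`, `association_scan()`).
* **TF binding-site scanning**: Match-style PWM scoring (matrix and
  5-position core similarity, MSS/CSS) over [-3 kb, +1 kb] promoter
  windows for the amplicon-resident factors MYC, ZEB1, FOXM1 and SOX9
  (`build_pwm()`, `match_score()`, `scan_promoters()`).
* **Pharmacology**: NCI growth percent against a time-0 baseline, GI50 /
  TGI by Hill-linearized interpolation on the nine-dose 1:5 grid from
  30 µM, Mann-Whitney comparison of high- vs low-MNAI lines, inter-drug
  GI50 correlation, pairwise-combination assessment, and siRNA screen
  statistics (`estimate_gi50()`, `compare_response_groups()`,
  `sirna_screen_stats()`).
* **Synthetic cohorts**: a generator that plants the assumed structure —
  a 54-gene module driven by four amplicons (8q24, 10p15-p12, 12p13,
  17q24-q25), survival hazard and drug sensitivity linked to module
  activity, promoter motifs for the four TFs — so every stage is testable
  without controlled-access data (`synthetic_config()`,
  `generate_expression()` and friends).

## Worked example

```r
library(mitonet)

cfg <- synthetic_config()            # 3 cohorts (60/100/200), 54-gene module
gen <- generate_expression(cfg)
ds  <- gen$datasets

thr <- sapply(seq_along(ds), function(d)
  permutation_null_threshold(ds[[d]], n_perm = 1000, alpha = 2.5e-5,
                             rng_seed = sub_seed(cfg$seed, 100 + d))$threshold_r)
net  <- build_relevance_network(ds[[1]], threshold_r = thr[1])
cons <- conserve_across_datasets(ds, net$nodes, thr)
net
#> relevance_network 'synthetic_1': 54 nodes, 1428 edges (|r| >= 0.5162; seeds: PLK1, CENPE, AURKB)
cons
#> conserved_network: 54 of 54 candidate genes retained across 3 dataset(s)
```

The discovery threshold (|r| ≈ 0.52 at n = 60) admits exactly the planted
54-gene module — the conserved set recovers 54/54 planted genes with 0
false positives. Scoring and stratifying the largest cohort:

```r
collapsed <- collapse_probes(ds[[3]], cons$gene_ids)$values
mn   <- compute_mnai(collapsed, cons$gene_ids, "cohort_3")
surv <- generate_survival(cfg, gen$truth$activity[[3]])
tertile_survival(surv, mn)$logrank$p
#> 1.66e-09
```

Samples in the upper MNAI tertile relapse significantly earlier than the
lower tertile, reflecting the planted log hazard ratio of 0.6 per
activity SD. The numbered scripts under `analysis/` run the complete
story (simulation → network → MNAI/survival → CNA scan → motifs →
pharmacology) and print, for example:

```
GSK462364: median GI50 38 nM (high MNAI) vs 251 nM (low), Mann-Whitney p = 6.8e-08
Inter-drug log10 GI50 Pearson r: GSK1070916~GSK462364 0.92, ...
siRNA screen: 22 genes called growth-inhibitory (both siRNAs p < 0.05)
```

i.e. high-MNAI lines are ~6-fold more sensitive to all three mitotic
inhibitors, the three drugs' response profiles are nearly collinear (so
combinations add no effect — the combination verdict is "no added
effect" on both a sensitive and a resistant line), and the screen
recovers the planted growth-essential genes.

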