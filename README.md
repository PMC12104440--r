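# screenfit

Scoring, quality control and hit calling for two-arm (control vs drug)
pooled CRISPR knockout resistance screens, plus the chromatin-accessibility
concordance analysis that usually accompanies them.

The screen design this targets: a drug-resistant cell line carrying Cas9 is
transduced with a focused knockout library (~10 guides per gene plus
non-targeting controls), split into a control arm and a drug-treated arm,
and cultured from T0 to a final timepoint. Genes whose knockout depletes
only under drug are **resensitizers** (they sustain resistance); genes
whose knockout enriches under drug are **resistance enhancers**.

## The statistic

Per guide *i*, the package computes a log2 fold change of normalized
abundance and its z-score across all guides in the comparison,

    z_i = (x_i − mean(x)) / SD(x),

and aggregates per gene as the **CRISPR fitness score** = median of the
gene's guide z-scores. The default treatment-vs-control contrast is the
per-guide difference `log2FC(treatment T24/T0) − log2FC(control T24/T0)`,
which cancels arm-independent (e.g. essentiality) effects. Negative
fitness scores flag resensitizers, positive ones resistance enhancers.
Around that core: median-of-ratios normalization, essentiality ROC-AUC QC
against core-essential / nonessential reference lists, replicate and
between-arm correlations, nine-square classification of per-arm selection
scores, and empirical p-values from a non-targeting-control pseudo-gene
null.

A built-in simulator generates guide libraries, negative-binomial screen
counts under known per-generation selection coefficients, FASTQ reads
(with the spacer counter to read them back), and paired differential
accessibility/expression tables with a tunable concordance fraction — so
the whole pipeline is validated by parameter recovery, no external data
needed.

## Worked example

Simulate a 500-gene screen (10 guides/gene, 100 NTCs, 3 replicates/arm,
12 population doublings, 500 reads/guide) with 10% core-essential, 10%
resensitizer and 10% enhancer genes, then score it:

```r
library(screenfit)

lib    <- build_library(n_genes = 500, guides_per_gene = 10, n_ntc = 100, seed = 1)
truth  <- assign_truth(lib, c(neutral = 0.7, core_essential = 0.1,
                              resensitizer = 0.1, resistance_enhancer = 0.1), seed = 2)
counts <- simulate_screen_counts(lib, truth, sim_design(), seed = 3)
scores <- score_screen(counts, lib)
scores
#> screen_scores: 500 genes, 5100 guides (100 NTC), contrast 'delta'
```

Essentiality QC — core essentials separate perfectly from neutrals on the
control-arm selection score in this simulation:

```r
ess <- truth$gene[truth$effect_class == "core_essential"]
neu <- truth$gene[truth$effect_class == "neutral"]
roc_essentiality(setNames(scores$genes$control_score, scores$genes$gene),
                 ess, neu)$auc
#> [1] 1
```

Hit calling against the NTC pseudo-gene null — the top-ranked depleted
genes are planted resensitizers, at the smallest attainable empirical p
(2000 null resamples):

```r
null <- ntc_null(scores$ntc_z, group_size = 10, n_groups = 2000, seed = 4)
hits <- rank_hits(scores$genes, null, direction = "negative")
head(hits, 3)
#>      gene fitness_score rank  empirical_p         call
#> 1 G000472     -2.598839    1 0.0004997501 resensitizer
#> 2 G000152     -2.574371    2 0.0004997501 resensitizer
#> 3 G000243     -2.564311    3 0.0004997501 resensitizer
```

The nine-square classification recovers the planted structure: the 50
core essentials land in the strong-both-negative cell, the 50
resensitizers in orange (weak control / strong negative treatment — the
synthetic-lethal cell), the 50 enhancers in green:

```r
table(nine_square_classify(scores$genes, threshold = 1)$group)
#>               purple                green                 blue
#>                    0                   50                    0
#>               orange               center strong_both_negative
#>                   50                  350                   50
#> strong_both_positive   discordant_neg_pos   discordant_pos_neg
#>                    0                    0                    0
```

And the accessibility–expression path: simulate peak/DE tables with a 40%
concordance target, then classify peaks, assign them to genes via
promoter windows and enhancer links, and measure concordance:

```r
bundle <- simulate_omics_tables(2000, 2600, concordance_target = 0.40, seed = 5)
concordance_pipeline(bundle)
#> concordance: 800/2000 DE genes concordant (40.0% of all DE, 40.0% of linked DE)
```

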