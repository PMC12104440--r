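---
title: "Scoring two-arm CRISPR resistance screens: models and methods"
author: "screenfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring two-arm CRISPR resistance screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenfit)
```

# The problem

A pooled CRISPR knockout resistance screen transduces a drug-resistant cell
population with a guide library at low MOI, splits it into a control arm and
a drug-treated arm, and cultures both from an initial timepoint (T0) to a
final one (T24, here ~24 days). Guides whose knockouts change fitness shift
in relative abundance; sequencing the integrated spacers before and after
selection quantifies the shift. Two gene classes matter for resistance
biology: *resensitizers* (knockout depletes only under drug — the gene
sustains resistance, so losing it restores drug sensitivity) and
*resistance enhancers* (knockout enriches under drug). Core-essential genes
deplete in both arms and serve as positive controls for screen quality;
non-targeting control (NTC) guides have no genomic target and define the
experimental null.

`screenfit` implements the count-to-hit-list path for such a screen —
spacer counting, normalization, the z-score fitness statistic, essentiality
ROC QC, nine-square classification and NTC-null hit ranking — together with
the chromatin-accessibility concordance analysis that typically accompanies
it, and a simulator that generates all inputs with known ground truth.

# The fitness statistic

For each guide $i$ and contrast, the per-guide signal is a log2 fold
change of normalized abundance; the guide-level normalization is the
z-score across all guides in the comparison,

$$ z_i = \frac{x_i - \overline{x}}{\mathrm{SD}(x)}, $$

and the per-gene *CRISPR fitness score* is the median of the $z_i$ of the
guides targeting the gene. The median over ~10 guides is robust to
individual inefficient or off-target guides, which is why screen pipelines
prefer it to the mean.

Conventions this package fixes (the formula itself does not):

* **SD denominator**: sample SD ($n-1$). With it, `zscore_transform(c(2, 4, 6))`
  is exactly `c(-1, 0, 1)`; a zero-variance input returns zeros with a
  `degenerate` attribute rather than `NaN`.
* **Treatment-vs-control contrast**: "treatment vs control" can mean a
  direct T24~treatment~ vs T24~control~ comparison or a
  difference-of-differences. The default is the per-guide difference
  $\Delta_i = \mathrm{log2FC}_i(\text{treatment T24/T0}) -
  \mathrm{log2FC}_i(\text{control T24/T0})$, z-scored across all guides:
  the subtraction cancels arm-independent fitness effects (essential genes
  drop out of $\Delta$), isolating drug-dependent selection.
  `score_screen(..., contrast = "t24")` exposes the direct comparison.
* **Replicates** are compared pairwise by replicate index
  (T24 rep *k* vs T0 rep *k*) and the per-guide log2FCs averaged, which
  keeps replicate-level variation visible to QC instead of pooling counts.
* **Pseudocount** 1.0 on normalized counts; with typical per-guide depth of
  several hundred reads its bias is negligible, while it keeps
  fully-depleted guides finite.
* **NTC centering** (subtracting the median NTC z) is available but off by
  default: the z-transform already centers on the bulk of guides, and with
  100 NTCs the extra centering mostly adds sampling noise.

Normalization defaults to the median-of-ratios estimator (size factor =
median over all-positive guides of count / geometric mean across samples),
which is robust to the strong asymmetric depletion a selection screen
produces; total-count normalization is available, and is the automatic
fallback when fewer than 100 guides are positive everywhere (a warning is
raised — size-factor medians over fewer guides are unstable). By the
median-of-ratios construction the size factors of a doubled column are in
ratio 1:2 with geometric mean 1, and the normalized columns coincide.

# Quality control

* `roc_essentiality()` ranks genes by a score (more negative = more
  depleted, stated explicitly, never inferred) and computes the ROC-AUC of
  reference core-essential genes against nonessential genes via the
  rank-sum (Mann–Whitney) identity with midrank tie handling — so the AUC
  is exactly the fraction of (essential, nonessential) pairs ordered
  correctly, with half credit for ties. Reference lists load from plain
  text (`read_gene_list()`); the package ships small *synthetic* stand-ins
  under `inst/extdata/` — real screens should substitute published sets
  (e.g. the ~1580-gene core-essential list).
* `replicate_correlation()` reports Pearson r of log2(normalized + 1)
  within each condition; `condition_correlation()` compares gene-level
  log2FC between arms (essential genes make this strongly positive).
* `coverage_report()` does the screen-design arithmetic: cells =
  guides × fold coverage (40,820 × 600 ≈ 24 × 10⁶).

# Hit calling

`ntc_null()` resamples NTC guide z-scores into pseudo-genes of the
library's modal guide count and records their medians, yielding a null for
per-gene median z that inherits the screen's actual noise. `rank_hits()`
attaches the one-sided empirical p-value
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{null}})$
(never zero by construction) and calls hits at a configurable cutoff
(default 0.05).

`nine_square_classify()` trichotomizes the two per-arm selection scores at
±threshold. The default threshold is 1.0 on the z scale — roughly the
2.5% tail of the per-gene median null — and is a declared convention, not
an estimate; boundaries are closed (|score| = threshold is "strong") so
classification is deterministic. The orange cell (weak control, strong
negative treatment) flags synthetic-lethal/resensitizer candidates; green
(weak control, strong positive treatment) flags resistance enhancers.

# Accessibility–expression concordance

The companion analysis asks whether differentially expressed (DE) genes
show matching chromatin changes. All interval logic is 0-based half-open
(BED convention; abutting intervals do not overlap) and is delegated to
GenomicRanges behind the module's interface.

* `classify_peaks()` labels peaks gained/lost/retained at
  |log2FC| > threshold (0.5 or 1.0 conventionally) and p < 0.05. Raw
  p-values are the default, mirroring common differential-accessibility
  practice; Benjamini–Hochberg is available via `adjust = "BH"`.
* `assign_peaks_to_genes()` uses a strand-aware promoter window (default
  2000 bp upstream / 500 bp downstream of the TSS — a declared convention,
  as annotation-based pipelines rarely publish their window) plus an
  optional enhancer–gene link table; the `source` column preserves
  promoter vs link provenance.
* `concordance()` counts DE-up genes with a gained assigned peak and
  DE-down genes with a lost one. Because "fraction concordant" is
  ambiguous about its denominator, both are reported: over all DE genes
  and over DE genes with at least one assigned peak.
* `tss_profile()` averages a binned signal track over TSS-centred windows,
  flipping minus-strand genes (their window is shifted one base so the TSS
  lands in the mirror-image bin). Bin values are coverage-weighted means
  over covered bases, uncovered bins contribute 0, and genes with no
  coverage in the window are skipped with a count.

# The simulator

The generator reproduces the statistical structure the analysis assumes,
not the biology of any particular genome:

* **Library**: `n_genes × guides_per_gene + n_ntc` guides with distinct
  random spacers; the published composition (4072 genes × 10 + 100 NTC =
  40,820) is the documented reference point.
* **Growth model**: per-generation geometric selection. A knockout with
  selection coefficient $s$ changes expected frequency by $(1+s)^g$ over
  $g$ doublings, renormalized per sample. Defaults: $g = 12$ (a ~24-day
  culture at about one doubling every two days), three replicates per arm.
* **Counts**: negative binomial with mean depth × frequency and dispersion
  0.1 (typical of screen count data; 0 degrades to Poisson). Default depth
  is 500 reads per guide. Initial abundances are lognormal with
  $\sigma = 0.5$, a realistic cloning skew; the true T0 distribution of
  any particular library is not calibrated here — $\sigma$ is a free
  parameter.
* **Effect classes** are allocated by largest-remainder apportionment of
  the requested fractions (exact integer counts, remainder ties broken by
  class order), with gene identity randomized. Default selection
  coefficients: −0.3 per generation for core essentials (both arms) and
  resensitizers (treatment only), +0.3 for enhancers (treatment only) —
  strong but not saturating effects over 12 generations.
* **Reads**: each read is 5′ flank + spacer + 3′ flank truncated to the
  read length, with i.i.d. substitution errors; read names carry the
  emitting guide as ground truth. The spacer counter anchors on
  `CACCG` — the terminal bases of the 5′ flank, ending at the vector G —
  which tolerates upstream stagger/trimming variation; its mismatch mode
  (0 or 1, via a precomputed Hamming-1 neighborhood with ambiguous
  variants discarded) is a declared convention, since published counting
  scripts rarely state theirs.
* **Omics tables**: one synthetic chromosome with genes every 100 kb; a
  rounded-target fraction of DE genes receives a concordant significant
  peak (promoter or linked enhancer, 50/50), the rest receive discordant
  or sub-threshold peaks or none, and surplus peaks land in gene deserts.
  The recovered concordance fraction therefore equals the target to within
  half a gene — the generator validates the analysis path, it does not
  model peak-calling noise.

What passing tests on these simulations shows: the pipeline recovers
planted selection structure of realistic magnitude at realistic depth,
and its arithmetic agrees with independent brute-force recomputation.
What it does not show: robustness to PCR amplification bias, guide-efficacy
heterogeneity, clonal interference, batch effects or peak-calling
artefacts, none of which the v1 generator models.

# Problem sizes and numerical choices

The shipped tests exercise parameter recovery at 500 genes × 10 guides
(+100 NTCs) at 500× depth; rank-1 recovery of a single strong
resensitizer ($s = -0.5$) across 100 seeded replicates on 100-gene
screens; null calibration on an all-neutral 10,000-gene screen; and
concordance recovery on 2000-gene omics bundles. These sizes were chosen
as the smallest at which the planted effects are comfortably detectable,
keeping the suite quick while preserving the screen's replicate and depth
structure.

Determinism: every stochastic operation takes an explicit seed and routes
all randomness through it, so identical inputs reproduce outputs
byte-for-byte. Degenerate inputs (zero variance, empty tables, all-zero
counts, too-few NTCs) raise informative errors or flagged zero results
rather than propagating `NaN`.

# Limitations

Beta-score estimation (MAGeCK-MLE style), RRA p-values, guide-efficiency
weighting, peak calling and differential testing of counts are out of
scope: the package consumes per-peak statistics and produces median-z
selection scores, which the nine-square and hit-ranking steps treat
generically. Empirical p-values are bounded below by 1/(1 + n_null), so
very small p requires a large NTC resample.
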