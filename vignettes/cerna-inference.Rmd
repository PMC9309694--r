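---
title: "Inferring lncRNA-miRNA-mRNA ceRNA networks from two-group RNA-seq counts"
author: "spongenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-miRNA-mRNA ceRNA networks from two-group RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongenet)
```

# The model

Competing endogenous RNAs (ceRNAs) are transcripts that share miRNA response
elements: a long non-coding RNA (lncRNA) that binds ("sponges") a miRNA
relieves the repression of that miRNA's mRNA targets. In a two-condition
experiment — here modeled on a geriatric-rat corpus-cavernosum design
comparing age-related erectile dysfunction (A-ED) animals against negative
controls (NC) — the ceRNA hypothesis predicts a characteristic signature
among differentially expressed transcripts:

1. a sponged miRNA is **negatively co-expressed** with both the lncRNA and
   the mRNA (screened by Spearman rank correlation, SCC < 0, strict);
2. the lncRNA and the mRNA are **positively co-expressed** (Pearson
   correlation, PCC > 0.5, strict), provided they share at least one
   screened miRNA;
3. the two transcripts share **more predicted sponge miRNAs than chance**:
   with $N$ universe miRNAs, $K$ targeting the lncRNA, $n$ targeting the
   mRNA and $x$ shared, the sponge p-value is the hypergeometric upper tail

   $$p = P[X \ge x] = \sum_{i=x}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

   retained when $p < 0.05$ on the raw p-value.

All retained pairs and their shared miRNAs are combined into a tripartite
lncRNA-miRNA-mRNA graph whose nodes carry the RNA class and regulation
direction, exportable to Cytoscape formats (SIF, GraphML).

Upstream of the screens, each RNA class is tested for differential
expression between the groups with a negative-binomial (NB) exact
conditional test (below), and only differentially expressed features enter
the network stage — the screening rules are conditional on the DE filter by
construction.

# Differential expression

Counts are modeled as NB with the RNA-seq variance convention
$\mathrm{var} = \mu + \phi\mu^2$. The test proceeds per feature:

* **Normalization.** Trimmed-mean-of-M-values (TMM) scaling factors: the
  reference sample is the one whose 75th CPM percentile is closest to the
  mean of those percentiles; each sample's factor is the precision-weighted
  mean of log2 count ratios against the reference after trimming the 30%
  tails of the M-values and the 5% tails of the A-values; factors are
  renormalized to geometric mean 1. Counts are then scaled to a common
  (geometric-mean) effective library size and rounded to pseudo-counts.
* **Dispersion.** A single common $\hat\phi$ per matrix, by method of
  moments pooled over all features and both groups (ratio of summed excess
  variances to summed squared means), floored at $10^{-8}$. With thousands
  of features and moderate sample sizes the pooled estimator recovers the
  generating dispersion closely; the package's null simulations estimate
  $\hat\phi \approx 0.098$–$0.099$ at a true 0.1.
* **Exact conditional test.** Group sums of pseudo-counts are NB with sizes
  $n_g/\hat\phi$; conditional on their total the group-A sum follows a
  negative hypergeometric (beta-binomial) law that is free of the unknown
  mean under the null. The two-sided p doubles the smaller tail and counts
  the observed outcome once, capped at 1. We deliberately count the
  observed point once rather than twice: double-counting makes the null
  distribution of p visibly conservative (its CDF at 0.5 drops to about
  0.48 on a 10,000-feature null), which a Kolmogorov–Smirnov uniformity
  check rejects, whereas the once-counted form is calibrated.
* **Effect size.** log2 fold change (A-ED over NC) of normalized group
  means with a pseudocount of 0.5, so zero-containing features stay
  finite. BH FDR is reported within each RNA class.

Features pass the DE filter when $|\mathrm{log2FC}|$ strictly exceeds the
class threshold (default 2 for miRNA/mRNA; 1 — i.e. fold change 2 — for
lncRNAs) and raw $p < 0.05$, both strict. The filter uses the raw p, as
selection criteria of this kind conventionally state, but the FDR is always
carried along (it is the volcano-plot ordinate). A separate candidate
window for qPCR validation keeps lncRNAs whose mean raw count across all
samples lies strictly in (1, 120) — a lowly-to-moderately expressed band in
which qPCR verification is practical — with fold change > 2 and $p < 0.05$.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lfc_mir`, `lfc_mrna` | 2 | strict \|log2FC\| threshold for miRNA/mRNA DE |
| `lfc_lnc` | 1 | strict \|log2FC\| threshold for lncRNA DE (fold change 2) |
| `p_threshold` | 0.05 | strict raw-p DE threshold |
| `scc_max` | 0 | strict SCC upper bound for miRNA-target screening |
| `pcc_min` | 0.5 | strict PCC lower bound for lncRNA-mRNA screening |
| `sponge_alpha` | 0.05 | strict threshold on the raw sponge p |
| `universe` | `"de_table"` | miRNA universe $N$ for the sponge test |
| `adjust_sponge` | `FALSE` | BH-adjust sponge p before retention |

Design choices where the procedure was genuinely open:

* **Sponge-test tail.** The cumulative test is read as the
  over-representation (upper) tail: the procedure looks for significantly
  *many* shared sponges; the lower tail would reward disjoint target sets.
* **Universe.** $N$ defaults to the differentially expressed miRNAs that
  appear in the (DE-restricted) target table, since every network RNA is
  differentially expressed by construction; `"de_screened"` (only miRNAs
  surviving the SCC screen) and `"all_de"` are available.
* **$K$ and $n$ counting.** Counted after the SCC screen — a predicted
  target only counts as a sponge when it is anti-correlated — matching the
  ordering of the three rules; the pre-screen variant can be obtained by
  passing the unscreened table to `sponge_test_pairs()`.
* **Correlation scale and pooling.** Correlations are computed on
  `log2(CPM + 1)` across all samples of both groups pooled: the group-mean
  difference is precisely the signal ceRNA co-expression exploits, and
  per-group correlations are underpowered at small n. CPM values use
  effective library sizes from the *full* matrices — column sums of a
  DE-only submatrix would absorb the group signal the screens look for.
* **Ties and degenerate vectors.** Spearman uses mid-ranks; constant
  vectors make a correlation undefined, and such pairs fail the screen
  rather than erroring the run.
* **No multiple-testing correction on the sponge p** by default (the
  retention rule is stated on raw p); BH is available via `adjust_sponge`.
* **Direction annotation.** Regulation direction (up/down) is annotated on
  every node but not enforced to be homogeneous: the method itself does not
  forbid mixed-direction networks.

# The raw-read filter

`filter_reads()` keeps a read iff it contains no adapter as an exact
substring, at most 10% unknown bases (N), and at most 50% low-quality
(Phred Q ≤ 20) bases. Boundary values are kept — the criteria are strict
"more than" rules — and Q = 20 itself counts as low quality. Failures are
attributed to the first failing rule in that order. Adapters are matched as
exact substrings against a user-supplied list because no mismatch-tolerant
trimmer is part of the procedure; reads are kept or dropped whole.

# Phenotype and qPCR arithmetic

Animals are grouped by the erectile-function readout ICP/MAP
(intracavernous over mean arterial pressure): strictly below 0.35 is A-ED,
strictly above is NC, and the exact boundary is flagged unassigned since
both groups are defined with strict inequalities. qPCR fold changes follow
$2^{-\Delta\Delta C_t}$ with replicates averaged on the Ct scale and
normalization against a reference gene (β-actin), which cancels per-sample
offsets. Two-group comparisons use a Welch t-test (unequal variances — the
safer default when homoscedasticity is unstated) or a Mann-Whitney test,
exact up to a combined n of 20 without ties; `auto` mode screens both
groups with Shapiro-Wilk at α = 0.05.

# The synthetic-data generator

`sim_config()` / `simulate_*()` emulate the two-group rat study design with
a planted, fully known truth so that every stage is testable without any
download:

* NB counts with $\mathrm{var} = \mu + \phi\mu^2$, per-feature baseline
  means log-uniform on [5, 500] (a moderately expressed band where the
  candidate-window and screening arithmetic is exercised), per-sample
  library-size multipliers log-uniform on [0.5, 2] so the normalization
  code has real work to do.
* Planted ceRNA triplets: an up-regulated lncRNA and mRNA (fold change 6)
  sharing 3 sponge miRNAs each down-regulated by 1/6 — miRNA repression is
  simulated marginally (opposite group fold change), which suffices to
  create the correlation structure the screens test for; no kinetic model
  is implied. Three sponges per pair reflects that validated ceRNA pairs
  typically share several miRNA response elements, and a design-time power
  analysis of the hypergeometric tail shows a single shared miRNA is only
  marginally detectable at the default universe size.
* A target table containing every planted relation plus background
  (miRNA, feature) pairs at density 0.05 with 1–3 pseudo-tool votes,
  emulating the union of several prediction tools.
* Gene sets, ICP/MAP phenotype records (7 below / 15 above the threshold,
  a realistic geriatric cohort split), qPCR plates with a closed-form
  truth, and FASTQ reads with planted per-rule QC failures, each violating
  exactly one rule so per-rule failure counts are exact.
* One global seed; each sub-generator draws from `seed + fixed offset`, so
  fixtures are individually reproducible and byte-identical across runs.

Default feature counts are 220 lncRNAs, 360 miRNAs and 1,520 mRNAs with 20
planted triplets — 2,000 decoy features in total, split roughly in the
proportions the three classes have in a transcriptome annotation.

What the generator does *not* emulate: real annotation structure,
sequence-derived target predictions, correlated (batch) noise, and
heavy-tailed per-feature dispersions. Passing the planted-recovery suite
therefore demonstrates that the implementation of the rules is correct and
well calibrated, not that the three-rule procedure is biologically valid on
any particular real data set.

# Problem sizes and runtime choices

The test and acceptance runs use 10 samples per group, 2,060 features per
simulated study (20 recovery seeds), 10,000 features for null calibration
(5 seeds), and 1,000 reads for the filter fixture — sizes at which the
exact conditional test's per-feature enumeration (a vector of length equal
to the feature's total pseudo-count) completes in a few seconds per run.
The hypergeometric tail is evaluated on the log scale with `lchoose`, so
universes of hundreds of miRNAs or gene-set universes of tens of thousands
of genes are unproblematic.

# Known limitations

* The common-dispersion NB test has no tagwise/trended dispersion and no
  GLM designs beyond two groups; strongly feature-specific overdispersion
  will make its p-values anti-conservative for the noisiest features.
* TMM assumes most features are not differentially expressed; with heavy
  one-sided composition shifts (e.g. many down-regulated miRNAs and none
  up), a small residual bias in the effective library sizes survives the
  trimming and attenuates fold changes near the threshold.
* The pipeline screens marginal correlations only; conditional or
  partial-correlation ceRNA methods are out of scope.
* `p_sponge` is reported unadjusted by default; with many candidate pairs
  the expected number of false retentions is `0.05 × #pairs`.
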