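---
title: "Methods: signed co-expression networks, preservation, trajectories, and motif enrichment"
author: "coexnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed co-expression networks, preservation, trajectories, and motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
options(coexnet.quiet = TRUE)
```

`coexnet` is a workbench for weighted gene co-expression network analysis
(WGCNA) of case/control neural differentiation studies, together with the
downstream analyses such a study needs: module–trait association, module
preservation in independent data, genotype-specific differentiation
trajectories, gene-set over-representation, and promoter motif
enrichment. This vignette explains the models implemented, the parameters
that matter, the numerical conventions, and what the synthetic validation
data do and do not establish.

## Study design and traits

The default design has 36 samples: 12 neural progenitor samples, 15
resting neuron samples, and 9 depolarized neuron samples, split between
control subjects (including an embryonic stem cell line coded as an
additional control) and one patient with multiple clones. Three binary
traits code the biology: `differentiation` (1 for neurons),
`depolarization` (1 for KCl-treated samples), and `TSmutation` (1 for
patient-derived samples). `pair_id` links each progenitor to the neuron
differentiated from the same clone in the same experiment; those pairs
drive the paired differential-expression tests. Depolarized neurons are
never members of differentiation pairs.

## Preprocessing

Raw intensities are log2-transformed and quantile-normalized. The
normalizer maps each sample onto the mean of the sorted per-sample
distributions; tied values receive the *mean of the target values their
ranks span*, which is deterministic and symmetric. Note that
quantile normalization is exactly idempotent only on tie-free data: with
ties, the first pass changes the pooled distribution the second pass
would target. On continuous microarray intensities this is immaterial.

Features are kept when their detection P value is below 0.05 in at least
`ceiling(0.5 × n_samples)` samples — "at least half", implemented with
`>=` so odd sample counts round up. Outlier samples are *flagged*, never
silently removed: each sample's mean inter-array correlation is
standardized across samples, and z < −2 flags a sample. A consequence of
standardization worth knowing: with *n* samples the most extreme z is
bounded by (n−1)/√n, so the −2 default can only trigger with roughly six
or more arrays — appropriate, since "outlier" is meaningless in tiny
batches. Constant samples are flagged separately (`zero_variance`).

## Network construction

The signed adjacency is `((1 + cor)/2)^β` with Pearson correlation over
pairwise-complete observations. β defaults to 12, the conventional choice
for signed networks satisfying approximate scale-free topology; a
`scale_free_fit()` sweep reports the signed R² of the log–log degree fit
per candidate power and recommends the smallest power reaching R² ≥ 0.8,
for data sets where the power should be re-derived. When the
configuration pins the power (the default), the sweep is bypassed.

Topological overlap follows the standard formula with unit diagonal.
Modules come from average-linkage clustering of `1 − TOM` with a *static*
cut at 99% of the maximum merge height, followed by two refinements:

1. **kME pruning and reassignment** (`reassign_by_kme()`): assigned genes
   whose own-module kME falls below 0.5 are demoted to grey, genes whose
   best kME exceeds their own-module kME by more than 0.1 are reassigned,
   and modules falling below the minimum size dissolve. The static cut
   alone is biased toward absorbing loosely attached background genes
   into modules (on the default synthetic scenario it costs roughly 0.4
   of adjusted Rand index); pruning is the deterministic analogue of the
   partitioning stage of hybrid dynamic tree cutting and restores
   recovery without any stochastic step.
2. **Eigengene merging**: modules whose eigengene dissimilarity
   `1 − cor(ME)` is below 0.25 are merged iteratively (each merged module
   takes the label of its largest member) until a fixed point.

Static cutting plus refinement is an intentional simplification of the
hybrid tree cutter: it is fully deterministic and each step is separately
testable. One boundary consequence: a data set that consists of a
*single* coherent module and nothing else has its dendrogram root inside
the module, so a relative cut below the root fragments it; in practice
any data set has background genes that push the root to the top of the
dissimilarity scale.

Module labels follow the conventional size-ranked color order (turquoise,
blue, brown, ...), so labels are comparable across runs in distribution,
though never gene-for-gene. "grey" is reserved for unassigned genes.

Eigengenes are the first right-singular vector of the per-gene
standardized module submatrix, sign-aligned so the eigengene correlates
positively with the module's mean standardized profile; for exactly
balanced modules (half the genes anti-correlated, mean profile zero) the
first usable gene decides orientation — an arbitrary but deterministic
convention. Constant genes are dropped from the SVD with a warning.
Hub genes are those with own-module kME above 0.6, capped at the top 200
(the smaller set wins), with kME ties broken lexicographically by feature
id so hub lists are reproducible.

## Module–trait association

Each module × trait pair is tested by OLS `ME ~ trait` with a two-sided t
test on the slope. Benjamini–Hochberg correction is applied *within each
trait across modules* (pooling across the full grid is available by
flag): the reported science is per-trait module rankings, so the per-trait
family is the natural unit. Binary trait recoding (0↔1) flips the
reported direction but leaves P and q untouched. No covariates are
fitted; nesting of clones within subjects is deliberately not modeled
(see Limitations).

## Module preservation

For each reference module the test set yields two density statistics
(mean within-module signed adjacency; mean within-module correlation) and
two connectivity statistics (correlation of intramodular-connectivity
ranks between data sets; correlation of the vectorized within-module
correlation matrices). Each is standardized against `n_perm = 200` random
gene sets of the same size drawn without replacement from the features
shared by both data sets; `Zdensity` and `Zconnectivity` are the medians
of their class and `Zsummary` their mean, with `Zsummary > 2` called
preserved.

Two design points deserve emphasis:

* **The permutation universe includes unassigned genes.** Restricting
  null draws to module-assigned genes makes the null itself
  module-structured — random sets then mix genes from strong modules and
  carry *more* apparent density/connectivity than a genuine single
  module, inverting the Z scores — and collapses entirely when only one
  module exists. Drawing from all shared features gives the intended
  "random gene set" null.
* **Degenerate nulls score zero.** When a statistic's permutation SD is
  zero and the observed value equals the null mean (e.g. `cor.kIM` is
  identically 1 when the test set *is* the reference set), the statistic
  carries no evidence and its Z is defined as 0 rather than NaN, leaving
  `Zsummary` to the informative statistics.

Modules with fewer than three genes in the feature intersection are
skipped with an explicit reason rather than scored.

## Differentiation trajectories

Per genotype, the paired test operates on per-pair differences (neuron −
progenitor) with empirical-Bayes moderated one-sample t statistics
(variances shrunk toward a scaled-χ² prior fitted by moment matching; the
moderated t is referenced to the augmented degrees of freedom). The
genotype × differentiation interaction is the two-sample moderated t
comparing control and patient per-pair differences — the paired-design
equivalent of the factorial interaction term, chosen because it uses
exactly the same experimental units as the per-group tests. A plain-t
fallback (`moderated = FALSE`) is provided for transparency.

Classification requires (1) significance in exactly one genotype and (2)
a significant interaction, both at raw P < 0.05; the significant
genotype's fold-change sign picks among `control_up`, `control_down`,
`ts_up`, `ts_down`. Raw (not FDR-adjusted) thresholds are intentional:
the classification is a screen whose output is itself validated by
enrichment analyses.

A structural property worth knowing when interpreting counts: the
interaction contrast shares the significant arm's paired differences, so
for a truly null gene the two criteria are positively correlated
(`corr ≈ 1/√2`). The null classification rate is therefore about 2.9% —
not the ≈0.5% that independence of the two criteria would suggest — for
any sample size. Simulated truth recovery shows ≥90% of genes with a
1.0 log2-unit genotype-specific differentiation effect (σ = 0.3, six
pairs per genotype) are correctly categorized.

## Enrichment

Fisher over-representation uses the one-sided (greater) hypergeometric
tail including the observed table, with the sample odds ratio
`(ad)/(bc)` and an `Inf` sentinel for complete containment. Queries and
annotations are intersected with the background — always the post-filter
expressed features — before testing, and BH q values are added across
annotation sets within one query. The permutation variant draws
query-sized random sets from the background and reports both the
over-representation Z and the empirical `P = (1 + #{null ≥ obs})/(1 +
n_perm)`, which cannot be zero by construction. ChIP validation of
predicted motif targets is the upper cumulative hypergeometric with the
expressed-gene count as population size. Annotation hierarchies (e.g.
ontology graphs) are deliberately not modeled: all collections are flat
GMT sets.

## Promoter motif enrichment

Promoters are the 1,000 bp upstream of each TSS (strand-aware,
reverse-complemented on the minus strand, truncated and flagged at contig
edges). PWMs (TRANSFAC-dialect or JASPAR files; real-valued counts and
missing terminators tolerated) get a pseudocount of 0.25 per cell before
normalization so no site scores −∞.

The set score of a promoter set is the mean over sequences of
`log( mean over positions and strands of the likelihood ratio
PWM/background )`. A background-equal motif scores exactly 0; planting
instances can only raise it. `N` bases contribute a neutral factor
(LR = 1) rather than being masked, keeping position counts comparable
across sequences. This log-average-likelihood-ratio score is a documented
simplification of the Clover-style raw score (which integrates over
subsequence subsets); it is exactly specifiable, strand-symmetric, and
monotone in planted signal, and all calibration machinery is identical.

Empirical significance compares the observed set score against 1,000
replicate sets of the same number and lengths of sequences drawn with
replacement from each of three background pools, with background base
frequencies estimated from the pool being used — observed and null scores
are always computed under the same background model. A motif is called
significant only at P < 0.05 in *all three* backgrounds; the conjunction
is strictly more conservative than any single background and guards
against composition artifacts. When pool sequences are longer than
required, random windows are cut; when they match exactly, per-sequence
scores are computed once and draws sample them, which makes the null
exact and fast.

Predicted targets are genes whose promoter carries at least one site, on
either strand, scoring at least 90% of the PWM's maximal attainable
log-likelihood-ratio site score. The 90% default is a package decision
(no canonical threshold exists for calling "at least one site"); it is
configurable and recorded in output metadata.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. Its model is
the minimal generative process consistent with eigengene summarization: a
module's latent factor is a linear combination of the binary traits plus
`N(0, 0.3)` sample noise; a member gene is `λ · factor + N(0, σ)` on the
log2 scale with loadings λ ~ U(0.6, 0.95) and σ = 0.25 by default, on top
of a per-gene baseline ~ U(7, 11). The default scenario plants five
modules (sizes 200, 150, 120, 100, 50): differentiation-up,
differentiation-down, depolarization, mutation, and one trait-null module
whose co-expression is purely latent. Trajectory-category genes receive
genotype-specific differentiation shifts of 1.0 log2 units at σ = 0.3 —
the effect size at which the three-way classification rule (own arm, not
other arm, interaction) retains ≥90% joint power at six pairs per
genotype; smaller published-style effects (~0.8) leave the conjunction
under-powered regardless of implementation. Detection P values pass the
expression filter by construction for expressed features, and planted
low-detection features miss the threshold by exactly one sample, making
filter tests exact.

Promoter simulation draws background sequence from given base
frequencies and inserts PWM-sampled instances at non-overlapping uniform
positions on a random strand. Three synthetic background pools (uniform,
GC-rich, mixed) stand in for genome-scale backgrounds so the
three-background conjunction rule is testable without downloads; real
backgrounds are user-supplied FASTA.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: bead-level noise, batch and
hybridization effects, probe cross-reactivity, correlated backgrounds
(noise genes are independent), heavy-tailed expression distributions,
dinucleotide structure and repeats in promoters, and realistic
intra-subject correlation between clones. Results on real studies depend
on those factors; the synthetic harness establishes correctness of the
computations, and calibration of their nulls, under the model stated
above.

## Problem sizes and runtime choices

The validation suite runs the full recovery harness at 3,220 features ×
36 samples over ten seeds, preservation at 500 features with 200
permutations over 20 seeds, trajectory calibration on 2,200 features ×
24 samples over three seeds, exhaustive Fisher checks over every 2×2
table with margins ≤ 60, and motif calibration over 50 seeded runs —
sizes chosen so the whole suite completes in a few minutes on one CPU
while leaving every statistical check enough resolution to fail loudly
if a formula or null is wrong. The pipeline itself handles the dense-TOM
regime (up to ~5,000 features comfortably); block-wise processing for
very large feature sets is out of scope.

## Known limitations

* Dynamic hybrid tree cutting is approximated (static cut + kME
  refinement); partitions agree with planted truth but will not match a
  hybrid cutter gene-for-gene on real data.
* Subject/clone nesting is not modeled in trait association or DE; with
  few subjects, trait P values understate subject-level uncertainty.
* The interaction test's correlation with the per-arm tests puts a ~3%
  floor on the null trajectory-classification rate at α = 0.05 (see
  above); treat category counts as a screen.
* Dense TOM memory is quadratic in features; collapse probes
  (`collapse_probes()`) or pre-filter before network construction.
* Motif scanning assumes independent positions (PWM model) and uniform
  or pool-estimated zero-order backgrounds; no dinucleotide-preserving
  shuffles.
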