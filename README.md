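# coexnet

Signed weighted gene co-expression network analysis for case/control
neural differentiation studies — module detection, module–trait
association, permutation module preservation, differentiation-trajectory
classification, gene-set over-representation, and promoter motif
enrichment — with a ground-truth synthetic-data generator that emulates
the full study design so every stage is testable end to end.

## The scientific problem

Bulk expression studies of iPSC-derived neural cells typically profile a
few dozen samples spanning cell type (progenitor vs. neuron), stimulation
(resting vs. KCl-depolarized), and genotype (patient vs. control). Rather
than testing genes one at a time, weighted gene co-expression network
analysis (WGCNA) groups genes into modules of shared expression patterns
and asks which modules track each biological trait, whether they
replicate in independent data, and which transcription factors plausibly
co-regulate them. `coexnet` implements that entire workflow for exactly
this three-trait design (differentiation, depolarization, disease
mutation), including the downstream tests a disease study needs:
genotype-specific differentiation trajectories and calcium-dependent
transcription-factor binding-site enrichment in module promoters.

## The model

**Network.** For genes *i*, *j* with Pearson correlation
*cor(x_i, x_j)* across samples, the signed adjacency is

    a_ij = ((1 + cor(x_i, x_j)) / 2) ^ β,     β = 12 by default,

so anti-correlated genes receive near-zero weight. Genes are clustered by
average-linkage hierarchical clustering on `1 − TOM`, where the
topological overlap

    TOM_ij = ( Σ_{u≠i,j} a_iu a_uj + a_ij ) / ( min(k_i, k_j) + 1 − a_ij )

rewards shared neighborhoods. Branches are cut at a static height, small
clusters go to the unassigned "grey" pool (minimum module size 40), weak
members (own-module kME < 0.5) are pruned, and modules whose eigengenes
are less than 25% dissimilar are merged.

**Module summaries.** Each module is summarized by its eigengene (ME, the
first principal component of the standardized module expression) and each
gene by kME = cor(gene, ME). Module–trait association is ordinary least
squares `ME ~ trait` with Benjamini–Hochberg FDR across modules within
each trait.

**Preservation.** A module's density (mean within-module adjacency and
correlation) and connectivity (cross-dataset correlation of intramodular
connectivity ranks and of correlation structure) in a second dataset are
standardized against 200 random same-sized gene sets:
`Zsummary = (Zdensity + Zconnectivity)/2`, preserved if `Zsummary > 2`.

**Trajectories.** Differentiation effects are tested per genotype with
moderated paired t-tests (empirical-Bayes variance shrinkage), the
genotype × differentiation interaction with a moderated two-sample t on
the paired differences. A gene is classified `control_up`,
`control_down`, `ts_up`, or `ts_down` only when it is significant in
exactly one genotype *and* the interaction is significant (P < 0.05).

**Enrichment.** Gene-set over-representation uses the one-sided Fisher /
hypergeometric tail and a 10,000-permutation over-representation Z
against the expressed-gene background. Promoter motif enrichment scores a
module's 1,000-bp promoters with a PWM log-average-likelihood-ratio set
score and compares it with 1,000 draws of length-matched sequence sets
from each of three background pools; a motif is called only at P < 0.05
in all three backgrounds. Predicted targets are validated against ChIP
gene lists with the cumulative hypergeometric test.

## Worked example

```r
library(coexnet)
options(coexnet.quiet = TRUE)

sim <- generate_expression(n_background = 1000, seed = 42)  # 36 samples
net <- detect_modules(sim$log2, beta = 12, min_module_size = 40)
table(net$partition)
#>      blue     brown     green      grey turquoise    yellow
#>       152       120        45      1002       199       102

adjusted_rand_index(sim$truth$module[names(net$partition)], net$partition)
#> 0.983

assoc <- associate_modules(net$eigengenes, sim$truth$traits)
subset(assoc, significant)
#>       module           trait  slope r_squared        p        q direction
#>    turquoise differentiation  0.207     0.342 1.81e-04 4.52e-04        up
#>         blue differentiation -0.279     0.621 1.16e-08 5.78e-08      down
#>        brown  depolarization  0.278     0.520 6.98e-07 3.49e-06        up
#>       yellow      TSmutation  0.280     0.688 4.07e-10 2.04e-09        up
```

The generator planted five modules (four trait-linked, one trait-null)
among 1,000 noise genes; the network recovers the partition almost
exactly (adjusted Rand index 0.983), the four trait-linked modules are
flagged at FDR < 0.05 for their planted traits with the planted signs,
and the trait-null module (green) is detected as a module but associated
with nothing — exactly the behavior a real study relies on.

The full composition — simulation through preprocessing, network, trait
association, preservation, differential expression, enrichment, and
TFBS — is available as `run_pipeline()` in R or through the bundled CLI:

```sh
Rscript inst/cli/coexnet.R run-all --seed 1 --out-dir ws
```

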