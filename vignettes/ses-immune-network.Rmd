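---
title: "From a socioeconomic exposure to a layered regulatory network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a socioeconomic exposure to a layered regulatory network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sesnet)
```

## The scientific problem

Socioeconomic status (SES) predicts a broad range of immune-related
diseases, and bulk blood transcriptomes show SES-associated expression
differences. A gene-by-gene view understates the biology: transcription
factors (TFs) and their protein partners can reshape expression programs
without being differentially expressed themselves. `sesnet` implements an
inference chain that starts from a count matrix and a continuous SES
composite (a sum of standardized education, income, occupation and
subjective-status indicators) and ends with a layered network of
differentially expressed (DE) genes, upstream TFs, and protein neighbors,
together with mediation estimates for behavioral risk factors and a
randomization assessment of set-level specificity.

The chain has eight stages:

1. low-count filtering, TMM normalization, log-CPM, empirical-Bayes batch
   adjustment;
2. per-gene covariate-adjusted linear models for the SES composite, with
   Benjamini–Hochberg (BH) false discovery control ("up" = positive
   association between SES and expression);
3. whole-genome co-expression modules, eigengene–SES association, and
   Fisher-exact module enrichment for SES-associated genes;
4. hypergeometric over-representation analysis (ORA) against a
   hierarchical pathway ontology, with parent–child pooling and combined
   multi-list enrichment;
5. the four regulator sets — Set A (DE genes at FDR < α), Set B (DE TFs
   acting as a source with a regulatory edge of confidence > 0.4), Set C
   (protein partners of Set B at interaction score > 0.7), Set D (TFs with
   a > 0.4-confidence edge onto a Set A gene);
6. relevance layers by enriched-pathway contribution counts (> 10
   pathways = layer 1 innermost; exactly 1 = layer 4 outermost);
7. counterfactual mediation of the SES–expression association (ACME /
   total effect) per gene and mediator, summarized per layer by medians;
8. a randomization test: 1000 random gene sets matched in size to Set A,
   re-derivation of Sets B/C/D per replicate, per-gene empirical p-values
   with add-one smoothing, combined per set by Fisher's method.

Both network thresholds are strict inequalities: a score of exactly 0.4
(regulatory) or 0.7 (protein interaction) does not qualify.

## What the synthetic-data module emulates

Cohort-scale transcriptomic studies with SES exposures are restricted-use,
and the external regulatory, protein-interaction and pathway resources are
versioned databases. The generators therefore produce a self-contained
study with *planted, recoverable ground truth*:

* **Cohort** (`generate_cohort`): a standardized continuous SES composite
  and mediators tied to it through a Gaussian one-factor copula. The
  default SES–BMI latent correlation is −0.3, a mid-range value for the
  well-documented inverse SES–adiposity gradient in high-income adult
  populations; stress, smoking and financial strain are negatively,
  insurance access positively correlated with SES. Covariates (sex, race,
  age 33–43, pregnancy, plate, fasting time, medication, recent illness)
  are drawn independently.
* **Counts** (`generate_counts`): negative-binomial counts — the standard
  RNA-seq noise model, with log-normal gene dispersions centered near 0.1
  and log-normal library factors. A DE gene's log2 mean response to SES is
  split between a direct path and a path through BMI according to its
  planted mediated fraction `f`; because BMI is itself a linear function
  of SES plus noise, the mediated proportion ACME/total has closed-form
  truth `f`.
* **Networks** (`generate_networks`): true modulating TFs wired onto DE
  targets at confidence 0.9 among uniformly scored decoys; DE TFs receive
  outgoing regulatory edges and high-scoring protein partners so Sets B
  and C are recoverable.
* **Ontology** (`generate_ontology`): a forest of exactly three levels
  below the roots, leaves annotated with 5–20 genes, parents annotated
  with (a superset of) the union of their children.

What the generator does **not** emulate: realistic linkage or eQTL
structure, survey weights, missing data, cell-type composition shifts, or
the gene-gene correlation induced by shared pathways beyond the planted
modules. Passing recovery tests therefore demonstrates correctness of the
inference chain under its stated model, not robustness to everything real
cohort data can contain.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | FDR threshold for Set A, module calls, pathway significance |
| `tf_threshold` | 0.4 | strict lower bound on regulatory edge confidence |
| `ppi_threshold` | 0.7 | strict lower bound on protein interaction score |
| `layer_bin_edges` | 10, 5, 1 | layer bins: >10, 6–10, 2–5, =1 pathways |
| `trim_m`, `trim_a` | 0.30, 0.05 | TMM double trimming fractions |
| `prior_count` | 0.5 | log-CPM offset |
| `n_sim` | 1000 | quasi-Bayesian draws per mediation model |
| `n_replicates` | 1000 | randomization replicates |

Only the innermost (>10) and outermost (=1) layer definitions are fixed by
the method; the middle split at 5 is a package default exposed through
`layer_bin_edges`.

## Numerical and design choices

**TMM and log-CPM.** Factors come from the weighted trimmed mean of
M-values with inverse asymptotic binomial variance weights, the reference
chosen by the upper-quartile convention, and factors renormalized to
geometric mean 1 (computed via edgeR). log-CPM uses the explicit formula
`log2((count + 0.5) / (effective library + 1) * 1e6)`. Depth-scaling a
sample leaves all M/A values and trimming decisions unchanged; the
variance weights depend weakly on library size, so factors are equal only
to ~1e-2 under scaling, which the tests assert explicitly.

**Batch adjustment.** Parametric empirical-Bayes location–scale
adjustment (ComBat) preserving the exposure/covariate design, followed by
a per-gene re-centering that restores each gene's grand mean exactly.
EB-shrunk batch effects are divided by batch-specific scale factors, so
raw adjusted values preserve gene means only approximately; the
re-centering removes that drift without touching batch contrasts. Genes
with zero within-batch variance pass through unadjusted; a single batch is
the identity.

**Differential expression.** Plain OLS with unmoderated t-tests — the
model is a covariate-adjusted linear fit, not a moderated-variance
method; with thousands of samples per gene, moderation buys little.
Constant genes are reported with `beta = 0, p = 1` and flagged
`degenerate` (rather than dropped) so every downstream module sees the
same gene universe. A gene fitted perfectly by the design (zero residual,
nonzero variance) reports p = 0; degeneracy is reserved for genes with
essentially zero outcome variance.

**Module detection.** Unsigned adjacency `|cor|^power` (power chosen as
the smallest candidate whose signed scale-free fit reaches 0.8),
topological overlap dissimilarity, average-linkage clustering, and a
*static* cut. The default cut height is the midpoint of the largest gap
between consecutive dendrogram merge heights: with genuine module
structure, within-module merges sit well below between-module merges and
the gap is wide (≥ ~0.04 in our count simulations), whereas pure-noise
dendrograms show gaps around 1e-4. When no gap reaches `min_gap` (0.01)
the matrix is declared structureless and all genes stay unassigned. A
fixed quantile of the dissimilarity distribution was considered and
rejected: whenever within-module pairs exceed that quantile's mass the cut
lands inside the module merges and shatters them, and on pure noise
chained average-linkage merges below the cut produce one spurious giant
module. Eigengenes are first right-singular vectors of the
gene-standardized submatrix, unit variance, signed to correlate positively
with the module mean profile — a deterministic, platform-stable
convention.

**Enrichment.** One-sided hypergeometric ORA; Cramér's V from the
uncorrected chi-square of the 2×2 query-by-pathway table (equal to |phi|);
pathways with no annotated universe genes are skipped. Parent–child
pooling applies the "most significant child" rule across up to three
levels: a pooled ancestor takes the minimum descendant p and inherits that
descendant's q-value rather than receiving a fresh BH pass — child tests
under one parent are strongly dependent, and re-adjusting minima would
double-count them. Combined multi-list enrichment tests the union and
reports per-list contributions with genes shared between lists split
equally.

**Mediation.** Quasi-Bayesian approximation: model coefficients are drawn
from their asymptotic normal sampling distribution, and ACME / direct /
total effects are computed per draw (for binary mediators the change in
mediator probability is averaged over the observed covariate
distribution). Point estimates are draw means, intervals are percentile
intervals, and the two-sided Monte-Carlo p uses add-one smoothing so it is
strictly positive — necessary because layer summaries Fisher-combine these
p-values. Mediated proportions are winsorized to [−5, 5] before taking
medians to tame near-zero totals; negative medians indicate suppression
(indirect and direct paths of opposite sign). Ordered alcohol categories
enter as scores 0–3. No exposure–mediator interaction is fitted by
default. Constant mediators return an exact zero ACME.

**Randomization.** Replicates are seeded from the master seed by a
counter-based schedule, so any replicate can be reproduced in isolation.
The empirical p of a molecule is its add-one-smoothed appearance frequency
among null-derived sets — small values mean the molecule is rarely
recruited by chance. Note a structural property of this estimator: the
appearance frequency of a gene is a fixed quantity (its
chance-recruitment probability), so under a random "observed" set the
per-gene empirical p-values concentrate near that probability rather than
being uniform, and the Fisher combination is correspondingly
concentrated. The combination is meaningful as a comparison against the
planted/observed configuration, not as a uniformly calibrated test.

**Determinism.** Every stochastic stage takes a seed derived
deterministically from the single master seed; two runs from one seed are
bit-identical (asserted on output file checksums in the test suite, at
2000 genes × 500 samples × 100 TFs × 1000 replicates).

## Problem sizes used in the checks

The test suite and the acceptance script work at deliberately modest
scale chosen to exercise every code path with tight planted truth:
null calibration at 200 genes × 200 samples; effect recovery at 500
samples with effects 0.5–1.5 log2 units per SD of SES; module recovery on
three 50-gene blocks at noise SD 0.3; mediation truth at n = 2000 with
a = 0.5, b = 0.4, c′ = 0.3 (ACME 0.20, proportion 0.40); planted mediated
fraction 0.5 at n = 1000; exact-test oracles enumerated over all
contingency tables with totals up to 12; and the full pipeline at 2000
genes × 500 samples with 1000 randomization replicates.

## Known limitations

* The mediation estimand assumes sequential ignorability; no sensitivity
  analysis is provided, and with observational exposures the estimates are
  descriptive decompositions, not causal claims.
* Per-layer mediation summarizes gene-level models by medians; it does not
  fit a single structural model per layer.
* Whether Set D should exclude Set B members is left open in the method's
  description; the sets may overlap here and the overlap is reported.
* Cramér's V is computed on the 2×2 ORA table; other contingency layouts
  are possible readings.
* The randomization combination is specific to the appearance-frequency
  estimator (see above) and should be read comparatively.
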