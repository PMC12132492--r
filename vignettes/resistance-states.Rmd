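---
title: "Detecting resistance-associated transcriptional states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting resistance-associated transcriptional states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistsig)
```

## The problem

Early in drug exposure, a minority of tumor cells shifts into a
transcriptional state that lets them tolerate the drug — a state that may
pre-exist treatment or emerge under it, and that often recurs across cell
lines and even across species. `resistsig` provides the statistical chain
for finding such states in clustered single-cell expression data and for
asking whether the associated gene programs predict clinical outcome.
This vignette documents the models, the tunable parameters, the numerical
decisions, and what the accompanying synthetic data can and cannot
establish.

## Consensus signatures by robust rank aggregation

Per-dataset evidence arrives as ranked differential-expression lists.
`differential_expression()` uses a per-gene two-sided Wilcoxon rank-sum
test on log-normalized values — the distribution-free default for sparse,
zero-inflated single-cell counts — with the log2 fold-change computed on
de-logged group means plus a pseudocount of 1 (so genes absent from one
group have a finite, shrunken fold-change). Bonferroni adjustment over
tested genes is the default (matching the convention of single-cell
marker tests); BH is available. Sorting is descending log2FC with ties
broken by ascending p and then gene id, so the ranking is deterministic.

`rra_aggregate()` scores each gene in the union of lists by the RRA rho
statistic: with normalized ranks $r_{(1)} \le \dots \le r_{(k)}$ observed
in $k$ of $m$ lists,
$$\rho = \min_j \; P\{\mathrm{Binom}(m, r_{(j)}) \ge j\},$$
the probability that $j$ or more of $m$ uniform ranks fall at or below
$r_{(j)}$. A gene missing from a list contributes no rank but $m$ stays
the total list count, which is conservative for sporadically detected
genes. The spec term "adjusted rank p-value" is implemented in two
explicit stages: Bonferroni over the $m$ order statistics
($\min(\rho m, 1)$, the aggregation method's own correction) followed by
BH across genes; genes with adjusted rank p < 0.05 (strict) are retained.

**Rank normalization.** For complete lists, the normalized rank is
position / list length. When the inputs are pre-filtered fragments of a
longer ranking — e.g. only the significantly upregulated genes of a
transcriptome-wide differential expression, as in supercluster consensus
signatures — dividing by the fragment length erases exactly the signal
the filter selected: every retained gene looks uniform. The
`universe_size` argument therefore normalizes positions against the full
ranking the fragment came from (the partial-list convention of the RRA
method); `supercluster_signature()` passes the transcriptome size.

## Activity scoring and the control-set threshold

`aucell_score()` ranks each cell's genes by descending expression, ties
broken by a seeded random permutation (a deterministic alternative would
systematically favor genes early in the matrix). With
$R = \lceil 0.05 \, n_{\text{genes}} \rceil$, the recovery curve
$y(x)$ counts signature genes among the top $x$ ranks, and
$$\text{score} = \frac{\sum_{x=1}^{R} y(x)}{\sum_{x=1}^{R} \min(x, s')},
\qquad s' = \min(|sig|, R),$$
i.e. the step-curve area normalized by the ideal curve in which all
usable signature genes occupy the top ranks. The score is 1 exactly for
ideal placement, 0 when no signature gene enters the window, and is
invariant to any strictly monotone transform of a cell's values. The top
fraction (default 0.05) is the scoring method's documented default; it is
configurable and recorded in every result.

The activity threshold is a null model built from expression-matched
controls: expressed genes are binned into 10 equal-frequency bins by mean
normalized expression; one repeat draws, per signature gene, one random
gene from the same bin (signature members excluded; exhausted bins fall
back to the nearest bin with candidates, with a warning), scores all
cells on the control set, and stores the 95th percentile. The final
threshold is the maximum over 100 repeats — monotone in the number of
repeats by construction, and deterministic given the seed. Matching
controls on expression level matters because highly expressed genes are
mechanically likely to appear near the top of every cell's ranking; an
unmatched null would call far too many cells active.

`module_score()` reuses the same binned-control construction for
mean-difference scores (100 controls per signature gene by default), and
`assign_cell_cycle()` assigns each cell the argmax phase over module
scores for G0/G1/S/G2M signatures, with ties broken deterministically in
the fixed order G0, G1, S, G2M (arbitrary but recorded in the output).

## RAC calling

Within each cell line, every cluster is tested against all other clusters
of the same line on the 2×2 table of activity calls. The odds ratio is
the exact ratio of ratios; boundary tables report 0 or Inf as flagged
sentinels rather than continuity-corrected estimates, so downstream
filtering sees the truth of the table. Significance comes from the
two-sided Fisher exact test (the R convention: summing probabilities of
tables no more probable than observed), BH-adjusted across that line's
clusters — BH rather than Bonferroni because cluster tests within a line
are a small, positively dependent family and the published criterion is a
discovery threshold, not a family-wise guarantee. A RAC requires strictly
OR > 1 and adjusted p < 0.05. When metadata carries informative treated
flags, RACs are re-called on untreated cells alone (same thresholds): a
RAC also flagged there is `pre_existing`, otherwise `emergent`. The
threshold itself is computed on all cells of a line pooled
(treated + untreated), since the published procedure does not restrict
it; this is the more conservative choice because untreated cells dilute
the control distribution symmetrically.

## Superclusters

Per line, `variable_genes()` ranks genes by a standardized-variance
statistic: a loess trend (span 0.3, degree 2) of log10 variance on log10
mean predicts each gene's expected standard deviation; values are
standardized by it, clipped at $\sqrt{n_{\text{cells}}}$, and the
variance of the clipped values ranks the genes — the
variance-stabilizing feature selection standard in the field, and fully
deterministic. The shared gene set is the intersection of per-line top
lists (default 2000), sorted for determinism.

Each cluster's differential mean-expression vector (cluster mean minus
same-line complement mean over the shared genes) enters an all-by-all
Spearman correlation; hierarchical clustering with average linkage on
$1-\rho$ is cut at height 0.7. Average linkage is the common default for
grouping correlation profiles and is less prone than complete linkage to
splitting a true block on one noisy member; the cut height of 0.7
(correlation ≈ 0.3 within groups) was fixed once as a conservative
within-block correlation floor, and the full tree is returned in the
result so any other cut is reproducible. A group becomes a supercluster
when it contains RACs from at least `min_lines` distinct cell lines —
default 2, because requiring all lines (available via `min_lines = 3`)
makes the definition brittle to a single line failing QC; non-RAC
clusters shape the correlation structure but are never assigned.

## Enrichment, cross-species, clinical

Over-representation uses the exact hypergeometric upper tail with the
universe defaulting to all genes expressed in the relevant matrix (the
genes that could have been discovered), BH within one collection at a
time. Ortholog mapping is set-valued: one-to-many mappings contribute all
targets once, unmapped members are dropped and counted.

`ssgsea()` walks the sample's descending ranking accumulating
rank$^\alpha$ weights (α = 0.25) for set members against a uniform
non-member CDF; no across-sample rescaling is applied by default because
scores are compared only within one cohort at a time. `gsea()` is the
classic weighted Kolmogorov–Smirnov running sum (weight |log2FC|) with a
gene-label permutation null — the null used by preranked enrichment
tools — NES = ES / mean(|ES of same-sign permutations|), and a +1
pseudo-count tail p. `cox_fit()` wraps the partial-likelihood fit with
Efron tie handling (the default of the survival machinery the field
uses); samples missing a covariate are dropped listwise with the count
reported, and coefficient magnitudes above 15 are treated as monotone
likelihood and raised as errors rather than reported. Median splits send
exact-median samples to the low group (deterministic; sizes reported).

## The synthetic-data generators

`simulate_cell_lines()` draws negative-binomial counts (dispersion 0.3,
log-normal baseline means, meanlog −0.5, sdlog 1 — library sizes and
detected-gene counts in the range typical of droplet data) over
pre-assigned clusters, multiplies the means of each planted program's
genes by `fold` in one designated cluster per line per program, and
concentrates a target drug class in each program's active clusters
(≈ 90% of treated cells there, 2% leakage elsewhere, i.e. ≥ 80% of the
class's cells in active clusters). Defaults — 3 lines × 8 clusters × 200
cells, 2000 genes, two 100-gene programs at fold 4 — are the study-scale
conditions exercised by the acceptance suite. `simulate_ranked_lists()`
permutes a shared universe with consensus genes placed uniformly in the
top fraction of every list; `simulate_survival_cohort()` gives each
sample a latent activity $a_s \sim N(0,1)$ that shifts signature-gene
expression and scales the exponential hazard by $e^{\beta a_s}$, with
independent exponential censoring whose rate is solved to match the
requested censored fraction, and covariates generated independently of
the hazard.

What the generators deliberately omit: batch effects, library-size
gradients, doublets, ambient RNA, correlated gene-gene noise beyond the
planted programs, and non-proportional hazards. Passing tests on this
data therefore demonstrates that the statistical machinery recovers
planted structure under clean, assumption-satisfying noise — not that it
is robust to the artifacts of real data, which enter through the QC and
normalization stages but are not adversarially simulated.

## Numerical and degenerate-input conventions

* Filters use the stated strict/inclusive bounds exactly: features in
  `[min, max]` inclusive; "detected" means count > 0; signature filters
  are strict (`log2FC > 0`, `p_adj < 0.05`).
* Zero-total cells are an error naming the cell; all-zero genes survive
  normalization as all-zero rows and are excluded from expression bins.
* Genes with identical values across both DE groups get p = 1.
* Empty QC results, empty rank-aggregation universes, constant
  correlation vectors, all-censored survival draws (after 10 retries) and
  perfect separation in Cox fits are errors, not silent empties; empty
  consensus signatures are returned with a warning because a legitimate
  direction (e.g. "down" on an upregulated program) can be empty.
* All randomized procedures (rank tie-breaks, control draws,
  permutations) take explicit seeds; `run_pipeline()` expands one global
  seed into fixed per-stage seeds so stages are independently
  reproducible, and identical configs yield byte-identical tables.

## Problem sizes used by the test suite

Unit tests run reduced fixtures (3 lines × 4 clusters × 80 cells, 600
genes, 40-gene programs) chosen so the full suite completes in well under
a minute while keeping every planted contrast far from its decision
boundary. The acceptance suite runs the full study-scale generator
defaults over 20 seeds for RAC recovery, a 10^6-draw Monte-Carlo oracle
for the rank-aggregation statistic, and 20–50 seed replications for the
clinical calibrations.

## Known limitations

Cluster labels are an input: the package neither clusters cells nor
checks that the labels are sensible. The RRA implementation targets the
m ≤ ~10 lists regime of this analysis; for very many lists the exact
binomial tail is still correct but the Bonferroni-over-order-statistics
correction grows conservative. The GSEA null permutes genes, not
phenotypes, so inter-gene correlation inflates its significance on real
data exactly as it does for the tools it mirrors. Supercluster calls
depend on the tree cut; the emitted dendrogram record should be consulted
whenever group boundaries matter.
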