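---
title: "Inferring pathway-interaction networks from expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pathway-interaction networks from expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panar)
```

## The problem

Enrichment-style pathway analysis treats gene sets as isolated boxes and
assumes all member genes contribute equally to pathway activity.  Neither
assumption holds in real regulatory systems: pathway activity is often
controlled by a handful of rate-limiting genes, and pathways interact —
through shared components, regulatory factors, or metabolic intermediates
that are not themselves pathway members.  `panar` addresses both points.
It summarizes each pathway by the dominant covariation patterns of its
genes ("pathway profiles"), links profiles across pathways with
association rules learned from their discretized activity states, and
reports which genes drive each profile.

## The model

### Phase 1 — pathway compression

Let $\mathbf{X}$ be the $N \times M$ expression matrix (genes by samples)
and $F$ a pathway annotation.  For each pathway $f$ with $N_f$ measured
genes, the submatrix $\mathbf{X}_f$ is transposed and column-mean
centered to $\mathbf{X}_f^c$, and decomposed by PCA:
$\mathbf{X}_f^c = \mathbf{T}_f \mathbf{P}_f^t + \mathbf{E}$, where the
score vectors in $\mathbf{T}_f$ (length $M$) are the candidate pathway
profiles and the loadings $\mathbf{P}_f$ give each gene's contribution.

How many components are *significant* is decided by a bootstrap with a
genome-wide noise reference.  In each of $R$ repetitions the $M$ sample
columns are resampled with replacement; the per-gene variances of the
resampled full matrix are fitted with a gamma distribution, whose
$(1-\alpha)$ quantile becomes the eigenvalue cutoff for that repetition;
the same resampled columns are used for the pathway submatrix PCA, and
the number of eigenvalues above the cutoff is recorded.  A component
index $i$ is retained when at least $i$ components were selected in more
than a fraction $Q$ of repetitions; $h_f$ is the largest such index.
Eigenvalues are sorted, so selected index sets are prefixes and the
retained set is always contiguous $1..h_f$.  Sharing the resampled
column indices between cutoff and submatrix keeps both quantities on the
same bootstrap replicate; decoupling them gives nearly identical
selections at these sample sizes but breaks that correspondence, which
is why the coupled form is used.

Final scores and loadings come from the original, un-resampled centered
submatrix.  The PLM (pathway level matrix) stacks all retained score
vectors: $\sum_f h_f$ rows by $M$ columns.  Since PCA signs are
arbitrary, each component is flipped so its largest-magnitude loading is
positive; this makes direct/opposite rule labels reproducible across
platforms and runs.

Gamma fitting uses the exact maximum-likelihood estimator (Newton
iteration on the shape via the profile likelihood; the rate MLE is
shape/mean), with a method-of-moments alternative available.  The two
differ negligibly on genome-scale variance vectors.

### Phase 2 — association rules

Each PLM row is a profile.  For a target profile $j$, the PLM is
discretized into high/low activity states ($+1$/$-1$): row $j$ at its
mean score, and every other row $l$ at the threshold $t_{lj}$ that
minimizes the *partition entropy* — the size-weighted average, over the
two partitions induced by $t_{lj}$ on row $l$ (value $\le t_c$ versus
$> t_c$), of the binary Shannon entropy of row $j$'s states.  Candidate
thresholds are the observed score values of row $l$ (the row maximum is
excluded, since it leaves the high partition empty); ties are broken
toward the smallest threshold, and entropies use base 2 with
$0\log 0 \equiv 0$, so the metric lies in $[0,1]$.

For each ordered pair $(l, j)$ of profiles from *different* pathways
(components of one pathway are orthogonal by construction, so rules
between them would be artifacts), both rule classes are scored on the
2×2 contingency of source and target states: a *direct* rule predicts
the target state equal to the source state, an *opposite* rule predicts
its negation.  Rule accuracy is the product of sensitivity
$TP/(TP+FN)$ and specificity $TN/(TN+FP)$, with "positive" meaning
target state $+1$; the better class is kept and the rule is emitted when
its accuracy reaches the threshold.  Both orientations of a pair are
evaluated independently (the discretization depends on the target), so
the rule table is directed; `build_network(dedupe = TRUE)` merges mutual
same-class rules into undirected edges for undirected views.

### Driving genes

Profile loadings typically split into a large near-zero component (genes
that do not shape the profile) and one or more high-loading components.
The cutoff between them is found by estimating the density of the
absolute loadings with a Gaussian kernel (Silverman's rule-of-thumb
bandwidth, 512 grid points on $[0, 1.05\,\max]$) and taking the first
local minimum after the first mode, scanning upward from zero.  Genes
above the cutoff are the profile's *driving genes*.  When the density
has no interior valley the distribution is effectively unimodal and no
data-driven cutoff exists; the profile is then flagged `no_bimodality`
and the single top-|loading| gene is reported, so every profile remains
interpretable.  Density values below $10^{-10}$ of the maximum are
floored to zero before the scan so that FFT round-off on empty stretches
of the grid cannot fabricate valleys.  Because tail stragglers of a
unimodal sample can form genuine kernel bumps, a cutoff may occasionally
isolate a few extreme loadings; results for profiles flagged `ok` but
with very few driving genes deserve a look at the loading distribution.

### Validation against association-score tables

Given an external table of gene-pair association scores (in the style of
integrated functional-genomics networks such as YeastNet), the strength
of a network edge between pathways $i$ and $j$ is
$ASp_{ij} = \sum s(g, h)$ over all unordered gene pairs with
$g \in i$, $h \in j$, $g \ne h$ (shared-gene pairs counted once, absent
pairs scoring 0), and the network mean is $ASn$.  Two reference analyses
are provided: the percentile breakdown of edge $ASp$ against the
*universal set* (all pathway pairs with $ASp > 0$, empirical quantiles
with linear interpolation), and a cardinality-matched null in which each
edge is compared against random pathway pairs drawn from the gene
universe with the same sizes and overlap, using the mid-rank percentile
convention (exchangeable scores give 0.5).  A pathway-size-versus-ASp
correlation is reported as a diagnostic, since $ASp$ is a sum and size
independence should be checked, not assumed.

## The simulation generator

`simulation_design()` / `simulate_dataset()` generate benchmark data
with a full factorial structure: pathway size × planted temporal profile
(SEP) × inner correlation (the fraction of pathway genes that follow the
SEP).  The defaults are the benchmark design used throughout the tests:
sizes 10/60/100/140/200, SEP types 1–7, inner correlations
0/0.2/0.4/0.5/0.6/0.7/0.8, 36 samples, noise variance $s = 0.01$ — 245
disjoint pathways and 24,990 genes.

The seven SEP shapes are canonical time-course patterns: linear rise,
convex exponential decay, early Gaussian peak, late Gaussian trough,
one- and two-cycle sinusoids, and a late step-up, each standardized to
zero mean and unit variance.  An obvious alternative set (mirror-image
ramps and symmetric peak/trough) was rejected because exact negation
pairs are indistinguishable up to sign ($|r| = 1$), which would make the
direct/opposite split of cross-pathway links meaningless; the chosen
library has maximum pairwise $|r| = 0.89$ at 36 samples, so all 21 shape
pairs are distinguishable.  `round(rho * g)` uses round-half-up, so a
10-gene pathway at $\rho = 0.45$ plants 5 signal genes.  Noise is
independent Gaussian with variance $s$ per gene per sample (covariance
$s\,\mathbf{I}$ across samples), the simplest covariance consistent with
a scalar noise level.  Background genes ($1-\rho$ fraction) are
noise-only around mean zero.

What the generator does *not* emulate: genes shared between pathways,
correlated (non-isotropic) noise, batch or array effects, heavy-tailed
expression, and missing values.  Tests passing on these simulations
demonstrate that the algorithmic machinery recovers planted structure
under its own model assumptions; they do not certify performance on real
microarray or RNA-seq data, where annotation overlap and structured
noise will loosen all of the bands observed here.

## Worked example

A reduced design keeps the vignette light; the mechanics are identical
at full scale.

```{r example}
design <- simulation_design(gene_counts = c(20, 60),
                            profile_types = c(1, 5, 6),
                            inner_correlations = c(0, 0.5, 0.8),
                            n_samples = 36, noise_s = 0.01, seed = 3)
ds <- simulate_dataset(design)
ds

res <- pana(ds$matrix, ds$annotation,
            compression_params(alpha = 0.05, n_boot = 50, seed = 3),
            accuracy_min = 0.9)
res

head(res$rules[, c("source", "target", "class", "accuracy", "correlation")])

# all pure-noise pathways rejected, all planted ones retained?
merge(res$profile_set$selection, ds$truth)[, c("pathway", "rho", "h")]

same_sep_fraction(res$network, ds$truth, class = "direct")
```

## Parameters that matter

* `alpha` (default 0.05): significance of the eigenvalue cutoff;
  smaller values demand stronger covariation before a profile is kept.
  Typical working values are 0.05–0.001.
* `n_boot` (default 100): bootstrap repetitions.  100 makes a 0.95
  frequency threshold meaningful (it requires selection in at least 96
  repetitions); fewer repetitions coarsen the frequency grid.
* `q_threshold` (default 0.95): the selection-frequency threshold Q.
* `accuracy_min` (default 0.9): rule filter.  Since accuracy is a
  sensitivity–specificity product, 0.9 already demands near-perfect
  state agreement; raising it prunes the network monotonically.
* Rule inference benefits from a reasonable number of samples: with
  fewer than ~10 samples the discretized states carry little entropy and
  accuracies saturate, so thresholds lose resolution.

## Numerical and degenerate-input choices

* Pathways with fewer than 2 measured genes, or whose components never
  pass the cutoff, yield $h_f = 0$ and are excluded from the PLM; a
  dataset where *no* pathway passes raises an explicit error suggesting
  a larger `alpha`.
* An all-constant matrix makes the gamma fit degenerate and is an error;
  zero-variance genes are dropped from the fit.
* Constant PLM rows cannot be discretized and are excluded from rule
  inference with a message.
* Profile scores are zero-mean by construction; loadings are unit-norm;
  eigenvalues are squared singular values over $M - 1$.
* Ties in the threshold scan resolve to the smallest candidate; ties
  between rule classes resolve to `direct` (correlation of the
  continuous profiles is reported alongside, so the call is auditable).

## Problem sizes used in the test suite

The packaged tests run the full 245-pathway factorial design (24,990
genes × 36 samples) for the end-to-end checks — five replicate seeds at
the main operating point ($\alpha = 0.05$, accuracy 0.9, $s = 0.01$,
$R = 100$) and one seed per noise level for the robustness check — and
reduced designs (2–18 pathways, 30 bootstraps) for unit-level
properties.  These sizes were chosen so the whole suite exercises the
genome-scale code paths while remaining quick to run on a laptop.

## Known limitations

* Pathway profiles are linear summaries; regulation confined to a small
  sample subset may be invisible to PCA (biclustering-style extensions
  would be needed).
* The rule scheme is pairwise and lag-free: no multi-antecedent rules,
  no time-shifted associations.
* Driving genes are a loadings construct, not a differential-expression
  statistic; they describe who shapes a profile, not who changes between
  conditions.
* The validation module quantifies agreement with an external score
  table; it cannot establish causality of the directed rules.
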