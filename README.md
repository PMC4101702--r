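# panar — pathway network inference from gene expression data

`panar` builds networks of *pathway interactions* from a gene expression
matrix and a pathway annotation (GMT gene sets).  It is aimed at
transcriptomics analysts who want to move past per-pathway enrichment
calls and ask which functional modules co-vary, in which direction, and
which genes drive that covariation.

## Method in brief

**Pathway compression.** For each pathway *f* with *N<sub>f</sub>*
measured genes, the expression submatrix **X**<sub>f</sub> is centered
and decomposed by PCA, **X**<sub>f</sub><sup>c</sup> =
**T**<sub>f</sub>**P**<sub>f</sub><sup>t</sup> + **E**.  The number of
significant components *h<sub>f</sub>* is chosen by a bootstrap: in each
of *R* repetitions the sample columns are resampled, the per-gene
variances of the resampled genome-wide matrix are fitted with a gamma
distribution, and components of the resampled submatrix whose
eigenvalues exceed the gamma (1 − *α*) quantile are counted; component
index *i* is kept when at least *i* components are selected in more than
a fraction *Q* (default 0.95) of repetitions.  Retained score vectors —
the *pathway profiles* — form the rows of the pathway level matrix
(PLM).

**Rule inference.** For every ordered profile pair (*l*, *j*) from
different pathways, the PLM is discretized into ±1 activity states:
target *j* at its mean, source *l* at the threshold minimizing the
partition entropy of the target's states.  A *direct* rule predicts the
target state equal to the source state, an *opposite* rule its negation;
rule accuracy = sensitivity × specificity, and rules above an accuracy
threshold define the network edges.

**Driving genes.** Per profile, the absolute loadings are split by the
first local minimum of their kernel density estimate; genes above the
valley are the profile's driving genes.

**Validation.** Given a gene-pair association-score table, each edge is
scored by ASp (sum of scores over cross-pathway gene pairs), compared
against the universal set of pathway pairs by percentile breakdown, and
against a cardinality-matched random null.

A factorial simulation generator (pathway size × planted temporal
profile × inner-correlation fraction, Gaussian noise of variance *s*) is
included, so every stage is testable without external data.

## Worked example

```r
library(panar)

design <- simulation_design(gene_counts = c(20, 60), profile_types = c(1, 5, 6),
                            inner_correlations = c(0, 0.5, 0.8),
                            n_samples = 36, noise_s = 0.01, seed = 3)
ds <- simulate_dataset(design)
ds
#> simulated_dataset: 720 genes x 36 samples, 18 pathways

res <- pana(ds$matrix, ds$annotation,
            compression_params(alpha = 0.05, n_boot = 50, seed = 3),
            accuracy_min = 0.9)
res
#> pana_result: 12 profiles, 64 rules (accuracy >= 0.9 ), 64 network edges

head(res$rules[, c("source", "target", "class", "accuracy", "correlation")], 4)
#>                source              target    class  accuracy correlation
#> 1 pw_g60_sep1_rho50#1 pw_g20_sep1_rho50#1   direct 1.0000000   0.9994116
#> 2 pw_g20_sep5_rho50#1 pw_g20_sep1_rho50#1 opposite 1.0000000  -0.7432636
#> 3 pw_g60_sep5_rho50#1 pw_g20_sep1_rho50#1 opposite 0.9444444  -0.7429628
#> 4 pw_g20_sep1_rho80#1 pw_g20_sep1_rho50#1   direct 1.0000000   0.9992479

same_sep_fraction(res$network, ds$truth, class = "direct")
#> [1] 1

driving_genes(res$profile_set, "pw_g60_sep5_rho50#1")
#> driving genes of pw_g60_sep5_rho50#1: 30 gene(s), cutoff 0.09242
```

Reading the output: the 18 simulated pathways (6 of them pure noise)
yield 12 profiles — exactly one per pathway that carries a planted
signal, none for the noise pathways.  Direct rules join pathways sharing
the same planted temporal profile (correlations ≈ 0.999, and the
same-SEP fraction of direct links is 1 here), opposite rules join
anti-varying profiles (e.g. the rise vs. the one-cycle sine, *r* ≈
−0.74, whose discretized states anti-match almost perfectly).  The
driving-gene report recovers the 30 planted signal genes of a 60-gene
pathway with 50% inner correlation.

Networks export to GraphML/SIF (`write_graphml()`, `write_sif()`), and a
command-line front end with `simulate` / `compress` / `rules` /
`drivers` / `network` / `validate` subcommands is installed at
`inst/cli/pana`.

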