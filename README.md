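# mitopart

Partitioned Bayesian phylogenetics for concatenated mitochondrial
genome alignments.

## The problem

A concatenated insect mitogenome matrix (~15.5 kb; 13 protein-coding
genes, 2 rRNAs, 22 tRNAs) mixes site classes with radically different
evolutionary dynamics. Before inferring a phylogeny from it, an analyst
must choose a *partitioning strategy* — by gene, by codon position, by
both, or none — and a substitution model per partition. `mitopart` is a
tested implementation of the full evaluation design for that choice,
for molecular systematists who want to run it end-to-end or reuse its
parts:

- the three nested dataset selections (37-gene, 15-gene, 13-gene) and
  the twelve partitioning strategies defined on them (PS1–PS12, from
  one combined charset up to 63 gene-by-codon charsets);
- per-partition GTR-family models with AICc selection on a fixed guide
  tree, and the replacement of sampler-incompatible best-fit families
  (TVM, TIM1–3, TPM3, TrN) by the nearest over-parameterised family;
- a self-contained Metropolis-coupled MCMC over topology, branch
  lengths, substitution parameters and per-partition rate multipliers,
  with compiled Felsenstein-pruning likelihoods;
- strategy comparison by harmonic-mean marginal likelihoods and Bayes
  factors, credible sets of topologies, free-parameter sums and
  tree-length statistics;
- maximum-likelihood and Fitch-parsimony cross-checks with bootstrap,
  majority-rule consensus, Robinson–Foulds congruence of single-gene
  trees against the whole-matrix tree;
- a synthetic generator (`makeFixtureStudy("nymphalid-mini")`) that
  emulates the statistical structure of a nymphalid mitogenome matrix
  (gene structure, AT-rich composition, codon-position rate
  heterogeneity, rare IUPAC ambiguities) so everything runs with no
  downloads.

## The statistics in brief

Partition *k* has a reversible model Q with q_ij = r_ij π_j normalized
to one expected substitution per site, discrete-gamma rate variation
(4 categories), and a rate multiplier m_k with site-weighted mean 1
over partitions. Topology and branch lengths are shared. Strategies are
compared by

    2 ln B10 = 2 [ ln HM1 − ln HM0 ],

where HM is the harmonic mean of post-burn-in likelihoods, read on the
Kass–Raftery scale (values over 10: very strong preference). Credible
sets of trees are the smallest frequency-ranked topology sets reaching
95% / 99% cumulative posterior frequency. Free parameters sum to
9k + (k−1) for k GTR+G partitions.

## A worked example

```r
library(mitopart)

cfg <- studyConfig(preset = "nymphalid-mini",
                   strategies = c("PS9", "PS12"),
                   mcmc = McmcConfig(nChains = 2L, nGenerations = 1500L,
                                     sampleEvery = 10L),
                   seed = 1)
st <- runStudy(cfg)
st$summary
#>   strategy dataset nPartitions freeParameters      lnHM csetTotal cset99 cset95
#> 1      PS9     D13           1              9 -5862.954         5      4      3
#> 2     PS12     D13          39            389 -5647.753         2      2      1
#>   treeLengthMean treeLengthSD
#> 1       1.992521   0.09605834
#> 2       1.649017   0.05306380
bfValues(st$bf$D13)["PS12", "PS9"]
#> [1] 430.4025
```

Read: on synthetic data generated with strong gene-by-codon rate
heterogeneity, the 39-partition strategy (PS12) improves the
harmonic-mean marginal log-likelihood over the unpartitioned one (PS9)
by >200 units, giving 2lnB10 ≈ 430 — far past the very-strong threshold
of 10 — and its credible set of topologies shrinks toward the single
generating topology. The exact numbers vary with the seed; the
preference for the partitioned model does not.

Single-gene versus whole-matrix congruence:

```r
fx <- makeFixtureStudy("nymphalid-mini", seed = 1)
sg <- runSingleGeneSuite(fx$alignment, fx$genemap, fx$tree,
                         mcmc = McmcConfig(nChains = 1L,
                                           nGenerations = 600L,
                                           sampleEvery = 10L))
head(sg$report, 3)
#>   gene rf identical
#> 1 nad2 13     FALSE
#> 2 cox1 13     FALSE
#> 3 cox2  9     FALSE
```

No single gene recovers the topology the whole matrix recovers — the
congruence table quantifies how far each falls (Robinson–Foulds
distance to the reference).

A thin shell wrapper with the same functionality is installed at
`inst/scripts/mitopart` (`mitopart charsets|simulate|run`).

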