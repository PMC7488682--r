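---
title: "Hill-number beta diversity, null models and consensus tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hill-number beta diversity, null models and consensus tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillbeta)
```

## The problem

Amplicon surveys of microbial communities produce count tables: read counts
of operational taxonomic units (OTUs) or amplicon sequence variants (ASVs)
across samples. Quantifying *beta diversity* — compositional difference
between samples — requires choosing a dissimilarity index, and the choice
matters: incidence-based indices (Jaccard, Sørensen) are dominated by the
long tail of rare, possibly spurious taxa, while abundance-weighted indices
(Bray-Curtis) are dominated by a handful of abundant taxa. `hillbeta`
implements a framework in which the weight given to relative abundance is a
continuous parameter, the *diversity order* `q`, so that the dependence of
any conclusion on that weighting can be inspected rather than assumed.

## Hill numbers and their decomposition

The Hill number of order `q` of a relative-abundance vector $p$ is

$$^qD = \Big(\sum_i p_i^q\Big)^{1/(1-q)}, \qquad
  ^1D = \exp\Big(-\sum_i p_i \ln p_i\Big),$$

the effective number of equally abundant taxa. At `q = 0` it is richness,
at `q = 1` the exponential of Shannon entropy, at `q = 2` the inverse
Simpson concentration. For $N$ communities compared with equal weights,
gamma diversity is the Hill number of the pooled vector
$\bar p_i = \frac1N \sum_j p_{ij}$, alpha diversity is the effective number
of taxa per community,

$$^qD_\alpha = \frac1N\Big[\sum_i\sum_j (p_{ij}/N)^q\Big]^{1/(1-q)},$$

with the corresponding entropy limit at `q = 1`, and beta diversity is the
ratio $^qD_\beta = {^qD_\gamma}/{^qD_\alpha} \in [1, N]$: the effective
number of distinct communities. This equal-weight alpha is the only
standard choice consistent with all the constraints the package's test
suite enforces simultaneously — $\beta \in [1, N]$, and the `q = 0`
equivalences below.

Beta is mapped onto $[0,1]$ by two transforms. The *local* dissimilarity

$$^qd = \frac{(^qD_\beta)^{1-q} - 1}{N^{1-q} - 1}$$

is the effective average proportion of a community's taxa not shared with
the others; at `q = 0` it is exactly the Sørensen dissimilarity. The
*regional* transform replaces the exponent $1-q$ by $q-1$ and measures the
unshared proportion of the pooled community; at `q = 0` it is exactly the
Jaccard dissimilarity. Both share the limit $\ln\beta/\ln N$ at `q = 1`,
so the two classes coincide there; the package uses the same limit
expression for both. When two samples have the same species-abundance
distribution and every shared taxon has identical relative abundance in
both, the Bray-Curtis dissimilarity coincides with $^1d$; the test suite
checks this identity on generated matched pairs to $10^{-10}$.

`dissimilarity_profile()` plots $^qd$ against `q` (default grid 0–2 in
steps of 0.05, covering the range where the index transitions from
incidence- to dominance-weighted behaviour; values of `q` much above 2 add
little, as the index is then already dominated by the top taxa).

## The generalized Raup-Crick null model

A dissimilarity value alone does not say whether it reflects deterministic
selection or random assembly: richness differences alone inflate it. The
null model controls for this. For a pair of samples, each iteration
re-assembles *both* samples from a regional pool, preserving each one's
observed richness and read depth, and records the dissimilarity of the
assembled pair; symmetric re-assembly of both members matches the
interpretation of the null distribution as the dissimilarity of two random
assemblies. The Raup-Crick index is the fraction of iterations with null
dissimilarity below the observed value, ties counted half:

$$^q\mathrm{RC} = \frac{N_{[d_{exp} < d_{obs}]} + 0.5\,N_{[d_{exp} = d_{obs}]}}{N_{TOT}}.$$

Values near 0 mean "more similar than random assembly"; near 1, "more
dissimilar"; `rescale_rc()` maps onto $[-1,1]$ with 0 as the null
expectation.

Assembly of one null sample proceeds in two stages. Taxa are picked
without replacement, with probability proportional to their *occurrence
frequency* in the pool (`scheme = "frequency"`, the default) or to their
pool-wide read totals (`scheme = "abundance"`). Reads are then populated:
each picked taxon is seeded with one read (so richness is exact) and the
remaining `depth - richness` reads are drawn multinomially with
probabilities proportional to the pool-wide read totals of the *selected*
taxa, renormalized over them. Renormalizing over the selected taxa (rather
than leaving probability mass on unselected ones and redrawing) keeps the
draw exact and single-pass; it is this package's choice where the
mechanism is underdetermined.

Numerical choices:

* **Tie tolerance.** $|d_{exp} - d_{obs}| \le 10^{-10}$ counts as a tie.
  At `q = 0` dissimilarities take few discrete rational values, so exact
  ties are real and frequent; a strict `==` on doubles would undercount
  them and bias RC.
* **Iterations.** Default 199; the per-pair null assemblies are generated
  once and reused across the whole `q` grid in `rc_profile()`, which is
  both cheaper and internally consistent.
* **Pool.** Defaults to all samples of the table; pass `pool_sample_ids`
  to restrict it (e.g. to one reactor's samples) when the regional species
  pool is narrower than the table.

Under self-null calibration — scoring a pair that is itself drawn from the
null — RC is approximately uniform on $[0,1]$ up to the $1/(N_{TOT}+1)$
discretization; the test suite checks this with a Kolmogorov–Smirnov test
over 200 replicates at 99 iterations.

## Consensus tables

Denoisers infer exact sequences, so a true ASV found by one pipeline
should be found by another, while error sequences tend to be
pipeline-specific. `consensus_table()` keeps only taxa detected in *all*
input tables (matched by representative sequence), computes per table the
fraction of reads on that shared set, and retains the single table with
the highest fraction, subset to the shared taxa. Counts are never merged
across tables. Matching is exact sequence equality by default; a
`subsequence` mode (containment, for pipelines that trim to different
lengths) and an `edit_distance` mode (Levenshtein $\le k$) are available
but off by default, because tolerant matching can conflate near-identical
true variants. Ambiguous multi-matches resolve to the minimal-distance,
then highest-read candidate, with a message; fraction ties retain the
table with fewer taxa, then the first by input order. Fractions are
computed on raw counts — rarefy after consensus, not before.

## Rarefaction and the depth simulation

`rarefy()` subsamples each sample *without replacement* to a common depth
(a multivariate hypergeometric draw), as a single seeded draw rather than
an average over draws: downstream analyses then operate on one concrete
equal-depth table. `simulate_depth()` draws replicate samples from a known
abundance distribution by multinomial sampling at a ladder of depths
(default $10^4$ to $10^6$). Because all replicates come from the same
community the true dissimilarity is zero, so the observed $^0d$ between
replicates measures pure undersampling bias; it shrinks with depth and
with increasing `q`. The demo truth distribution is a lognormal
rank-abundance curve (`make_lognormal_community()`, default shape
`sigma = 2`), a standard parametric stand-in for the long-tailed
distributions real amplicon data show.

## Permutation tests

`mantel_test()` correlates the upper triangles of two dissimilarity
matrices (Pearson default, Spearman available) with a null from
simultaneous row/column permutation. `permanova()` forms the Anderson-type
pseudo-F directly from squared dissimilarities,
$SS_{total} = \frac1n\sum_{i<j} d_{ij}^2$ partitioned into within- and
between-group parts, with a null from label permutation; one-way designs
only. Both use the +1-corrected p-value
$p = (\#\{stat_{perm} \ge stat_{obs}\} + 1)/(permutations + 1)$, so with
the default 999 permutations the smallest attainable p is 0.001. Note that
permutations reproducing the observed grouping tie with the observed
statistic and are counted, so the floor is reached only when no sampled
permutation recreates the partition.

## The structured toy table

`make_structured_table()` generates eight samples whose sharing structure makes
index behaviour predictable: S0–S3 each hold 2 abundant, 4 intermediate
and 8 rare taxa with identical class abundances; S1 shares exactly half of
each class with S0 (dissimilarity 0.5 at every `q`); S2 shares no abundant
taxa (profile rises toward 1); S3 shares all intermediates (a valley); S4
shares all taxa but with a ramp abundance distribution; S5–S7 are
richness-2 samples sharing S0's abundant, intermediate or rare taxa. It
is the sharing pattern, not any particular cell value, that produces
these behaviours, so the class abundances are parameters (default
`a = 0.25, i = 0.075, r = 0.025` at depth 1000, chosen to give whole
counts with roughly a 3–10× abundance step between classes); every
property asserted in the tests holds for *any* scheme satisfying the
constraints, and a self-check of all class sizes and sharing counts runs
at construction. The mutual overlap among S1–S3 is a free design choice;
here their non-S0 taxa are unique per sample.

## What the generators do and do not emulate

The synthetic communities capture multinomial sampling noise, long-tailed
abundance distributions and controlled sharing structure. They do not
emulate PCR/sequencing error (spurious ASV generation), compositional
biases of DNA extraction or amplification, or overdispersion between
biological replicates. Passing tests therefore demonstrate correctness of
the indices and the null machinery, not robustness to artefacts that real
data contain upstream of the count table.

## Problem sizes and determinism

The test suite runs at desk scale by design: random tables of 3–25 taxa
and 2–8 samples for exactness properties, an exhaustive sweep of all
two-taxon/two-sample tables with counts up to 6 against a literal
brute-force oracle plus several hundred random larger ones, 200 self-null
replicates at 99 iterations for RC calibration, 500 null simulations at
99 permutations for the size of the permutation tests, and a 919-taxon
lognormal truth at depths up to $3\times10^5$ for the undersampling
simulation. All stochastic functions accept a `seed` argument and restore
the caller's RNG state; the command-line interface refuses to run
stochastic subcommands without an explicit `--seed`.

## Limitations

Taxonomic indices only — no phylogenetic or functional generalizations;
one-way permanova only; no richness extrapolation (Chao1 etc.); the
consensus step matches sequences, it does not attempt chimera detection or
abundance reconciliation across pipelines.
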