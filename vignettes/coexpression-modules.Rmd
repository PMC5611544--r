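---
title: "Coexpression modules and perturbation scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression modules and perturbation scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

This vignette is the package's account of its statistical machinery: the
models and formulas each stage implements, the defaults and why they are
what they are, the numerical conventions that make runs reproducible, and
what the synthetic-data tests do and do not demonstrate about real data.

## Coexpression scores

Given a genes × conditions matrix of log2-scale expression values (for a
condition compendium, replicate arrays are first averaged per condition
with `average_replicates()`), `pairwise_scores()` computes for every
unordered gene pair

* the Pearson correlation $r_{uv}$ across conditions,
* the Fisher transform $z_{uv} = \operatorname{arctanh}(r_{uv})$, which
  variance-stabilizes $r$ and makes the null distribution approximately
  normal, and
* the standardized coexpression score
  $z^{cs}_{uv} = (z_{uv} - \bar z)/s_z$, where $\bar z$ and $s_z$ are the
  mean and standard deviation over the *entire population of unordered
  pairs* (the upper triangle). Per-gene standardization is deliberately
  not offered: a single global standardization keeps one pair ranking and
  makes the cutoff interpretable as a population tail.

Conventions: $r$ is clamped to $\pm(1 - 10^{-15})$ before the arctanh so
duplicated profiles stay finite while preserving the ranking; with
missing values, correlations are pairwise-complete and pairs whose
sample overlap falls below `min_overlap` (default: every sample) are
dropped with a warning; zero-variance genes are an error rather than a
silent NaN. Correlation is computed block-by-block (`block_size`,
default 1000 genes) so memory stays bounded at large gene counts.

`threshold_network()` keeps pairs with $z^{cs} > 1.96$ (strict). For a
normal score population this is the top 2.5% tail; the realized kept
fraction and the minimum $r$ among kept edges are recorded as graph
attributes because both are empirical properties of the data set at
hand, not constants. At 45 conditions the Fisher z of a null correlation
has slightly heavier tails than a normal, so the realized kept fraction
on independent genes is ≈2.52% rather than 2.500% — the package reports
what it measures. Edge weight for all downstream arithmetic is $r$
itself; $z^{cs}$ travels along as metadata. Negative-weight edges cannot
arise at the default cutoff, and the clustering stage rejects them
explicitly if a user forces a permissive cutoff.

`first_neighbors()` answers the single-gene query: the induced subgraph
on a query gene and every neighbor connected by weight above 0.80 (on
the $r$ scale, strict), the conventional default for "show me this
gene's strong coexpression context".

## Dense modules

`spici_cluster()` implements a greedy density-based clustering in the
SPICi family. Density of a gene set $S$ is
$d(S) = \sum_{(u,v) \in E(S)} w_{uv} \big/ \binom{|S|}{2}$. The
procedure repeats until no nodes remain: seed at the unclustered node
with the highest weighted degree; pair it with its best available
neighbor (maximum edge weight, ties by weighted degree, then
lexicographic gene order); then repeatedly add the unclustered node with
maximal *support* (summed weight into $S$) while support
$\ge T_s \cdot |S| \cdot d(S)$ and the grown density stays $\ge T_d$;
emit the cluster and remove its nodes. Clusters below 3 genes are
returned as unclustered. Two properties are guaranteed on every run and
asserted in the test suite: every emitted cluster has $d(S) \ge T_d$,
and the output is byte-identical across runs (every tie-break is
lexicographic).

Design notes. Only $T_d$ is a scientifically meaningful dial; $T_s$
defaults to 0.5 per the original SPICi formulation. The original's
weight-binned seed selection is simplified to exact maxima with
deterministic tie-breaks: correctness here is judged by the density
invariant and by planted-module recovery, not bit-compatibility with any
particular binary. Weighted (not unweighted) mode is used throughout,
since all downstream statistics are weight-based.

## Choosing the density threshold

`sweep_cluster()` re-clusters the network independently at each
$T_d$ (default grid 0.1–0.9) and `evaluate_sweep()` scores each point
by four criteria:

1. number of clusters of size ≥ 3;
2. fraction of network genes inside clusters;
3. per-cluster **average segregation**: the mean weight of edges
   internal to the cluster divided by the mean weight of all distinct
   network edges incident on cluster members. Internal edges are
   members of the incident set and each distinct edge is counted once,
   which makes an isolated clique score exactly 1. (The alternative
   reading that double-counts internal edges in the denominator is not
   used; it would make a perfectly isolated module score above 1 by an
   amount that depends on its size.) The report emits medians, quartiles
   and box-plot notch bounds ($\pm 1.58\,\mathrm{IQR}/\sqrt{n}$) so
   neighboring sweep points can be compared for overlapping notches;
4. gene-set enrichment at $q < 0.1$: how many clusters hit at least one
   set and how many distinct sets are hit, using sets annotating fewer
   than 500 genes (`filter_genesets(..., max_size = 499)`) so broad
   terms do not dominate.

The package deliberately does not auto-select $T_d$: "first significant
drop" is a judgment made on the emitted table (the notches support it),
not an elbow heuristic baked into code.

## Enrichment statistics

The overlap test is the upper cumulative hypergeometric tail
$$P(X \ge m) = \sum_{x=m}^{\min(n_i, n_j)}
  \binom{n_i}{x}\binom{N-n_i}{n_j-x}\Big/\binom{N}{n_j},$$
implemented in log-space (`lchoose`) and verified in the tests against
both exhaustive subset enumeration (all parameter combinations with
$N \le 12$) and `phyper`. Multiple testing uses Benjamini–Hochberg
throughout the package — one procedure, parameter-free and conservative —
with the family always defined as *all* (cluster, set) pairs of a call.
ES $= -\log_{10} q$, and the annotation default ES $> 1.3$ corresponds
to $q < 10^{-1.3} \approx 0.05$. Gene-set size bounds default to
[10, 1500] (inclusive: a 10-gene set is kept, a 1501-gene set is not),
computed against the declared universe. The universe defaults to all
network genes and is overridable; enrichment p-values shrink as the
universe grows, so the choice is surfaced rather than hidden.
`identify_responsive_clusters()` applies the same test to up/down DE
lists and reports signed scores $\pm(-\log_{10} q)$, zeroed below the
significance cutoff, so a heat-map of cluster × condition scores is
directly readable. Motif annotation is a simple presence rule — a motif
must occur in strictly more than 50% of a cluster's genes — applied to
precomputed hit tables; de novo motif discovery is out of scope.

## Differential expression

`de_test()` fits the two-group linear model per gene: pooled-variance
$t$ with $n_1 + n_2 - 2$ degrees of freedom on replicate samples (never
on replicate-averaged columns), two-sided p, BH q. No empirical-Bayes
variance moderation is applied: moderation hyperparameters are
data-dependent and the package prefers the assumption-light classical
test; users with very few replicates should expect the corresponding
loss of power, and the simulation sizes in the test suite reflect that —
the planted-shift recovery test uses 6 replicates per side (df = 10),
where the unmoderated $t$ genuinely has the power to clear a BH
$q < 0.01$ screen, rather than 3 per side, where no classical test
could. Selection is strict: $q <$ cutoff and a sign condition on the
fold change, so up and down lists are disjoint by construction.

## Perturbation scoring (PAGE)

For a profile of fold changes with mean $\mu$ and standard deviation
$\delta$ over *profiled genes*, a cluster with $m$ profiled members and
set mean $S_m$ scores $Z = (S_m - \mu)\sqrt{m}/\delta$. Under a null
profile $Z$ is approximately standard normal (the test suite checks
this with a Kolmogorov–Smirnov test over 5,000 random sets), which is
what makes $Z$ comparable across clusters and profiles. Conventions:
cluster genes absent from the uploaded profile are ignored ($m$ counts
profiled members only); clusters with $m <$ 10 are skipped — below that
the normal approximation and the set mean are both fragile; the profile
should cover at least ~1000 genes for $\mu, \delta$ to be stable
(warned otherwise); profiled genes, not all array genes, define the
population moments, since the uploaded profile is the user's statement
of what was measured. $Z$ is invariant to shifting or positively
scaling the whole profile and antisymmetric under negation — all three
asserted numerically in the tests. Selection keeps $q <$ cutoff ranked
by $|Z|$; a detectability guide: a coordinated per-gene shift of
$\Delta$ gives $E[Z] = \Delta\sqrt{m}/\delta$, so a shift of
$2\delta/\sqrt{m}$ (set mean two standard errors from background) sits
at $E[Z] = 2$ and is *not* reliably selectable after multiple-testing
correction — roughly $\Delta \gtrsim 4.5\,\delta/\sqrt{m}$ is needed
for dependable selection at $q < 0.01$ among hundreds of clusters.

## Synthetic data

`simulate_expression()` draws each block-$b$ gene as
$\sqrt{\rho_{out}}\,G + \sqrt{\rho_{in} - \rho_{out}}\,F_b +
\sqrt{1-\rho_{in}}\,\varepsilon$ with independent standard-normal
latent factors and noise, so within-block correlation is exactly
$\rho_{in}$ in expectation and cross-block correlation $\rho_{out}$ —
an analytically controlled fixture, which is why the recovery
thresholds in the tests (Jaccard ≥ 0.8 per planted block) are
principled rather than tuned. Defaults: 45 conditions (a realistic
condition-compendium scale), five 30-gene blocks, $\rho_{in} = 0.9$,
$\rho_{out} = 0$; the planted-recovery tests surround the 150 block
genes with 350 independent background genes so that thresholding and
clustering face a realistic sea of null pairs. `simulate_profile()`
plants coordinated per-gene shifts on chosen clusters over an
i.i.d. standard-normal background.

What the generator does **not** emulate: probe-level artifacts, batch
structure, correlated background (housekeeping co-regulation),
heavy-tailed expression noise, or missingness patterns. Passing the
planted-recovery tests therefore demonstrates algorithmic correctness
and calibration under the stated model, not performance on any real
compendium; on real arrays the empirical $r$ equivalent of the 1.96
cutoff, the edge count, and the cluster-size distribution will all be
data-set properties.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale by choice: the
million-pair threshold-calibration check uses 1,415 genes (1,000,405
pairs), the acceptance script 2,000 genes (1,999,000 pairs), recovery
tests 500 genes × 45 conditions × 3 seeds, and the PAGE calibration
5,000 random sets over a 10,000-gene profile. Every simulation is
seed-parameterized; every clustering is deterministic by construction,
so identical inputs give byte-identical outputs, including through the
command-line driver (asserted in the tests).

## Known limitations

* The greedy clusterer is order-dependent by design; it trades global
  optimality for speed and determinism, and a gene swallowed by an
  early cluster cannot be reclaimed by a later, better-fitting one.
* BH is used where some pipelines use Storey's q-value; BH is more
  conservative, so counts of "significant" clusters are lower bounds
  relative to such pipelines.
* The unmoderated DE t-test is underpowered at 2–3 replicates per
  group relative to moderated alternatives.
* Hypergeometric annotation treats gene sets as flat lists; no
  ontology-graph propagation is performed.
* PAGE assumes profiled fold changes are exchangeable under the null;
  strong global asymmetries (e.g. normalization artifacts) shift every
  $Z$ and should be removed upstream.
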