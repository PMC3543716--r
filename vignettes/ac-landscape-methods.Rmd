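---
title: "Methods: Always-Correlated co-expression landscapes"
author: "aclandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Always-Correlated co-expression landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aclandscape)
```

## The problem and the approach

Tissue-level gene co-expression networks built from a single condition are
notoriously sensitive to the samples used. The *Always Correlated* (AC)
approach addresses this by inferring one co-expression network per analysis
group — subsets of the data defined by genotype, developmental stage or
phenotype contrast — and then retaining only the gene pairs whose
correlation is judged significant in **every** group's network. The
resulting AC landscape is sparse, robust to single-condition artefacts, and
decomposes into functionally coherent modules (muscle contraction,
mitochondrial, ribosomal, and so on, in skeletal-muscle applications).
Paired with a confident 1:1 gene mapping, two such landscapes from
different platforms or species can be compared node by node and edge by
edge.

This package implements the full chain: preprocessing, per-group PCIT
network inference, edge intersection, MCODE-style module detection under a
correlation cut-off sweep, flat hypergeometric enrichment,
module-to-regulator ranking, and cross-landscape comparison — plus a
synthetic-data generator with known ground truth that exercises every
stage.

## Preprocessing

Starting from a normalised, log2-scale probe-by-sample matrix with
detection calls:

1. **Dubious probe removal** (`drop_dubious_probes`): probe sets with no,
   or several, predicted genes are dropped.
2. **Probe-to-gene collapse** (`collapse_to_genes`): for genes with several
   probe sets, the probe set with the highest mean expression over *all*
   samples is retained and relabelled with the gene identifier. Ties are
   broken by the lexicographically smallest probe identifier so the result
   is deterministic.
3. **Detection filter** (`filter_present`): a gene is kept when called
   Present in at least one sample (`min_timepoints = 1`). The phrase "at
   least one time point" admits a stricter reading — Present in all
   replicates of at least one time point — which is available by supplying
   a sample-to-timepoint table; with no replicate structure given, the
   per-sample reading is the default.
4. **Variation filter** (`filter_low_variation`): genes with no deviation
   beyond `k_sd` (default 1) standard deviations from their own group mean
   are removed, per analysis group. Whose SD is meant is genuinely
   ambiguous; both readings are implemented as modes. The default
   (`global_sd`) uses the SD of the whole subset's value distribution,
   reading "one standard deviation across each dataset, or subset" as a
   dataset-level quantity; `gene_sd` uses each gene's own SD. The
   `gene_sd` mode is strictly idempotent; `global_sd` recomputes the
   yardstick on whatever matrix it is given.

Filters only restrict membership; retained values are never altered.

## PCIT edge significance

For each analysis group the Pearson correlation matrix is computed over the
group's samples and pruned with the partial-correlation-and-information-
theory (PCIT) rule. For every unordered gene trio $(x, y, z)$ the three
first-order partial correlations are formed, e.g.

$$r_{xy \cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
  {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},$$

and the trio's tolerance $\varepsilon$ is the mean of the three
partial-to-direct ratios. The edge $(x, y)$ is flagged non-significant in
the trio when

$$|r_{xy}| < |\varepsilon\, r_{xz}| \quad\text{and}\quad
  |r_{xy}| < |\varepsilon\, r_{yz}|,$$

that is, when both flanking correlations dominate it at the trio's own
scale. An edge survives if and only if its correlation is nonzero and no
trio flags it; with only two genes any nonzero correlation survives. Two
numerical choices are configurable so behaviour can be pinned against any
reference implementation, since published descriptions do not fix them:
the ratios may be averaged signed (default) or in absolute value, and the
flag inequality may be strict (default) or not.

Degenerate cases: a ratio whose direct correlation is zero (within 1e-12)
is simply excluded from the mean, and a trio containing a near-unit
correlation (|r| ≥ 1 − 1e-12, typically duplicated genes) is skipped
entirely and counted — duplicates keep their edge but never serve as
conditioning variables, which would make the partials singular.

The trio scan is $O(n^3)$ and runs in compiled code with a branch-light
inner loop; a few thousand genes per group (the scale of condition-subset
networks after filtering, roughly 3,000–4,500 genes) is practical on one
core, and ~5,000 genes is a sensible ceiling.

A property worth knowing: the AND-condition only removes an edge that is
dominated by *both* flanks, so a single network retains a modest fraction
of weak null edges (we measure roughly 10% of cross-module pairs at 40
samples and noise SD 0.5). Single condition networks are therefore dense
and hard to interpret on their own — it is the intersection across all
condition networks that drives the null rate toward zero, which is
precisely the argument for the AC construction.

## The AC landscape

`intersect_networks` keeps the unordered pairs present in every supplied
network. Edge identity is the pair alone: per-network correlation values
are recorded but not required to agree. Each AC edge is assigned the
correlation (and its sign) from a designated reference network — by
convention the "Overall" network computed over all samples — because the
source analysis reports a single sign per edge without naming the network
that supplies it; edges whose per-network correlations disagree in sign
are kept and flagged `sign_consistent = FALSE`. The sign composition
report rounds percentages half-up to one decimal (so 1,368 negative of
5,196 edges prints as 26.3).

## Module detection: MCODE and the cut-off sweep

Correlation cut-offs are applied to the landscape with strict inequality
(`|r| > c`, matching ">0.85"-style thresholds), then modules are found
with a re-implemented MCODE:

* **Vertex weighting**: the weight of $v$ is $k_{\max} \times$ density of
  the highest $k$-core of the subgraph induced by $v$'s closed
  neighbourhood. A vertex inside $K_n$ weighs $n-1$; a star centre weighs
  $1/3$ for five leaves.
* **Expansion**: unassigned vertices seed in decreasing weight order (ties
  to the smallest gene identifier); BFS admits unassigned neighbours with
  weight at least $(1 - \mathrm{vwp})$ times the seed weight, to a maximum
  depth. Every vertex joins at most one module, so modules are
  vertex-disjoint before fluff.
* **Post-processing**: haircut iteratively removes vertices singly
  connected within the module; fluff (off by default) adds boundary
  neighbours whose closed-neighbourhood density exceeds a threshold.
  Modules smaller than two vertices are discarded, and results are ordered
  by score (density × size) with deterministic tie-breaks.

Defaults are the plug-in's: vwp 0.2, haircut on, fluff off, depth 100.

One behaviour deserves a note. Because admission is relative to the *seed*
weight, two equally dense cliques joined by a direct bridge edge have
identical weights everywhere and expansion crosses the bridge: they merge
into one module. They separate exactly when joined through a low-weight
bridging vertex, whose weight falls below the admission threshold. Both
behaviours are asserted in the test suite.

The manual practice of relaxing parameters per module until the module
stops being cohesive is mechanised by `sweep_modules`. Modules are tracked
across adjacent cut-offs by best Jaccard overlap (≥ 0.3 continues a
lineage). Each module's *connectivity ratio* is boundary edges divided by
internal edges at that cut-off. A cut-off is ineligible for a lineage when
the ratio both reaches 1 (boundary outnumbering interior — the module has
lost cohesion) and has grown by at least `jump_factor` (default 2) over
the previous cut-off; the chosen cut-off maximises module size over
eligible entries, ties going to the lowest cut-off. Both conditions are
needed: connectivity along a lineage is not monotone — while a cut-off
bisects a true module, the fragment's "boundary" is the rest of its own
module, so the ratio spikes transiently and returns to zero once the
module assembles — and a pure relative-growth rule would freeze such
fragments at the strictest cut-off (a 0 → positive transition is an
infinite relative jump). The absolute component makes the rule robust;
`jump_factor` remains the tunable notion of "major step".

## Enrichment and regulators

Module annotation uses the flat hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, evaluated in
log-space via `stats::phyper` and cross-checked in the tests against
direct log-space summation (agreement to 1e-12 relative for all universes
up to 200 genes). Gene-ontology hierarchy propagation is deliberately out
of scope: collections must be pre-propagated if the hierarchy matters. The
default universe for module enrichment is the AC landscape node set;
supplying all filtered genes instead is supported and changes $N$ — the
choice is the analyst's, as the reference set behind published module
p-values is typically unstated. The same statistic drives the two-set
overlap test used for cross-landscape node overlap. Multiple-testing
correction is Benjamini–Hochberg by default.

The module-to-regulator score of a transcription factor $t$ against a
module $M$ is the mean of $|r_{tg}|$ over $g \in M \setminus \{t\}$, taken
from the overall (all-samples) correlation matrix and *not* restricted to
PCIT-significant pairs. This is a deliberate concretization — the minimal
reading of ranking regulators "based on the correlation values" — and two
alternatives are switchable: signed mean, and masking to PCIT-kept pairs.
A TF that is itself a module member never benefits from its own
self-correlation. The top 10 TFs per module are cross-tabulated against
module membership into three disjoint, exhaustive columns (member and
top-ranked; member only; top-ranked only).

## Cross-landscape comparison

Two landscapes are compared strictly inside a confident 1:1 identifier
mapping (`build_mapping` links two platform annotations through a shared
symbol column, excluding any symbol with multiple candidates on either
side). Comparing outside the mapping universe would conflate biological
difference with platform coverage, so nodes not measurable on both
platforms are ignored throughout. Node overlap gets a hypergeometric
p-value with the mapping universe as $N$; an edge is shared when its
mapped unordered pair is an edge in both landscapes (sign agreement is
reported, not required); per paired module the a-only / both / b-only gene
counts are tabulated.

## The synthetic-data generator

`generate_expression` emulates the features the pipeline must cope with:

* several analysis groups of samples, with an independent standard-normal
  latent factor per module, group and sample;
* member genes valued $8 + \lambda_i f + \epsilon$, with loadings
  $\lambda_i$ of mixed sign (a configurable fraction negative) and
  Gaussian noise of SD $\sigma$;
* modules active in all groups (always-correlated pairs) or in a strict
  subset (condition-specific pairs);
* flat genes at $8.0$ with noise $\sigma/100$, which the one-SD variation
  filter provably removes;
* detection calls Present except for a configurable random fraction;
* planted transcription factors: ordinary module members with loading
  $0.9\lambda$, flagged in the ground truth so recovery is measurable;
* a paired second dataset (`generate_species_pair`) sharing its leading
  modules under a partial, strictly 1:1 identifier mapping, with private
  modules placed on disjoint gene blocks so their edges cannot overlap.

All genes share the 8.0 baseline (a log2-scale convention): the global-SD
variation filter compares deviations against the spread of the whole
subset, and a baseline offset between flat and informative genes would
dominate that spread and distort the filter. Under this single-factor
model the expected correlation of members $i, j$ is
$\lambda_i \lambda_j / \sqrt{(\lambda_i^2 + \sigma^2)(\lambda_j^2 +
\sigma^2)}$ — at loading 1 and $\sigma = 0.5$, about 0.8 — which the tests
verify empirically, including convergence at $n = 2000$ samples.

The default study design (`default_simulation_config`) mirrors a
six-condition muscle study: five condition subsets of 16, 19, 15, 20 and
40 arrays plus a sixth group of 20 (the published design's sixth group is
an "Overall" union of all samples; with factors drawn per disjoint group,
the pooled all-samples matrix plays that role where needed, e.g. for
consensus weights and regulator ranking). It plants two always-active
modules of 30 and 15 genes (one regulator each), one module active in
three of the six groups, 20% flat genes, loading 1.0, noise SD 0.5 and
150 genes in total. These sizes keep the full six-network pipeline fast
enough that ten independent replicates run in a few seconds while leaving
hundreds of planted pairs to score against.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: probe-level effects, array batch
effects, heavy-tailed or heteroscedastic noise, correlated latent factors
(e.g. co-regulated modules), time-course autocorrelation within groups
(deliberate: the AC construction uses only within-group correlation, not
temporal order), and many-to-many homology. Results on real arrays will be
noisier in exactly the ways the source analysis itself cautions about.

## Determinism and numerical choices

Every random draw flows from a single integer seed; identical seeds give
bit-identical outputs, and the pipeline's artifacts are byte-reproducible.
Edge identity is always the lexicographically ordered gene pair. Ties —
probe collapse, MCODE seeding, module ordering, regulator ranks — break on
the smallest identifier. Correlation matrices are validated for symmetry
(1e-12) and unit diagonal; partial correlations are clamped to $[-1, 1]$.
Percentages round half-up to one decimal.

## Worked scale

The test suite and the acceptance script run the entire pipeline on the
default synthetic design (150 genes, six groups, 130 samples) over ten
seeds: AC sensitivity for always-pairs is typically ≥ 0.95 with
conditional-pair leakage ≤ 0.01, planted-module recovery Jaccard ≥ 0.9,
and planted-regulator top-10 recovery 10/10. The PCIT kernel itself is
validated against an independent naive trio loop on random
positive-definite matrices up to 25 genes, and the closed-form
constant-correlation case ($\varepsilon = 1/(1+\rho)$, all edges kept) at
$\rho = 0.3, 0.6, 0.9$.

## Known limitations

* PCIT's $O(n^3)$ trio scan makes whole-transcriptome single networks
  (≫ 5,000 genes) impractical; the intended use is per-condition subsets
  after variation filtering.
* Single-network specificity is modest by construction (see above); do
  not interpret a lone PCIT network's edge list as a significance-filtered
  set of direct interactions.
* Flat enrichment ignores gene-set hierarchy; propagate collections first
  if parent terms matter.
* The sweep's jump rule is a formalization of a manual procedure; its
  `jump_factor` and the ratio-≥-1 cohesion bound are conventions, exposed
  as parameters.
* Cross-landscape statistics depend on the chosen mapping universe; with
  the universe unstated in published comparisons, absolute p-values are
  not comparable across analyses that chose differently.
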