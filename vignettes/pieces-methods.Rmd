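---
title: "Methods: models, conventions and design choices in pieces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in pieces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pieces)
```

This vignette documents the models implemented in `pieces`, the
conventions adopted where the literature leaves room, and the reasoning
behind the package's numerical and design choices. It states no
empirical results beyond what the test suite and the acceptance script
themselves compute.

## The priority index

The PIECES score of a candidate taxon is

$$\mathrm{PIECES} = 100\,(w_1\,\mathrm{SB} + w_2\,\mathrm{LC} +
w_3\,\mathrm{GE} + w_4\,\mathrm{ED}), \qquad w_i \ge 0,\ \textstyle\sum_i w_i = 1,$$

with every component normalized to $[0,1]$ so the score spans 0–100.

**Collection deficits (SB, LC).** Counts of seed-bank and
living-collection records are transformed as
$1 - \ln(x+1)/\ln(x_{\max}+1)$. The logarithm encodes diminishing
returns — the step from 0 to 1 collections matters far more than from 20
to 21 — and the reverse scaling makes *absence* score highest. The
denominators ($x_{\max}$ per collection type) are always computed over
the **full candidate pool**, never a selected subset, and are recomputed
for every input table; subsetting the pool therefore changes scores, by
design, because deficits are relative to what the pool's best-covered
taxon shows is attainable.

**Threat (GE).** Ordinal ranks map linearly:
R1 = 1, R2 = 0.75, R3 = 0.5, R4 = 0.25, R5 = 0. The same ladder scaled
by 4 (R1 = 4 … R5 = 0) is the integer "threat level" used by the EDGE
score and by ROI's mean threat rank. Extending the level scale to
R5 = 0 (rather than leaving secure taxa undefined) keeps every
candidate scoreable; a selection containing R5 taxa simply dilutes its
mean threat toward 0.

**Distinctiveness (ED).** Raw fair-proportion ED (below) is min–max
scaled over the pool. Min–max (rather than max-only) scaling is used so
that the least distinct taxon anchors 0 exactly; with max-only scaling
the ED component would never reach 0 and weight $w_4$ would leak a
constant into every score.

**Weights.** `published_weights()` = (0.4623, 0.0771, 0.1979, 0.2627)
for (SB, LC, GE, ED) is the default. These values are treated as given
constants of the North American angiosperm analysis; the elicitation
session behind them is not reproducible from any printed matrix, so
`ahp_weights()` exists to elicit *new* weights, not to re-derive these.

## Evolutionary distinctiveness

`fair_proportion()` assigns each edge's length in equal shares to the
tips descending from it; a tip's ED is the sum of its shares. The
values conserve total branch length exactly (the invariant the test
suite asserts on random trees), with any root edge excluded — a root
edge is shared by every tip and cannot distinguish among them.

**Polytomy correction.** Unresolved nodes inflate ED: each daughter of
a $c$-way polytomy carries a full pendant branch where a resolved tree
would let daughters share internal edges. The correction named in the
EDGE literature is cited there without an algebraic definition, so this
package implements a documented multiplier of its own: every edge whose
parent has $c > 2$ children contributes $2/c$ of its length. The factor
is exactly 1 on bifurcating trees (the testable contract), strictly
down-weights polytomy daughters, and reduces smoothly as resolution
improves. Corrected ED no longer sums to total branch length; it is an
index, not a partition. The correction defaults to off in
`ed_scores()`; the pipeline turns it on automatically when the input
tree has polytomies. Users comparing against other ED implementations
should expect agreement only on resolved trees.

## Phylogenetic signal: the D statistic

For a binary trait, the raw statistic $\Sigma d$ accumulates, over
internal nodes, the absolute deviations of each child's estimated value
from the node's value, where a node's value is the **plain mean of its
children's values** computed tip-to-root with unit branch lengths. For
a bifurcation this is $|l - r|$; the plain-mean rule extends it to
polytomies so that heavily unresolved trees (common after grafting) are
first-class. Nodal estimation deliberately ignores the tree's branch
lengths — the standardization below absorbs any scheme-dependent
scaling as long as observed and null $\Sigma d$ use the identical
scheme.

$D$ standardizes the observed $\Sigma d$ between two simulated
expectations at matched prevalence:

$$D = \frac{\Sigma d_{\mathrm{obs}} - \overline{\Sigma d}_{B}}
{\overline{\Sigma d}_{R} - \overline{\Sigma d}_{B}}$$

* $R$: tip permutations (phylogenetically random; $E[D] = 1$);
* $B$: threshold Brownian traits — a continuous character with
  per-edge Gaussian increments of variance proportional to edge length
  (real branch lengths; unit fallback when all lengths are zero),
  binarized by **rank**: the $n_1$ largest tip values become 1. Rank
  thresholding guarantees the exact prevalence match the statistic
  requires, unlike a fixed cut value ($E[D] = 0$).

One-sided p-values are null proportions: `p_random` = fraction of
permutation replicates with $\Sigma d \le$ observed (tests $D < 1$),
`p_brownian` = fraction of Brownian replicates with $\Sigma d \ge$
observed (tests $D > 0$). The default `n_perm` is 1000; calibration
tests run at 100. Degenerate caution: on a pure star tree $\Sigma d$
depends only on prevalence, both null means coincide and $D$ is
undefined (0/0); the resolution sweep therefore loses meaning at total
collapse, which is also the scientifically expected endpoint — no
topology, no signal.

`resolution_sensitivity()` re-estimates $D$ on trees degraded with
`collapse_short_edges()`. The collapse removes **internal** edges
shorter than the threshold (the `di2multi` convention); tips are never
deleted, surviving lengths unchanged, so the operation is idempotent at
a fixed threshold and resolution is non-increasing in the threshold.

## Tree manipulation

Grafting attaches a missing taxon as a new child of its genus's crown
node (the MRCA of the genus's tips) with pendant length equal to the
crown depth, defined as the **maximum** node-to-descendant-tip distance
— on ultrametric trees this is the unique crown age, and the definition
stays well-posed on non-ultrametric inputs. Grafts therefore preserve
ultrametricity (asserted to $10^{-9}$ in tests). Taxa without congeners
fall back to the family crown. A genus represented by a single tip has
no crown; the default rule bisects that tip's terminal edge and attaches
the new taxon there, preserving the genus's monophyly (a family-crown
fallback is available via `singleton = "family"`). Grafts are applied
sequentially, so earlier grafts can provide congeners for later ones.

## Set similarity

PhyloSor is $2\,BL_{shared}/(BL_A + BL_B)$ where a set's branch length
sums the edges on the union of **root-to-tip** paths of its members
(root-spanning convention, root edge excluded). The alternative —
spanning only to the set's MRCA — gives different values; root-spanning
matches the common community-phylogenetics implementation, and the test
suite pins the convention against an independent implementation.
Taxonomic overlap is plain Jaccard.

## AHP numerics

Weights are the principal right eigenvector of the reciprocal
comparison matrix, normalized to sum 1 (strictly positive by
Perron–Frobenius), computed by power iteration from the uniform vector
(tolerance $10^{-12}$ on the sup-norm, max 10,000 iterations) with a
dense `eigen()` fallback — power iteration is reproducible and
dependency-light, and the fallback covers pathological
non-convergence. $\lambda_{\max}$ is the Rayleigh-style mean of
$A w / w$. The consistency ratio uses Saaty's random indices for
$n \le 10$; CR > 0.1 produces a warning, never an error, since a
consistency gate is a policy choice the analyst should make knowingly.
Saaty-scale bounds ($[1/9, 9]$) are enforced only on request.

## Schemes, ROI and trade-off analysis

Five selection schemes are implemented. PIECES, EDGE and
ED + Seed Bank (top-ED among taxa with no seed collections) are
deterministic, with ties broken by ascending taxon label so repeated
runs agree exactly. Endangered and Ex Situ admit many equivalent
solutions, so they return families of uniformly random subsets
(default 100 replicates) from their candidate pools — the most
threatened stratum and the fully uncollected pool respectively — and
their ROI and similarities are reported as means across replicates.
When the top threat stratum holds fewer than $n$ taxa, Endangered
includes all of it and samples the remainder from the next stratum
(R1 → R2 → …); the rule keeps the scheme total even though typical
pools have a surplus of R1 taxa.

ROI of a selection: novel seed-bank additions (`n_seed == 0` among
selected), novel living-collection additions, mean threat level (0–4),
mean raw ED. Weight-space analysis samples weight vectors uniformly on
the 3-simplex — a flat Dirichlet via normalized unit-rate exponentials,
the natural "no information beyond $\sum w = 1$" choice — and maps each
through scoring, top-$n$ selection and ROI. Pareto frontiers are
computed per objective pair by sort-and-scan (equivalent to the
$O(k^2)$ dominance filter, which the tests use as an oracle), with all
four ROI objectives oriented "more is better".

The gap table cross-tabulates collection status (seed only / living
only / both / neither) against rank and applies Pearson's chi-squared
test without continuity correction.

## Synthetic data

The generator exists so every analysis is testable without downloads.
`yule_tree()` produces ultrametric pure-birth trees. Defaults in
`synth_params()` were chosen once to echo a continental flora:

* rank proportions = the North American angiosperm totals
  (1490, 2025, 3352, 5582, 6317)/18766;
* per-rank zero-inflation of counts = the observed per-rank absence
  fractions for seed banks and living collections, so about a third of
  taxa carry seed collections and about half carry living collections;
* positive counts are geometric with mean 3 (seed) and 6 (living) —
  one-parameter, over-dispersed, easy to moment-match, and with a tail
  long enough to produce the occasional taxon held in hundreds of
  living collections, as real pools show;
* `signal_strength = 0.3`, a mild Brownian/noise variance ratio in the
  latent vulnerability trait, consistent with threat ranks that are
  clustered but much closer to random than to Brownian ($D$ in the
  0.8–0.9 region).

Ranks come from **exact-quota thresholding** of the latent trait rather
than independent per-tip draws, removing a nuisance source of test
flakiness; counts are then conditionally independent given rank. What
the generator does *not* emulate: real taxonomy (genera/families),
geographic structure, collection counts correlated with ED or with each
other beyond rank, non-ultrametric trees, or sampling error in ranks.
Passing tests on these fixtures validate the computational contracts
and the statistical calibration of the methods — not the biological
conclusions one would draw from any real pool.

## Problem sizes and tolerances

The test and acceptance runs use sizes chosen to make the checked
properties statistically crisp: a 128-tip Yule tree with 100 traits ×
100 permutations for D calibration (mean D within [0.85, 1.15] under
shuffling, [−0.15, 0.15] under Brownian thresholding), 200 random trees
for branch-length conservation (relative error < $10^{-6}$), 100 random
clouds up to 1000 points for Pareto/oracle equivalence, a 500-tip
integration fixture for scheme-level checks, and 100,000 draws for the
simplex-moment check (coordinate means within 0.25 ± 0.005). Exact
worked examples (Σd = 1 vs 2 on the four-tip tree, PhyloSor = 4/7,
component score 73.73 under the published weights) are asserted at
floating-point precision.

## Known limitations

* The polytomy correction is this package's own documented factor;
  other ED implementations using a different correction will disagree
  on unresolved trees.
* $\Sigma d$ uses unstandardized plain-mean nodal estimation; raw
  $\Sigma d$ values are not comparable across estimation schemes, only
  $D$ is.
* The Endangered/ExSitu similarity means pair replicate draws
  positionally when both schemes are families; with the default 100
  draws the pairing choice is negligible.
* No cost model: prioritization ignores species-specific acquisition
  and maintenance costs, and `n` is a pure count, not a budget.
* Chi-squared gap tests assume large expected cell counts; small pools
  trigger the standard approximation warning.
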