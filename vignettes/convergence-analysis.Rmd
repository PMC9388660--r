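---
title: "Cell-type-specific PPI convergence analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-specific PPI convergence analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiconverge)
```

## The model

`ppiconverge` asks a network question: given a set of seed genes — for
instance, genes translationally dysregulated in a specific neuron type,
or disease-risk genes — which genes do the seeds' protein-interaction
neighborhoods converge on?

The statistic is deliberately simple. On an undirected PPI graph, the
*community* of a seed is its closed 2-hop ego neighborhood: all nodes at
shortest-path distance ≤ 2, including the seed itself (distance 0
qualifies, so every seed belongs to its own community). For a gene $g$,
the *membership number* $m(g)$ counts the seed communities containing
$g$, and the *membership proportion* is $p(g) = m(g)/C$ where $C$ is the
number of communities — the number of seeds actually present in the
filtered graph. Seeds absent from the graph induce no community and are
excluded from $C$, but are restored to the final gene list with a flag.

### Why a null model is needed

$p(g)$ confounds convergence with connectivity: a high-degree gene sits
in many communities of *any* seed set. The null model therefore asks how
often $g$ would be a member under $R$ random seed sets of the same size
$k$, drawn uniformly without replacement from the graph's own node set
(the space in which the observed statistic lives; a user-supplied
universe can be substituted). Each node gets a null mean $\mu(g)$ and
standard deviation $\sigma(g)$ of its membership proportion, and the
*fold enrichment* — the connectivity value used for scoring — is
$p(g)/\mu(g)$.

By symmetry of undirected shortest paths, gene $g$ lies in seed $s$'s
community exactly when $s$ lies in $g$'s 2-ball. The number of random
seeds in $g$'s ball of size $m_g$ (out of $N$ nodes) is hypergeometric,
so the null is available in closed form:

$$\mathrm{E}[p(g)] = \frac{m_g}{N}, \qquad
  \mathrm{Var}[p(g)] = \frac{1}{k}\,\frac{m_g}{N}
  \Bigl(1-\frac{m_g}{N}\Bigr)\frac{N-k}{N-1}.$$

`closed_form_null()` implements this as an exact, randomness-free oracle;
`simulate_null()` is the Monte Carlo version (default $R = 1000$), kept
as the reference implementation because it generalizes to any sampling
universe and matches the procedure the statistics are defined by. The
test suite checks that the two agree within Monte Carlo error and are
identical on complete graphs. The same ball symmetry makes the
simulation cheap: one pass tabulates each replicate from precomputed ego
balls, so an interactome-scale null (4,400 nodes, 10,000 edges, $k =
470$, $R = 1000$) runs in seconds; the largest problem exercised by the
tests is exactly that size.

### Filters and list expansion

Two exclusion rules define the convergent set:

* **3-SD filter** — exclude genes with $p(g) < \mu(g) + 3\sigma(g)$. A
  gene exactly at the threshold is retained (the rule excludes "less
  than"). With $\sigma(g) = 0$ (nodes never sampled into any community)
  this degenerates to $p(g) > 0$, the intended limiting behavior.
* **Membership filter** — exclude genes with membership number 1:
  presence in a single community is not convergence, however
  statistically surprising.

Input seed genes failing either rule are appended back to the list with
`is_restored_seed = TRUE`, carrying their raw statistics (zeros when the
gene is absent from the graph); restoration re-adds them to the *list*,
not to the passing statistics. Fold enrichment divides by
$\max(\mu(g),\ 1/(R \cdot C))$ — $1/(RC)$ being the smallest nonzero
proportion resolvable at $R$ replicates — so enrichment stays finite
without disturbing the ranking.

### Composite prioritization

Retained genes are scored on three variables: connectivity (fold
enrichment), expression (mean atlas abundance over the target clusters),
and relative enrichment (target over off-target mean expression,
pseudocount-stabilized). Each variable is divided by its maximum over
the scored set and the three quotients are summed, giving a composite in
$[0, 3]$; a gene holding all three maxima scores exactly 3.0. Ranking is
deterministic (ties broken alphabetically) and the default report takes
the top 25. Only genes passing both filters are scored by default;
`include_restored_seeds = TRUE` widens the scored set to the expanded
list, which changes the normalization maxima and is therefore exposed as
an explicit switch.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_publications`, `min_methods` | 2, 2 | evidence filter: an edge needs ≥ 2 distinct publications *or* ≥ 2 distinct experimental systems (disjunctive, per-edge distinct counts) |
| `taxon` | 9606 | both interactors must carry this NCBI taxon id |
| `min_level` | 0 | presence threshold: expression strictly above this in ≥ 1 target cluster |
| `radius` | 2 | community radius in edges (unweighted hops) |
| `replicates` | 1000 | Monte Carlo seed sets |
| `sd_multiplier` | 3 | SD-filter multiplier |
| `min_membership` | 2 | minimum membership number |
| `top_n` | 25 | final target list size |
| `pseudocount` | `1e-6 × max(atlas)` | enrichment stabilizer; proportional to the atlas scale, so enrichment is invariant under rescaling |

## Design decisions

Where the procedure left genuine choices, the package resolves them as
follows, and exposes each as configuration:

* **Symbol case.** All gene symbols are upper-cased on read. Human
  interaction dumps use upper-case symbols while mouse seed lists use
  title case; case-insensitive matching is the sensible default, and an
  explicit two-column symbol map handles anything beyond it
  (cross-species homology is user-supplied, never inferred).
* **Evidence disjunction.** "2 or more publications or experimental
  methods" is read literally as a disjunction over distinct counts.
  Methods are counted as distinct experimental-system strings (not
  system *types*); both physical and genetic evidence count by default,
  with a switch to restrict.
* **Self-loops** are removed at collapse: the community statistic is
  about distances between distinct genes.
* **Null sampling universe** is the filtered graph's node set, sampled
  without replacement within a set, independently across replicates.
  The null SD uses the sample divisor $R - 1$.
* **Missing atlas genes** score abundance 0 and enrichment 0 and are
  flagged, keeping the pipeline total rather than dropping genes
  silently.
* **Malformed evidence rows** are skipped and counted, not fatal —
  public interaction dumps contain them; structural errors (a missing
  mapped column, a negative atlas value) *are* fatal.

Published node/edge counts for any specific interactome release are
version-dependent, so the pipeline treats auditability as the substitute
for exact reproduction: every stage writes its table, its counts go to a
log, and the run manifest records the full configuration including the
RNG seed. Reruns with an identical manifest are bit-identical.

## The synthetic-data generators

Three generators emit the exact file formats the pipeline consumes, with
planted ground truth:

* `generate_interaction_table()` samples gene pairs and controls evidence
  multiplicity: extra-publication rows with probability `p_second_pub`,
  extra-method rows with `p_second_method`, off-taxon rows with
  `p_off_taxon`. Its ground-truth table records distinct on-taxon counts
  per pair, so collapse/filter results can be checked exactly.
* `generate_atlas()` draws log-normal baselines and multiplies designated
  genes' target-cluster values by a known factor; at zero noise the
  enrichment ratio recovers the factor exactly.
* `generate_planted_convergence()` wires hub genes to every seed on top
  of an Erdős–Rényi background (a degree-preserving configuration-model
  rewiring is available for stress tests), forcing each hub's membership
  proportion to 1.0 at radius 2.

What the generators emulate is the *statistical structure the analysis
assumes*: evidence multiplicity, organism mixing, non-negative expression
with planted enrichment, and known convergent hubs. They do not emulate
real interactome degree distributions (which are heavy-tailed, not
binomial), literature ascertainment bias, or real cluster covariance
structure — so green tests demonstrate algorithmic correctness, not
biological validity on any particular data release.

A property worth knowing when interpreting fold enrichments: a hub
adjacent to *every* seed necessarily has a large 2-hop ball, hence a
large null expectation $m_g/N$ and a modest fold enrichment — under the
hypergeometric null, extreme folds belong to low-degree genes whose balls
are small. Planted hubs are reliably *retained* (proportion 1.0 passes
both filters) and rise to the top of the *composite* score when they also
carry expression signal, but fold enrichment alone ranks small-ball
bystanders above them. This is intrinsic to ratio-to-expectation
statistics on graphs, and is why prioritization uses the composite rather
than connectivity alone.

## Numerical and degenerate-input choices

* Distances are unweighted hop counts; `radius = 0` gives the singleton
  community.
* Membership maps are sparse: genes in no community are simply absent
  from the table (at interactome scale most nodes are members of
  something, but the representation does not assume it).
* An empty post-filter edge set, an empty retained set, a seed list
  disjoint from the graph, and a single-node graph ($N = 1$, variance
  defined as 0) are each handled explicitly — the first warns, the next
  two are fatal errors naming the stage, the last is exact.
* Tie-breaks in ranking are alphabetical, making every output ordering
  deterministic.
* All randomness flows through explicit integer seeds; no generator or
  simulation touches global RNG state (the caller's `.Random.seed` is
  saved and restored).

## Known limitations

* "Presence" in a cell type at `min_level = 0` is permissive; real
  atlases with ambient contamination may need a positive threshold.
* The null randomizes seed identity only; it does not rewire the graph,
  so it controls for seed-set size and node position but not for
  modular structure correlated with the seed set itself
  (degree-preserving *edge* nulls are out of scope).
* No multiple-testing correction is applied to the SD filter — it is a
  screening rule, not a calibrated test.
* Overlap reports count genes; they attach no significance to overlaps.
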