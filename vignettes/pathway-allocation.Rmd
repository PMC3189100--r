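---
title: "Allocating multi-membership genes to pathways: model, searches and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocating multi-membership genes to pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathalloc)
```

## The problem

A large fraction of the genes annotated to biochemical pathways belong to
more than one pathway. When a microarray (or RNA-seq contrast) reports such
a *multi-membership* gene as up- or down-regulated, the measurement is a
net effect: the cell may be raising the gene's product for one pathway
while another pathway it serves is being shut down. Conventional pathway
visualisation superimposes the expression value on *every* member pathway,
which fills pathways with apparently contradictory genes and obscures
their state.

`pathalloc` treats the assignment itself as the unknown. Given a
membership snapshot and one experiment's log2 ratios, it searches for the
*allocation* of each expressed multi-membership gene to a nonempty subset
of its member pathways that maximises per-pathway expression consensus,
and provides statistics to judge how reproducible and how far from chance
the resulting allocations are.

## Model and notation

- \(P \in \{0,1\}^{N \times M}\): the membership snapshot; \(p_{ij} = 1\)
  iff gene \(i\) is annotated to pathway \(j\). \(P\) is immutable.
- \(A \in \{0,1\}^{N \times M}\) with \(P - A \in \{0,1\}^{N \times M}\):
  an allocation. A gene can be dropped from a pathway, never added beyond
  \(P\).
- \(X(i) \in \{+1, -1, 0\}\): the discretised state of gene \(i\),
  \(+1\) if its log2 ratio exceeds the threshold \(c\), \(-1\) below
  \(-c\), else 0. Both inequalities are strict, so a ratio exactly at
  \(\pm c\) is stable.

An allocation is **valid** when every expressed gene keeps at least one
membership (an all-zero row is rejected), expressed single-membership
genes keep their only pathway, stable genes are allocated nowhere, and —
in module mode — no gene occupies both members of an opposing module pair.

The objective is the consensus fitness
\[
F(A) \;=\; \sum_{j=1}^{M} \Bigl|\sum_{i=1}^{N} a_{ij}\,X(i)\Bigr|,
\]
the sum over pathways of the absolute difference between allocated up- and
down-regulated genes. Written with the inner sum signed and un-absolved,
the objective would be maximised degenerately by allocating every up gene
everywhere and deleting every down gene; the absolute per-pathway net is
what rewards grouping genes of *like* expression and separating
contradicting ones, and it matches the intended behaviour (down-regulated
genes are retained and grouped, not discarded). The signed nets remain
available via `pathway_nets()` so the raw signed sum is recoverable.

## Searches

All three metaheuristics explore only valid allocations, starting from a
uniformly random one (each free gene's row drawn uniformly from its
\(2^n - 1\) nonzero strings — the same null model used by the Hamming
statistics below).

**Hill climbing** (`method = "hc"`). Each iteration picks an expressed
multi-membership gene uniformly, one of its member pathways uniformly, and
toggles that bit; a removal that empties the row triggers reassignment to
a uniformly chosen member pathway. The move is kept unless it *strictly*
decreases the fitness — plateau moves are accepted, which lets the search
drift across equal-fitness ridges.

**Simulated annealing** (`method = "sa"`, the default). Identical moves,
but a move that loses \(\Delta F\) fitness is accepted with probability
\(e^{-\Delta F / T_t}\) under the geometric schedule
\(T_t = T_0 \lambda^t\), \(\lambda = e^{(\log T_{final} - \log T_0)/I}\).
Defaults: \(T_0 = 1\), \(T_{final} = 0.01\), \(I = 10\,000\) iterations
(\(\lambda \approx 0.99954\)). The best-so-far allocation is tracked and
returned, so late high-temperature excursions cannot lose the optimum.
The engine draws the acceptance uniform for every worsening proposal in
both methods, so annealing at vanishing temperature reproduces hill
climbing bit-for-bit on the same seed — a useful equivalence check.

**Genetic algorithm** (`method = "ga"`). A population (default 100) of
valid allocations evolves for a number of generations (default 400). Each
generation: every parent is mutated (each free gene flips one uniformly
chosen member bit with probability \(1/n_{free}\), i.e. about one gene per
individual; flips that would empty a row are redrawn); the mutated
individuals are paired by a random permutation and consecutive pairs
undergo single-point crossover on the gene list (rows inherited whole, so
children are always valid; an odd leftover passes through unchanged);
parents, mutants and offspring are pooled and the fittest
`pop_size` survive. Elitism makes the best-per-generation trace
non-decreasing. Several pairing conventions are possible for the
crossover step; the random-permutation pairing is the cleanest
well-defined choice and is what we implement.

In **module mode**, a table of opposing module pairs (glycolysis versus
gluconeogenesis being the canonical example: the two directions of a
futile cycle are never active together) constrains shared genes to at most
one side of each pair. Whenever a move or mutation adds a gene to one side
it is removed from the other, including after forced reassignment, and
random initial rows violating a pair are resampled — resampling rather
than deterministic repair keeps the initial distribution uniform over
admissible rows.

Every search takes a `seed` and is bit-reproducible from it. Fitness
deltas are computed incrementally from the affected pathway nets; a
property test asserts the increment always equals full recomputation.

## How far from chance is an agreement?

Two runs of a stochastic search rarely return identical allocations. To
calibrate observed differences we use the exact distribution of the
Hamming distance between two *independent uniformly random valid*
allocations. For one gene with \(n\) member pathways there are
\((2^n - 1)^2\) ordered pairs of valid rows; the number at distance 0 is
\(2^n - 1\) and at distance \(r \ge 1\) it is \(\binom{n}{r}(2^n - 2)\)
(choose the differing positions; choose the first string freely, which
fixes the second; discard the two pairs containing the all-zero string).
These counts sum to \((2^n - 1)^2\) — asserted exactly for
\(n = 1..12\) in the tests, and cross-checked against exhaustive
enumeration for \(n \le 5\).

Distances add across genes, so the instance-level null is the convolution
of per-gene distributions (`combine_hamming_nulls()`,
`allocation_null()`). Counts are kept as exact integers in doubles (exact
up to \(2^{53}\), i.e. per-gene \(n \le 26\)); probabilities are ratios of
these integers. `null_tail_probability()` reports the lower tail — the
probability that chance alone would bring two allocations at least this
close; the upper tail is available with `lower = FALSE`.

The normalised similarity
\(S(D, E) = 1 - d(D, E)/(NM)\) rescales the total Hamming distance
\(d\) to \([0, 1]\).

## The fuzzy adjusted Rand index

Hamming distance is label-sensitive: two runs that group the same genes
together but swap which pathway hosts each group look maximally different.
A pair-counting index answers the complementary question — are gene
*pairs* kept together or apart consistently?

Because an allocation may place a gene in several pathways, the classical
adjusted Rand index (ARI) does not apply directly. We use a pair-counting
fuzzy extension with equal weights: gene \(g\) gets membership degree
\(1/|\text{row}_g|\) in each allocated pathway; the co-membership degree
of a pair is \(\psi(g, g') = \sum_k \min(u_{gk}, u_{g'k})\); treating
"together" as a fuzzy set over pairs, the four Rand counts become fuzzy
cardinalities (intersection via \(\min\), differences one-sided) and the
index is the pair-counting form
\(2(ad - bc)/((a{+}b)(b{+}d) + (a{+}c)(c{+}d))\).

This variant was chosen for three properties, which are its tested
contract: it is exactly 1 for identical allocations; it reduces to the
classical ARI whenever every row has a single 1 (verified against an
independent ARI implementation to \(10^{-10}\)); and on the pile-swapping
fixture above it stays at 1 while \(S\) drops to 0. One honest caveat: for
*heavily multi-assigned random* allocations its baseline is positive
(around 0.4 in our simulations) rather than 0 — two random overlapping
allocations genuinely co-allocate many pairs — so near-zero expectation
holds only in the crisp case, and comparisons of fuzzy values should be
made against that baseline, not against 0.

## Enrichment

`enrichment_pvalue(G, C, n, k)` is the standard hypergeometric upper tail
— the probability of at least \(k\) affected genes in a set of \(n\),
when \(C\) of the \(G\) platform genes are affected — evaluated with
`stats::phyper()` (log-space internally), and cross-checked in the tests
against a direct log-space combinatorial sum.

## The synthetic generator

Real platform-scale datasets and a pathway-database snapshot are outside
the package's scope, so benchmarking rests on `simulate_instance()`,
which emulates exactly the premise the method relies on: each pathway has
a latent direction \(\pm 1\); each gene contributes to a planted subset of
its member pathways; its log2 ratio is the *net effect* of those
directions with half-normal noise,
\(\text{ratio} = \mathrm{sign}(\text{net}) \cdot
(c + e + |\mathcal{N}(0, \sigma)|)\).

Choices worth recording:

- **Effect margin `e`** (default \(0.5c\)): without it a zero-noise gene
  would sit exactly at the threshold and, under the strict inequalities,
  be classified stable; the margin is the generator's effect size above
  the calling threshold, a realistic property of genuinely regulated
  genes.
- **Coherent planting** (default): each multi-membership gene is planted
  into *all* member pathways sharing one sampled direction. Under the
  consensus objective this makes the planted allocation the unique
  optimum (each pathway's net sign is anchored by its single-membership
  genes), which is precisely what a parameter-recovery benchmark needs:
  the question "did the search find the planted truth?" has a
  well-defined answer. `planting = "random"` plants a uniform nonempty
  subset instead, allowing opposing contributions to cancel into stable
  genes (net 0 draws a ratio uniformly inside \((-c, c)\)).
- **Equal per-pathway weights** in the net effect; noise additive on the
  log2 scale. This is the simplest model consistent with the net-effect
  premise; it does not attempt probe-level noise, normalisation artefacts,
  or correlated gene behaviour, so passing recovery tests demonstrates
  correctness of the machinery, not performance on real arrays.
- Stable genes keep all-zero rows in the returned planted allocation (a
  stable gene's planted subset is unobservable and takes no part in the
  search), keeping the planted allocation valid by construction.

The default conditions (60 genes, 8 pathways, 40% multi-membership, noise
\(\sigma = 0.25c\)) give instances on which annealing recovers the
planted allocation with Hamming similarity above 0.95 in at least 9 of 10
seeds — one of the package's acceptance properties.

## Numerical and design choices

- Ties at exactly \(\pm c\) are stable (strict inequalities).
- Genes present in expression but absent from the membership are dropped
  with a message; membership genes without a measurement are treated as
  stable.
- Hill climbing accepts equal-fitness moves (restores only on strict
  decrease); ties between equal-fitness allocations are resolved by the
  search dynamics, never by a secondary objective.
- \(\Delta F\) in the acceptance probability is the positive fitness
  loss; improving or equal moves bypass the draw... except that the
  uniform *is* drawn for every worsening proposal in both local searches,
  to keep their seed streams aligned (see above).
- GA selection sorts the pooled population by fitness with a stable
  order, so equal-fitness survivors keep their insertion order and runs
  are deterministic.
- Forced reassignment after an emptying removal may choose the pathway
  just vacated; the move is then a no-op and is accepted at zero delta —
  a deliberate choice that keeps the move kernel simple and symmetric.
- Search traces record the best-so-far fitness per iteration (HC/SA) or
  per generation (GA); `fitness_trace()` additionally reports cumulative
  fitness-evaluation counts so the population method can be compared with
  the single-solution methods on a common axis.

## Sizes used by the test suite

The oracle-equivalence suite enumerates instances with at most 12 free
allocation bits (where exhaustive search is exact) and runs annealing for
1500 iterations and the GA at 40 individuals for 60 generations; these
are deliberately smaller than the full-scale defaults, which is
conservative for a convergence claim. Recovery and consistency suites use
the default synthetic conditions above with full 10 000-iteration
annealing runs.

## Limitations

- Only set membership is modelled — no pathway topology, reaction
  stoichiometry or gene weights; repressors and isoenzymes that
  legitimately contradict their pathway's trend are not special-cased.
- One experiment at a time; no cross-experiment borrowing.
- Full-platform results (fitness tables, cross-run index statistics on
  real arrays) require platform data and a pathway-database snapshot and
  are outside the package's scope; the synthetic property suites above
  are their desk-scale counterparts.
- The fuzzy Rand baseline caveat noted above.

## A worked micro-example

```{r example}
sets <- read_gene_sets(pathalloc_example("trp_mini_synthetic.gmt"))
membership <- pathway_membership(sets)
expression <- read_expression(pathalloc_example("gsm513_trp_expression.tsv"))
fit <- allocate_genes(membership, expression, method = "sa",
                      iterations = 2000, seed = 42)
glance(fit)
pathway_summary(fit)
```

The down-regulated yqeF leaves the (up-regulated) tryptophan-metabolism
pathway for the degradation pathways it also serves, raising the
consensus fitness above the full-membership baseline.
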