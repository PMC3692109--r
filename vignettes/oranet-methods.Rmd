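---
title: "Methods: enrichment statistics and hierarchical network modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment statistics and hierarchical network modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oranet)
```

This vignette documents the statistical model behind `oranet`, the
parameters that matter and their defaults, the synthetic benchmarks the
package generates for itself, and the numerical and design choices made
where more than one defensible option existed.

## Over-representation analysis

### Model

An input gene list is modelled as a uniform draw without replacement from a
finite reference universe (the *reference set*): all genes that could have
appeared in the list — the genes on the assayed platform, or all genes of
the interaction network under study. Every count is taken **inside** this
universe: with universe size $N$, input size $n$, category size $m$ and
overlap $k$, the p-value is the hypergeometric upper tail
$P(X \ge k) = \sum_{i=k}^{\min(n,m)} \binom{m}{i}\binom{N-m}{n-i} / \binom{N}{n}$,
equal to the one-sided Fisher exact test on the 2×2 table
$(k,\; n-k,\; m-k,\; N-n-m+k)$. The implementation evaluates the tail in
log space (`stats::phyper`), so extreme enrichments in universes of $10^5$
genes keep non-zero p-values down to the smallest representable doubles.
The enrichment ratio $kN/(nm)$ reports effect size on the natural
observed/expected scale, independently of significance.

Choosing the universe is the analyst's main modelling decision: an input
list enriched against "all annotated genes" when it was drawn from a
2 000-gene panel will produce spurious hits. `run_ora()` therefore demands
an explicit reference and drops (with a warning, not an error) input genes
outside it — in practice signatures are occasionally contaminated with ids
the platform does not carry, and failing hard would be unhelpful.

### Multiple testing

Five corrections are supported: Bonferroni, Holm, Hochberg,
Benjamini–Hochberg (BH) and Benjamini–Yekutieli (BY) — the canonical
family-wise and FDR procedures in standard statistical practice; the
computation is delegated to `stats::p.adjust`. The multiplicity universe is
exactly the categories actually tested in the run: categories are first
intersected with the reference and size-filtered, then corrected as a
family. Correcting over categories that could never have been tested (empty
intersection, out-of-bounds size) would be anticonservative bookkeeping in
the opposite direction: the family must equal the tested hypotheses.

Defaults: BH at cutoff 0.05 on the adjusted scale; category size bounds
`min_size = 3`, `max_size = 2000` after intersection. Size bounds are
conventional ORA hygiene — one- and two-gene categories cannot be
meaningfully enriched, and multi-thousand-gene categories say little — and
both are exposed parameters, not hidden constants. The Top-K view
(`top_k()`, default 10) deliberately ignores the cutoff: it exists to help
choose a cutoff, not to apply one.

Ties in raw p-values (common, since overlap counts are discrete) are broken
by set id ascending, so reports are byte-reproducible.

### Identifier mapping

Platform and database identifiers are mapped to one canonical namespace
before analysis. A probe mapping to $k$ genes contributes all $k$ genes
(then the union is deduplicated); the alternatives — dropping ambiguous
probes, or keeping an arbitrary one — silently discard or distort signal.
The expansion is auditable: `map_ids()` reports every multi-target source
id and every unmapped id. Matching is exact-string and case-sensitive,
because case-folding merges distinct identifiers across platforms. Mapping
the input and the reference through the same table preserves the
input-⊆-reference contract.

## Hierarchical network modules

### Procedure

A protein–protein interaction network is treated as a simple undirected
graph. One decomposition round:

1. **Partition.** The walktrap algorithm merges communities
   agglomeratively by short-random-walk distance (walk length $t$); the
   returned partition is the cut of the merge dendrogram with maximum
   Newman–Girvan modularity
   $Q = \sum_c \left[ L_c/L - (d_c/2L)^2 \right]$.
2. **Null ensemble.** `n_random` degree-preserving randomizations of the
   network are produced by edge switching — pick two edges $(u,v),(x,y)$
   uniformly, rewire to $(u,y),(x,v)$, reject self-loops and multi-edges —
   and each is scored by its own best walktrap partition.
3. **Decision.** The empirical p-value with plus-one smoothing,
   $p = (1 + \#\{Q_\text{null} \ge Q_\text{obs}\})/(1 + n_\text{random})$,
   is compared with `alpha`; if significant, the network splits along the
   observed best partition and each block is processed recursively, until
   no sub-network shows modular organization.

Re-running walktrap per random network (rather than re-scoring the observed
partition on them) is essential: the null must be the distribution of the
*best achievable* modularity on degree-matched graphs, because even
Erdős–Rényi graphs admit partitions with substantially positive $Q$.

### Parameters

| parameter | default | role |
|---|---|---|
| `t` | 4 | walktrap walk length (the method's canonical default); short walks resolve local structure, long walks blur it |
| `n_random` | 1000 | null networks per test; tests and examples use 49–199 for desk-scale runtime and always record the value used |
| swaps per null | `10 * |E|` successful | standard mixing heuristic for degree-preserving rewiring |
| `alpha` | 0.05 | per-split significance level |
| `min_test_size` | 10 | smallest subnetwork worth testing — modularity comparisons on a handful of nodes are noise |
| `min_leaf_size` | 3 | blocks below this are flagged leaves and excluded from the exported gene sets — 1–2-gene sets are useless as ORA categories |

### Numerical and procedural choices

* **Plus-one p-values.** $(1+r)/(1+B)$ never returns 0, is a valid
  permutation-test estimator, and makes `n_random = 0` degenerate to
  $p = 1$ rather than an error.
* **Edge-switch termination.** Swap counts are *successful* swaps, but some
  graphs (a star, for example) admit no valid swap at all, so attempts are
  capped at 50× the requested count; a rigid graph is then returned
  unchanged, which is the correct null for it. Conservation — node set,
  every degree, edge count, simplicity — is asserted after every batch.
* **Seed discipline.** Null replicate $b$ of a test runs under
  `base_seed + b`; each significance test inside the recursion derives its
  seed from the tree's `base_seed` and a test counter. Identical inputs and
  seed give bit-identical trees and serialized outputs, and any single
  replicate can be regenerated in isolation.
* **Disconnected inputs.** Walktrap distances and modularity comparisons
  are ill-defined across components, so a disconnected (sub)network is
  first split into components *without* consuming a significance test; the
  component children carry no split record. Null networks produced by edge
  switching may themselves be disconnected; their best-partition modularity
  is still well-defined per component and is used as-is.
* **Determinism of block order.** Partition blocks (and component children)
  are sorted by their lexicographically smallest member, making tree
  traversal order, module ids and serialized bytes reproducible.
* **No correction across the recursion.** Each split is judged at the
  per-test `alpha`; the recursive procedure tests a data-dependent,
  nested family for which standard corrections do not directly apply. This
  is a known liberal choice: deep trees have inflated family-wise error,
  and downstream users should read deep splits with that in mind.

### Known limitations

* **The dendrogram cut is greedy, not globally optimal.** The maximum-$Q$
  cut is taken over the walktrap merge dendrogram, not over all partitions.
  On graphs with genuine community structure the two coincide, but on
  small unstructured graphs the dendrogram frequently does not contain the
  global maximizer at all (every horizontal cut can score $Q \le 0$ while
  some non-nested partition scores above it). The test suite measures this
  directly by exhaustive enumeration over all partitions of random
  ≤10-node graphs; exact optimality there is an aspiration the greedy
  algorithm does not meet, and the corresponding check documents the gap
  rather than papering over it.
* **Modularity maximization has a resolution preference.** On the
  two-level benchmark generated by `gen_two_level_network(2, 2, 16, 0.9,
  0.15, 0.01)`, the fine 4-group partition scores higher modularity than
  the coarse 2-super-module partition, so the root split recovers the four
  fine groups directly (ARI 1.0) and the recursion terminates at depth 1:
  the hierarchy is detected bottom-up as "root → fine groups", not as the
  nested "root → super-modules → groups" chain. Recovering coarse levels
  above the modularity optimum would require a different objective or
  scale parameter, which this method does not have.
* Weighted, directed and overlapping-community models are out of scope, as
  is any multiplicity control across the recursion (above).

### Ortholog transfer

Edges are transferred between organisms through a many-to-many ortholog
table: source edge $(a,b)$ yields every pair $(a',b')$ of orthologs,
self-pairs excluded, then the result is simplified. Expansion (rather than
one-to-one pruning) mirrors the identifier-mapping decision and keeps
paralog information; combining transferred with curated target-organism
edges is left to the caller so provenance stays visible.

## Enriched DAGs

Enrichment results over hierarchically organized categories (GO-style
ontologies, or the module trees above) are displayed as the sub-DAG induced
by the enriched categories plus *all* their ancestors: enriched nodes
flagged red, ancestors black, edges child→parent. All original edges among
retained nodes are kept — no transitive reduction — because multiple-parent
paths are real structure in ontologies. Chains of single-child ancestors
are likewise not collapsed. Multiple roots are supported and no artificial
root is injected (merging namespaces is the caller's choice). An analysis
with no significant categories yields an empty DAG, not an error. DOT
output is emitted in sorted order so identical inputs give identical bytes.

## Synthetic benchmarks: what they do and do not show

The generators produce the ground truth the test suite measures against:

* `gen_planted_partition(n_groups, group_size, p_in, p_out)` — independent
  Bernoulli edges, dense within planted groups ($p_{in} = 0.9$ in the
  standard benchmark of 3 groups × 10 nodes, $p_{out} = 0.05$); recovery is
  scored by adjusted Rand index.
* `gen_two_level_network(n_super, groups_per_super, group_size, p1, p2,
  p3)` — three edge densities (within group 0.9, within super-module 0.15,
  across 0.01 in the standard benchmark of 2 × 2 × 16) planting a
  two-scale structure.
* `gen_spiked_ora_fixture(N, n_sets, set_size, input_size, spike_overlap)`
  — uniform background sets plus one set with a forced input overlap
  (universe 1000, 50 sets of 20, input 50, overlap 15 in the standard
  fixture: fifteenfold enrichment over the expected single gene).

All generators are deterministic functions of their seed and regenerate
byte-identical files. These benchmarks emulate the *statistical* structure
the methods target — planted blocks, planted overlap — under independence
assumptions that real interaction data violate: real networks have
heavy-tailed degrees, geometric/clustering structure, ascertainment bias
toward well-studied proteins, and annotation categories that overlap
heavily and follow the same study bias. Passing these tests therefore
demonstrates correctness of the statistics and algorithms, not biological
validity of any particular module catalogue.

Simulation sizes used by the test suite (100-seed ensembles; 199 nulls for
type-I-error runs, 99 for hierarchical recovery, 49 for CLI determinism)
were chosen as the smallest ensembles at which the measured rates are
stable to re-seeding; `n_random = 1000` remains the analysis default.

## Degenerate inputs, by contract

* Empty GMT file → empty collection; empty collection → empty GMT file.
* `filter_collection` with an empty reference → error (a silent empty
  universe would make every downstream count meaningless).
* `hypergeom_pvalue(0, ...)` = 1 exactly; bounds violations are errors,
  not clamps.
* Single p-value → every correction is the identity.
* Single-block partitions score $Q = 0$ exactly; modularity of an edgeless
  graph is an error.
* `n_random = 0` → $p = 1$; a star network under edge switching → itself.
* No enriched categories → empty enriched DAG; unknown seed/category ids →
  error naming the offender.
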