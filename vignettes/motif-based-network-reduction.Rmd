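---
title: "Motif-based network reduction: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based network reduction: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supernoder)
```

## The problem

Large labeled networks — protein–protein interaction maps, food webs,
annotated infrastructure graphs — are often too dense to inspect directly.
One way to simplify them is to find *motifs*: small connected subgraphs,
with node labels taken into account, that occur more often than a chosen
threshold. Once a motif class is known to be over-represented, a set of
pairwise **node-disjoint** occurrences can be collapsed, each occurrence
becoming a single *supernode*, yielding a smaller network that preserves
every adjacency to the rest of the graph. Repeating the procedure produces
a hierarchy of progressively coarser summaries in which supernodes from one
round can themselves participate in the motifs of the next.

Formally, for a labeled graph $G = (N, E, \ell)$ and a motif size $k$:

1. **Enumeration** lists every connected induced $k$-node subgraph of $G$.
2. **Census** partitions the instances into label-preserving isomorphism
   classes and keeps the classes whose instance count (the F1 frequency
   measure, which allows overlapping occurrences) reaches a threshold $t$.
3. **Selection** extracts, within the frequent classes, a large set of
   instances that share no node (the F3, node-disjoint, measure). This is
   a maximum independent set (MIS) problem on the *overlap graph* whose
   vertices are instances and whose edges join instances sharing a node;
   MIS is NP-hard, so five heuristics are provided.
4. **Reduction** collapses each selected instance into a supernode and
   recurses on the reduced graph.

## Enumeration: exhaustive and sampled

`enumerate_k_subgraphs()` implements the ESU ("exact subgraph enumeration")
scheme: nodes are visited in increasing ID rank, each subgraph is grown only
through the *exclusive neighborhood* of its extension set, and neighbors with
rank below the root are blocked. This guarantees that every connected
$k$-subgraph is produced exactly once, which we verify in the test suite
against a brute-force oracle that filters all $\binom{|N|}{k}$ subsets for
connectivity.

Setting `sampling_probs` to per-depth probabilities $p_1, \dots, p_k < 1$
gives the randomized variant (RAND-ESU): each recursive extension at depth
$d$ survives with probability $p_d$, so the expected number of enumerated
instances is the exhaustive count times $\prod_d p_d$. The test suite checks
this expectation by Monte-Carlo over 200 seeds. On directed graphs,
connectivity is taken on the undirected skeleton.

## Census: signature hashing refined by isomorphism

Comparing all instance pairs is quadratic, so instances are first bucketed
by a cheap invariant, the **label/degree signature**: for every label
present in the instance, the number of nodes carrying it and the sums of
their in- and out-degrees *within the induced subgraph* (for undirected
graphs in = out = degree). The signature is isomorphism-invariant but not
complete — a 5-cycle and a triangle with a pendant 2-path, all nodes
sharing one label, have identical signatures — so each bucket is refined by
an explicit label-preserving isomorphism check, a backtracking matcher that
prunes candidate assignments on label and in/out degree. The test suite
includes exactly that collision fixture and compares the matcher against an
independent VF2 implementation.

A design decision worth stating: a class is *frequent* when its F1 count is
**at least** `t` (`f1_count >= t`), so `t` reads as "the minimum number of
occurrences required".

## Disjoint selection: five heuristics over the overlap graph

All five heuristics operate on the overlap graph and return pairwise
node-disjoint instances; they differ in how they trade solution size
against cost.

* **H1 (greedy shuffles, `n_shuffles = 5`)** — repeat `n_shuffles` times:
  shuffle the instances, scan once keeping every instance disjoint from
  those already kept; return the best scan. Always maximal; with 50
  shuffles it matches the exact optimum on the great majority of small
  random fixtures (measured in the acceptance run).
* **H2 (Ramsey recursion, `sample_size = 1000`)** — split the instances
  into chunks of `sample_size`, run the classical Ramsey independent-set
  recursion on each chunk, merge the survivors, and repeat until no overlap
  remains.
* **H3 (ranked elimination)** — rank instances by *motif degree*, the
  number of edges leaving the instance (host degree sum minus twice the
  induced edge count); for each node pick the lowest-degree instance
  containing it as a potential supernode, then scan in ascending degree
  order keeping instances disjoint from those kept. Deterministic and
  cheap, but a single pass can strand recoverable instances.
* **H4 (repeated ranked elimination)** — run H3, remove the covered nodes,
  and repeat on the instances that contain no already-covered node until a
  pass adds nothing. Always maximal, and strictly better than H3 on an
  adversarial chain fixture shipped with the tests.
* **H5 (sampled overlap elimination, `sample_size = 1000`)** — process
  overlap-graph edges in chunks; for each conflicting pair remove the
  endpoint with the larger *current* overlap degree (ties broken by
  instance key), until no conflicts remain.

Two small termination devices were added where the plain formulations can
stall: H2 and H5 double their effective chunk size whenever a full cycle
removes no conflict (so even `sample_size = 1` terminates), and both carry
a 100-round cap that raises a classed error rather than looping. An exact
branch-and-bound MIS (`exact_mis()`, capped at 25 instances) is included
purely as a yardstick.

## Collapse and recursion

`collapse_instances()` replaces each selected instance by a supernode named
`SN<iteration>_<counter>`, labeled with the alphabetically sorted
concatenation of member labels (e.g. `A-A-B`), re-attaching every external
edge to the supernode, merging duplicates and dropping the edges internal
to an instance. Node count therefore drops by exactly $(k-1)$ per selected
instance. Supernode membership is preserved in a provenance sidecar, and
serialized node rows carry a `#supernode` marker so reduced networks
round-trip through `read_network()` / `write_network()`.

`run_pipeline()` chains enumerate → census → select → collapse for a fixed
number of iterations, stopping early when no class is frequent or the
selection is empty. The result supports `tidy()` (per-iteration report),
`glance()` (one-row summary) and `autoplot()`.

## Label hierarchies

Node labels may come with an ancestor chain (e.g. an ontology path).
`map_labels(graph, hierarchy, level)` replaces each label by the entry at
position `min(level, chain length - 1)` of its chain, leaving topology
untouched. Coarser levels can only merge isomorphism classes, so the number
of instances belonging to frequent classes is non-decreasing in the level;
the number of distinct frequent *classes* typically grows on sparse labeled
fixtures but is not monotone in general, because classes can also merge.
`generate_hierarchy()` builds a balanced tree: level $\ell$ of a
depth-$d$, fanout-$f$ hierarchy has $\min(n, f^{\,d-1-\ell})$ categories,
with a single root for $d \ge 2$.

## The synthetic benchmark

`generate_planted_network()` plants `n_planted` disjoint copies of a
labeled motif (default: six `(A, A, B)` triangles) in an Erdős–Rényi
background of `n_background = 60` nodes with edge probability `0.01`,
background labels drawn from a 15-letter alphabet, and sparse
planted-to-background attachment edges. With `ensure_no_extra = TRUE` the
generator re-enumerates and resamples attachments until the planted class
has exactly `n_planted` occurrences, so "recover the planted motifs" has a
known right answer. The defaults are calibrated so that, at $k = 3$ and
$t = 6$, the planted class is the only frequent one; the generator emulates
the *structure* of the benchmark task (a known motif hidden in noise), not
the degree distribution or clustering of any real biological network.

## Determinism

Every ordering in the package uses radix (C-locale) sorting, all randomness
flows through a single optional `seed` argument per entry point, and
`run_pipeline()` seeds the whole run once so repeated runs are
byte-identical, for every heuristic. This is enforced by tests that compare
serialized output files across repeated runs.

## Limitations

* Enumeration is exponential in $k$; the package targets small motifs
  ($k$ of 3–5) on networks of up to a few thousand nodes, with RAND-ESU as
  the escape hatch for denser inputs.
* Only the F1 frequency measure and F3 disjointness are implemented;
  edge-disjoint (F2) counting is not.
* Graphs are simple: duplicate edges are deduplicated with a warning and
  self-loops are rejected.
* `exact_mis()` is a test yardstick, not a production solver; it refuses
  overlap graphs with more than 25 instances.
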