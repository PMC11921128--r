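---
title: "Flat phylogenies: the model, the parser, and the design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flat phylogenies: the model, the parser, and the design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloflat)
```

## The model

`phyloflat` stores a rooted phylogeny as parallel arrays indexed by a 0-based
node identifier: `parent`, `children`, and optionally `label` and `length`.
The load-bearing invariant is the identifier order: IDs are assigned in the
depth-first pre-order of the Newick text, so node 0 is the root and
`parent[u] < u` for every other node.  Everything else in the package is a
consequence of this ordering:

* **Traversals are index sweeps.**  Ascending IDs visit every node before
  its descendants; descending IDs visit every node after its descendants.
  Neither needs a stack, recursion, or pointer chasing.
* **MRCA is a parent-pointer race.**  Replacing the maximum-ID member of a
  query set with its parent strictly decreases the maximum and can never
  skip past a common ancestor, so it converges to the MRCA.
* **Ancestor walks are strictly decreasing**, which several validity checks
  exploit.

The price is immutability: any topology edit could break the ordering, so
trees are sealed after construction.  Labels and branch lengths remain
editable; rerooting, pruning and grafting are out of scope by design.

### Identifier width and the null sentinel

The maximal value of the configured width is reserved as the null node: under
32-bit IDs, values `0 .. 2^32 - 2` are usable and `2^32 - 1` means "no node",
giving `2^32 - 1` representable identifiers.  R has no unsigned integer
types, so identifiers live in doubles, which hold integers exactly up to
`2^53`.  The 32-bit configuration is therefore exact throughout.  Under the
64-bit configuration the sentinel `2^64 - 1` is stored as its nearest double
and the practical capacity is bounded by the exact-integer range of a double;
for any tree that fits in memory this is not a constraint, but it is an
honest difference from a native unsigned 64-bit integer.

### Branch-length conventions

Three conventions are deliberate and worth knowing:

* **A missing length token stores `0`.**  The length array is
  zero-initialized and sums stay well-defined; there is no missing-value
  marker, so a true zero-length edge and an absent length are
  indistinguishable.
* **A root length token (`(...)R:0.1;`) is parsed and stored at node 0 but
  excluded from `total_branch_length()` by default**, because a root edge is
  conventionally not part of the tree's branch-length sum; `include_root =
  TRUE` reverses this.  `avg_branch_length()` divides by the number of edges
  `N - 1`, not by `N`.
* **Single precision is the default length storage** (`tree_config()`),
  matching the memory-minimal intent: parsed lengths pass through a float
  cast, keeping about 7 significant digits.  `length_precision = "double"`
  disables the cast.  The writer emits 9 significant digits for single and
  17 for double, both of which round-trip their type exactly.

## The streaming parser

`parse_newick()` makes exactly one left-to-right pass over the input through
a fixed-size buffer (default 16 KiB, tunable per call).  Its transient state
is the buffer plus one in-flight token — the label or number currently being
read — so memory during parsing is independent of tree size; the parser
reports both quantities in the `"parser_stats"` attribute, and the test suite
asserts that a tenfold longer input leaves them unchanged.  Node IDs are
assigned the moment a node group opens, which is what makes the output order
a pre-order without any post-processing.

Dialect decisions (the Newick "standard" is folklore, so these are explicit):
single-quoted labels with `''` escaping; unquoted labels end at structural
characters or whitespace; square-bracket comments are skipped, never stored
or interpreted (so NHX annotations are dropped); underscores are kept
verbatim rather than converted to spaces, since that conversion is lossy;
scientific notation and signs are accepted in lengths, and negative lengths
— which occur in real trees — are kept with a warning rather than rejected;
a bare `";"` is the single-root tree; and exactly one tree per input is
allowed, with anything after the terminating semicolon an error.

## Traversal semantics

The descending-ID post-order visits a node's children right-to-left relative
to the Newick text.  It satisfies the defining post-order property — every
node after all of its descendants — and that property, not the conventional
child order, is what the sweep guarantees; no conventional stack-based
post-order is provided, because offering both would blur which one is O(1)
per step.  Level-order is a true breadth-first queue with children in stored
order.  In-order is only defined here for strictly binary trees (left child,
node, right child); requesting it on a multifurcating or unary tree is an
error rather than an improvised generalization, since any generalized
in-order would be a silent guess about semantics.

## Subtree extraction and distances

`extract_subtree()` copies a node and its descendants into a fresh tree with
a new pre-order numbering.  The new root's stored length is zeroed by default
— the cut edge is no longer part of the tree — with `keep_root_length` to
retain it.  `patristic_distance()` requires stored lengths and refuses to
invent unit lengths silently; `unit_lengths = TRUE` gives hop counts
explicitly.

## The level-order re-encoding

In the depth-first numbering, a node's children are scattered, so the child
structure needs either per-node lists (per-container overhead) or one flat
child array with 2 offsets per node (`build_flat_children()`).  Renumbering
the nodes breadth-first (`to_level_order()`) makes every node's children a
contiguous ID interval, so two integers per node — the minimum and maximum
child — encode the entire child structure: `N` parents plus `2N` range
entries, versus `N` parents plus `N - 1` child entries plus whatever
bookkeeping the child lists cost (`integer_storage_count()` makes this
accounting concrete; it counts only ID-typed slots and ignores container
overhead, which in R is substantial for a list of `N` small vectors).

The conversion is a post-parse transformation of the in-memory tree.  A
file-level level-order parser would need either the whole Newick string in
memory or multiple passes over the file; converting after a single-pass
parse keeps the parser streaming and still yields the compact encoding.
Sibling order under the renumbering follows stored child order, making the
permutation deterministic, and `parent[u] < u` still holds (breadth-first
also numbers parents before children), so the MRCA algorithm and the ID-sweep
traversal properties carry over unchanged — the test suite checks MRCA and
distance agreement between the two encodings through the permutation.
Leaves mark their empty child range with the null sentinel pair.

## The simulator

`simulate_tree()` implements a dual-birth branching process by Gillespie
simulation: each live lineage carries one of two splitting rates `rate_a`
or `rate_b` (per unit time); the waiting time to the next event is
exponential with rate equal to the sum of live rates; the splitting lineage
is chosen with probability proportional to its rate and replaced by one
daughter of each class.  Equal rates (the default, `rate_a = rate_b = 1`)
give the Yule pure-birth model, which is the configuration the package's
statistical tests target; unequal rates are supported and invariant-tested.
The root lineage carries `rate_a`.  Because only two distinct rates exist,
lineages are kept in two pools and each event is O(1), so simulation is
linear in tree size.

Simulation stops when `n_leaves` live lineages exist, i.e. at the final
split.  A lineage's branch length is the time from its creation to its
split, and lineages still alive at the stop are truncated at the stopping
time.  Two consequences are worth stating plainly.  First, truncation is
what makes the analytic check exact: while `k` lineages are alive the tree
accrues length at rate `k`, over an exponential stage of mean `1/(k·lambda)`,
so each of the `n - 1` stages contributes `1/lambda` in expectation and the
expected total branch length is `(n - 1)/lambda`; the test suite and the
acceptance script verify this at `n = 200`, `lambda = 1` over 500 replicates
against a three-standard-error band.  Second, truncating every live lineage
at the same stopping time already equalizes all root-to-leaf path lengths,
so under this stopping rule the `ultrametric` flag does not change the
lengths; it is accepted to make intent explicit at call sites, and the
equal-depth property is tested under both settings.  (The alternative —
giving pending lineages a full exponential draw — would break the
`(n - 1)/lambda` identity, doubling the expected total.)

Determinism: a seed pins the tree exactly (R's default Mersenne-Twister),
and `make_fixture_suite()` seeds once and lets the stream run across files,
so repeated sizes give distinct trees while the whole suite is reproducible
byte for byte.  Leaf labels are zero-padded indices (`L001`, ...) assigned
in ID order; internal nodes are unlabeled.

### What the simulator does and does not emulate

Simulated trees are strictly binary, ultrametric-by-truncation, with clean
labels and well-behaved lengths.  Real trees have multifurcations, missing
and duplicated labels, zero and negative lengths, quoted names and comments
— the randomized Newick generator in the test helpers covers those parser
stresses, but the statistical tests say nothing about non-Yule branching,
extinction, or sampling-through-time shapes.  Passing tests demonstrate
correctness of the data structure and algorithms on those inputs, not
realism of the branching model.

## Problem sizes and numerical tolerances

The test and acceptance runs use sizes chosen to exercise every code path
while staying desk-scale: 1000 randomized Newick strings against the
reference parser, 100-leaf trees for the 1000 oracle queries, 500
replicates at 200 leaves for the Yule recovery, and trees up to a few
thousand leaves for buffer-accounting and benchmark smoke tests; the
simulator and parser themselves are linear-time and have been run far
larger.  Distance comparisons use absolute tolerances around `1e-9` (double
oracles) and `1e-6` relative where single-precision storage is involved.
Monte-Carlo checks use three standard errors.  The self-benchmark
(`run_benchmark()`, CLI `bench`) reports mean wall-clock and a t-based 95%
confidence half-width over repetitions, and degrades to time-only if the
garbage-collector memory probe is unavailable.

## Known limitations

Newick in and out only; one tree per file.  No topology editing.  No
unrooted-tree semantics: the Newick root is the root.  One label and one
length per node; comments and NHX payloads are discarded at parse time.
The nested `children` list is the R-idiomatic but memory-heaviest part of
the representation; the flat-children index and the level-order encoding
exist precisely to quantify and avoid that cost.
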