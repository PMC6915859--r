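---
title: "Generating and counting tree-child and normal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and counting tree-child and normal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcnet)
```

## The objects

A rooted binary phylogenetic network (RPN) on taxa $\{1,\dots,n\}$ is an
acyclic digraph with a unique indegree-0 root of outdegree 1, $n$ labelled
leaves of indegree 1 and outdegree 0, and internal nodes that are either
*tree nodes* (indegree 1, outdegree 2) or *reticulate nodes* (indegree 2,
outdegree 1, modelling hybridisation or recombination); parallel edges are
excluded.  An edge is *reticulate* if its head is reticulate, and a *tree
edge* otherwise.  Ancestry is taken reflexively throughout this package:
$u$ is an ancestor of $v$ iff some root-to-$v$ path contains $u$, so every
node is an ancestor of itself.  Two nodes (or two edges, via their heads)
are *incomparable* when neither is an ancestor of the other.

Two network classes are central:

* **tree-child (TCN)**: every non-leaf node has at least one child that is
  a tree node or a leaf;
* **normal**: tree-child, and the two parents of every reticulate node are
  incomparable.

`tcnet` implements the class predicates, the three rearrangement
operations that generate these classes, isomorphism-free exhaustive
enumeration, and exact counting.

## The generation procedure

Trees on $n$ taxa are classically generated by inserting taxon $n$ into
every edge of every tree on $n-1$ taxa.  The generalisation to networks
uses three operations:

* **leaf insertion** — subdivide a tree edge with a new node $w$ and hang
  the new leaf from $w$;
* **reticulation insertion** — subdivide tree edges $e_1$ and $e_2$ (not
  necessarily distinct) with $w_1, w_2$, make both parents of a new
  reticulate node $r$, and hang the new leaf from $r$;
* **child rotation** — at a reticulate node $r$ with tree-node parent $u$
  not ancestral to the other parent, exchange $r$'s child with $u$'s
  other child.

Every TCN with $k$ reticulations on $n$ taxa arises *exactly once* from
either (i) a unique TCN on $n-1$ taxa with $k$ reticulations by a leaf
insertion, or (ii) a unique TCN on $n-1$ taxa with $k-1$ reticulations by
a reticulation insertion followed by at most one admissible child
rotation at one of the two inserted parents.  `enumerate_tcn()` walks
this lattice bottom-up from the one-taxon tree.  At a same-edge straddle
only the rotation at the lower inserted parent is admissible; at a
comparable pair of distinct edges exactly one rotation is; at an
incomparable pair both are.  The engine simply emits every admissible
rotation, which reproduces this 2/2/3 census — and with it the master
recurrence (see below) — without special-casing.

```{r}
enumerate_tcn(3, 1, count_only = TRUE)
length(enumerate_normal(4, 2))
```

The reverse map `reduce_last()` undoes the step that produced the
highest-numbered leaf, classifying it by the leaf's parent and sibling
(reticulate parent / tree sibling / reticulate sibling); the third case
first applies the inverse rotation and then reduces, and provably needs
at most one such rotation — the implementation asserts this rather than
assuming it.

### The normal refinement

For normal networks, reticulations are inserted only into *incomparable
pairs of distinct tree edges*, and a rotation that makes $v_1$ (the head
of $e_1$) the child of $r$ is skipped iff the pre-insertion network
contains a reticulate edge $(x, y)$ with

1. $y$ below $v_1$,
2. $x$ not an ancestor of $v_1$, and
3. $x$ a **proper** ancestor of $v_2$.

The properness in (3) is a deliberate design decision.  With reflexive
ancestry, reading (3) as "$x$ is an ancestor of $v_2$" would also fire
when $x = v_2$; but in that configuration $x$ stays strictly below the
subdivision node of $e_2$ after the rotation and gains no new
descendants, so normality is not threatened.  Excluding those rotations
demonstrably loses networks (the counts at $(n,k) = (4,2)$ and $(5,3)$
drop from 48 to 42 and from 1920 to 1512).  Because $v_2$ has indegree 1,
proper ancestry of $v_2$ is equivalent to (reflexive) ancestry of its
tail, so the condition stays a single reachability lookup.  Conditions
(1) and (2) are insensitive to the strict/reflexive choice — their
degenerate cases are vacuous because $y$ is reticulate and tree-edge
heads are not.

`cross_validate_normal()` certifies the whole scheme: for every $(n,k)$
with $n \le 5$ the direct normal enumeration equals, as a set up to
isomorphism, the `is_normal()`-filtered tree-child enumeration.

## Counting

With $a_{n,k}$ the TCN count and $u$ the total number of incomparable
tree-edge pairs, the generation census above gives

$$a_{n,k} = (2n+k-3)\,\{a_{n-1,k} + (2n+k-4)\,a_{n-1,k-1}\} + u_{n-1,k-1},$$

with $a_{1,0} = a_{2,0} = 1$ (notably $a_{2,1} = 2$ is *derived*, via the
one-taxon base).  For $k = 1$ the $u$ term ranges over trees and has a
closed form; everything reduces to odd double factorials:

$$u_{n,0} = (n+1)(2n-1)!! - 2^n n!\,, \qquad
  c_n = 2^n n! - 2\,(2n-1)!!\,,$$

where $c_n$ (comparable pairs, recurrence $c_n = 2n\,c_{n-1} +
2\,(2n-3)!!$ from $c_2 = 2$) is the complement of $u_{n,0}$ in
$\binom{2n-1}{2}$ pairs per tree.  This yields closed forms with one
reticulation:

$$a_{n,1} = n\,(2n-1)!! - 2^{n-1} n!\,, \qquad
  b_{n,1} = (n+2)\,(2n-1)!! - 3 \cdot 2^{n-1} n!\,,$$

and the normal recurrence $b_{n,1} = (2n-2)\,b_{n-1,1} + 3u_{n-1,0}$.
Since every RPN with a single reticulate node is automatically
tree-child, $a_{n,1}$ counts *all* binary RPNs with one reticulation.
No closed form is known for $b_{n,k}$, $k \ge 2$; those cells are
counted by enumeration (`b_by_enumeration()`), guarded by an arithmetic
size bound.

```{r}
as.numeric(b_one_ret_closed(6))      # 14040 normal networks, n = 6, k = 1
count_table(5, "normal")
```

### Which u?  An edge-scope subtlety

The incomparable-pair statistic can be read over *all* edges (the
textbook definition, exposed as `u_of()`) or over *tree edges only* (the
insertion sites, exposed via `incomparable_tree_edge_pairs()` and
`u_total(..., "tree_only")`).  The two coincide on trees, i.e. whenever
$k-1 = 0$, which covers every printed one-reticulation number.  For
$k \ge 2$ they differ, and only the tree-only reading makes the master
recurrence agree with the enumeration — e.g. at $(3,2)$: enumeration 42,
recurrence with tree-only $u$ 42, with all-edges $u$ 46.  The package
therefore defaults the recurrence's `u_provider` to the tree-only scope
and keeps `u_of()` faithful to the all-edges definition; the test suite
asserts both the agreement and the disagreement for every $(n,k)$ with
$n \le 5$.

### Exact arithmetic

Counts overflow doubles well before the $n \le 20$ identity checks
($b_{20,1}$ has 22 digits), and no arbitrary-precision package is
assumed, so `bigint` implements little-endian base-$10^6$ arithmetic on
double limbs (sums, differences, products, comparisons — all the
recurrences need).  All closed forms are evaluated division-free via
$(2n)!/(2^n n!) = (2n-1)!!$.

## Isomorphism and deduplication

Generation is provably duplicate-free, but the package *verifies* rather
than trusts this.  Two independent mechanisms are used:

* `canonical_code()` — the sorted multiset of per-node *path-count
  vectors* (number of directed paths from each node to each leaf),
  concatenated with the sorted multiset of per-edge vector pairs.  The
  code is isomorphism-invariant by construction, so isomorphic networks
  always collide; that distinct tree-child networks never collide is an
  empirical claim, certified below.  Codes are only offered for
  tree-child inputs.
* `are_isomorphic()` — backtracking search for a label-preserving edge
  bijection, seeded by the forced root/leaf correspondence and pruned
  only by degree signatures.  It never consults the code.

The test suite checks the two agree on *every* pair of enumerated TCNs
with $n \le 4$ and on sampled pairs at $n = 5$.  Duplicate-freeness at
$n \le 5$ is then checked by grouping on codes and running the
backtracking oracle inside any colliding group — equivalent in strength
to the full quadratic pass (a duplicate pair must share a code because
codes are isomorphism-invariant), but feasible; at $n = 6$ the normal
enumerations (424k networks) are checked for code uniqueness.

## Synthetic data, and what a green test establishes

There is no external data: every fixture is generated by the package
itself from the one- and two-taxon base trees, which is exactly the
stated world of the generation theory (its own closure *is* the object
of study).  Consequently the tests certify combinatorial correctness —
counts, uniqueness, class membership, reverse maps, serialization
round-trips — on complete populations up to $n = 6$; they say nothing
about biological realism of any particular network, and nothing about
scales beyond $n = 8$ (enumeration past that is an explicit non-goal;
the size guard refuses predicted outputs above $10^6$ networks unless
overridden).

## Numerical and engineering choices

* Node ids are allocated by a per-network monotone counter, so runs are
  byte-for-byte reproducible; isomorphism never depends on ids.
* Intermediate enumeration levels are materialised sorted by canonical
  code; emission order is parents-in-code-order, then leaf insertions by
  edge index, then reticulation insertions by lexicographic edge-pair
  index (plain, rotation at $e_1$, rotation at $e_2$).
* Ancestry matrices are recomputed per network (networks stay below ~30
  nodes at feasible scales); no incremental maintenance.
* `subdivide()` is the one operation allowed to return a transiently
  invalid network (its contract says so); every public operation
  validates its output class.
* Reachability, path counts, canonical codes and isomorphism are
  implemented in C++ (Rcpp); everything else is plain R.
* The eNewick writer retains the outer parentheses (the outdegree-1 root
  is part of the object), orders children by their path-count key
  (lower-taxon subtrees first), and numbers hybrid tags in traversal
  order, so output is deterministic; the reader tolerates and discards
  branch lengths.

## Known limitations

* Canonical-code completeness is certified empirically on the enumerated
  populations, not proved; `are_isomorphic()` remains the fallback
  oracle, and the acceptance tests would fall back to it on any
  collision.
* Isomorphism testing is exponential in the worst case; it is only
  intended for the desk-scale networks this package generates.
* Non-binary networks, unrooted networks, general rNNI moves (beyond the
  child-rotation special case) and the richer eNewick dialect (branch
  lengths, internal names, bootstrap values) are out of scope.
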