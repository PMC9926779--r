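---
title: "Counting labeled histories of rooted binary galled trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting labeled histories of rooted binary galled trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gallhistories)
```

## The objects

A **rooted binary galled tree** is a rooted binary phylogenetic network —
a DAG with one in-0/out-2 root, in-1/out-0 leaves, in-1/out-2 tree nodes
and in-2/out-1 reticulation (hybrid) nodes — in which every hybrid node
closes a cycle (a **gall**) with a unique top node via two non-overlapping
paths, and the galls are pairwise vertex-disjoint and non-nested. Each gall
consists of its top node, the hybrid node, the two **hybridizing side
nodes** (the hybrid's parents), and any further **non-hybridizing side
nodes** along the two paths, each of which carries exactly one off-cycle
subtree.

Time runs from the root towards the contemporaneous leaves. A
hybridization is modeled as instantaneous: the hybrid node and its two
parents share one time point, so a hybridization is a single **event**, as
is each ordinary coalescence (tree node). A galled tree with $n$ leaves has
exactly $n - 1$ events and $n - 1 + 2g$ internal nodes for $g$ galls. A
**labeled history** is the labeled topology together with a total temporal
order of its events — formally a sequence of simultaneity sets
$W_1, \dots, W_n$ with $W_1$ the root, $W_n$ the leaves, and every
non-final $W_i$ either one coalescing node or one hybridization triple.

`validate_galled_tree()` checks all of this and names the first violated
condition (`NOT_ROOTED_DAG`, `DEGREE_VIOLATION`, `NESTED_CYCLES`,
`SHARED_CYCLE_VERTICES`, `TEMPORALLY_INCONSISTENT`). Temporal consistency
is verified by contracting each hybridization triple to one event and
checking that the induced precedence relation is acyclic; the disallowed
"temporal impossibilities" are exactly cycles among events, and for
vertex-disjoint, non-nested galls the check never fires — it guards the
general machinery.

## Counting labeled histories

For a gall-free tree the count is classical. The recursion multiplies the
two subtree counts by the number of interleavings of their event
sequences,

$$L_H(T) = L_H(T_\ell)\,L_H(T_r)\binom{v(T_\ell)+v(T_r)}{v(T_r)},$$

with $L_H = 1$ for a leaf or cherry; the closed form is
$L_H(T) = (n-1)! \big/ \prod_i v(T_i)$ over the internal nodes $i$. Both
are implemented (`count_labeled_histories()` uses the recursion;
`count_histories_closed()` the closed form) and tested against each other
and against the oracle below.

At a gall's top node the recursion changes. A gall with $N$ left and $M$
right non-hybridizing side nodes carries $N+M+3$ subtrees (including those
of the two hybridizing nodes and of the hybrid). The count multiplies the
subtree counts by a sum over:

1. **Arrangements** (`side_arrangements()`): the $\binom{N+M}{N}$
   interleavings of the two side-node chains, each preserving its own
   ancestral order. An arrangement cuts the time below the top node into
   $N+M+1$ periods — one after each ranked side node, the last of those
   lying just above the hybridization, plus one after the hybridization.
2. **Assignments** (`enumerate_assignments()`): each subtree's $v(T_i)$
   events go into its available periods — those after its own side node
   (the subtree ranked $k$ gets $p = N+M+2-k$ periods; the hybridizing and
   hybrid subtrees only the final one) — in
   $\binom{v(T_i)+p(T_i)-1}{v(T_i)}$ ways per subtree (stars and bars).
3. **Weights** (`assignment_weight()`): within each period the events of
   different subtrees interleave freely while each subtree's internal
   order is fixed, giving the multinomial coefficient of that period's
   column; the assignment's weight is the product over periods.

`count_gall_histories(tree, trace = TRUE)` exposes the per-arrangement
breakdown:

```{r worked}
t3 <- fig_worked_example_tree()
count_gall_histories(t3, trace = TRUE)
```

The 17-leaf, three-gall fixture reproduces every intermediate of the
worked calculation: subtree counts $(1,1,1,2,3)$ with product 6, inner
sums 2,162,160 (over 45 assignments) and 1,801,800 (over 30), and total
$6 \times (2{,}162{,}160 + 1{,}801{,}800) = 23{,}783{,}760$.

Two representational choices are deliberate. The row order of assignment
matrices is fixed as (left side subtrees, right side subtrees, $T_L$,
$T_R$, $T_C$); only the number $N+M+3$ of rows is meaningful, and the
weight is symmetric in the rows, so any fixed order is valid. Second, the
boundary events themselves (top node, side nodes, hybridization) are never
placed in a matrix; they are part of the gall subtree's own event count
$v = n - 1$ when that subtree is interleaved higher up.

The inner sum is evaluated by nested weak-composition iteration — the
direct transcription of the definition — folding rows in one subtree at a
time and multiplying $\binom{S_j + c_j}{c_j}$ per period, which is the
incremental form of the column multinomial. A test confirms it equals the
naive "materialize all matrices, weigh each" route on the worked example.
Isomorphic subtrees are counted once, memoized on canonical form.

## The independent oracle

`build_event_poset()` contracts each hybridization triple to a single
event and takes the strict precedence relation induced by ancestry,
transitively closed through the simultaneity classes.
`count_linear_extensions()` counts the total orders extending this partial
order by exact dynamic programming over order ideals (downsets) — for the
17-leaf fixture, 16 events and a small ideal lattice, where the naive
$16!$ permutation sweep would be infeasible. Because a labeled history
*is* a linear extension of this poset, the oracle is a second, independent
route to the same number, sharing no code with the gall recursion. The
suite checks agreement on every enumerated galled tree with up to 6 leaves
(102 trees) and on 200 seeded random trees with up to 8 leaves.
`enumerate_labeled_histories()` additionally materializes the histories as
$W_1,\dots,W_n$ sequences and re-checks the definitional invariants.

## Enumerating small galled trees

`enumerate_gallfree()` reproduces the Wedderburn–Etherington counts by
combining unordered pairs of smaller shapes. `enumerate_galled()` extends
the idea: either the root is not a gall top (unordered pairs of smaller
galled trees) or it is, in which case leaves are distributed over the
$n_\ell + n_r + 3$ gall positions by positive compositions, read around
the gall from the most ancestral left side node to the most ancestral
right side node, with $n_\ell \ge n_r$.

Reflection of a gall is treated as an isomorphism of unlabeled galled
trees — this is the reading implied by the palindrome handling in the
generation scheme, and the package makes it explicit and testable through
`canonical_form()`, which sorts child keys at tree nodes and takes the
lexicographic minimum of each gall's key and its mirror. Three
under-specified points are resolved as follows:

* of a non-palindromic composition and its reversal, the lexicographically
  smaller is used (any fixed choice gives the same set);
* for a palindromic composition, the "specified order" on the two
  side-subtree lists is the lexicographic order of canonical-key vectors,
  and the left list must not exceed the right;
* output trees are labeled `t1..tn` arbitrarily, since labels never affect
  counts here.

Because these rules are the one place where the scheme could silently
over- or under-count, the package carries a second, dumber generator
(`method = "naive"`): all orientations, no rules, deduplicated by
canonical form. The suite requires the two key sets to be identical for
all $n \le 6$. The totals for $n = 1..6$ are 1, 1, 2, 6, 20, 72, with
gall-count strata $(2,4)$, $(3,15,2)$ and $(6,48,18)$ at $n = 4, 5, 6$,
and the $g = 0$ stratum equals $U_n$ for all $n \le 8$ (1064 trees at
$n = 8$, about four seconds).

`max_histories_table()` summarizes each stratum's size and maximal count.
Removing a gall via `remove_gall()` — delete the hybrid and one
hybridizing side node, reconnect the two dangling subtrees — keeps the
leaf count and never decreases the count of labeled histories, since every
history maps injectively into the transformed tree's histories; hence the
per-$n$ maximum always sits in the gall-free stratum. The deleted side
defaults to the right one; both sides are exercised in tests since the
choice is arbitrary.

## The random generator

`random_galled_tree(n, g, seed)` emulates the study conditions for
property tests: exact leaf and gall counts, every feasible shape
reachable, deterministic per seed. It recurses top-down; the root opens a
gall with probability $g/(\lfloor (n-1)/2 \rfloor + 1)$ (forced when no
binary split can host all $g$ galls), side-node counts and leaf
compositions are drawn uniformly over feasible choices, and remaining
galls are allocated sequentially with feasibility bounds. The sampler is
*not* uniform over shapes — simplicity was preferred, as its only role is
to feed property tests — and a coverage test confirms every enumerated
shape with $n \le 5$ appears within 2,000 seeded draws per stratum. It
emulates no biological signal whatsoever (no branch lengths, no labels
with meaning), so passing tests speak to combinatorial correctness, not to
fit on real data.

## Numerics, sizes, and limitations

* **Exact arithmetic with a guard.** No arbitrary-precision integer
  library is part of the package's dependency footprint; counts are
  computed in doubles, which represent every integer up to $2^{53}$
  exactly. Every product, binomial and factorial goes through a checked
  path that raises `OVERFLOW` instead of losing precision. Stepwise
  division in the closed form is always exact: any subset of the internal
  node counts has product dividing $(n-1)!$, because the quotient by the
  full product is an integer and the complement factors are integers. The
  guard caps the closed form near $n = 19$ and caps any count at
  $2^{53} \approx 9\times 10^{15}$; all shipped analyses stay orders of
  magnitude below it.
* **Problem sizes.** The test suite enumerates exhaustively to $n = 6$
  everywhere, to $n = 8$ for stratum counts and oracle spot checks, and
  uses 200 random fixtures at $n \le 8$; these sizes keep the full suite
  under a minute while covering all 102 small shapes. Wide galls are
  exercised to $k = 6$ cherries per side ($\binom{12}{6} = 924$
  arrangements); the arrangement count grows as $4^k/\sqrt{\pi k}$, which
  is the practical wall for the exact algorithm.
* **Left/right is cosmetic.** Gall orientation is stored (it follows the
  input's edge order) but declared non-semantic; counting, canonical
  forms, and written output are invariant under reflecting any gall and
  swapping children of any tree node, and the suite scrambles edge order
  to prove it.
* **Scope.** Galled *networks* (cycles sharing vertices), nested galls,
  non-binary networks, branch lengths, and unrooted networks are out of
  scope and rejected by validation. No closed-form count over galls is
  attempted (none is known); the gall recursion's cost is exponential in
  side-node counts. The eNewick dialect is the common two-occurrence tag
  convention; rich-Newick and NEXUS network blocks are not read.
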