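# gallhistories

Labeled histories of rooted binary galled trees.

A *labeled history* is a leaf-labeled phylogenetic topology together with
the temporal order of its internal events. For rooted binary trees the
number of labeled histories of a topology `T` with `n` leaves is classical:

    L_H(T) = L_H(T_l) * L_H(T_r) * C(v(T_l) + v(T_r), v(T_r))
           = (n-1)! / prod_i v(T_i)

where `v(T_i)` counts the internal nodes of the subtree at internal node
`i`. This package extends the computation to **galled trees** — rooted
binary phylogenetic networks whose reticulation cycles (*galls*) are
vertex-disjoint and non-nested — under the convention that a hybrid node is
contemporaneous with its two parents, so each hybridization is a single
event and a galled tree with `n` leaves has exactly `n - 1` events. At a
gall's top node the recursion sums, over the `C(N+M, N)` interleavings of
the gall's left and right side-node chains and over all stars-and-bars
assignments of subtree events to the resulting time periods, the product of
per-period multinomial coefficients. It is aimed at mathematical
phylogenetics: combinatorics of ranked tree-child networks, coalescent-style
calculations, and exhaustive studies of small network shapes.

The package provides:

* `galled_tree()` / `validate_galled_tree()` / `find_galls()` /
  `gall_subtrees()` — a validated data model with explicit gall anatomy;
* `parse_enewick()` / `write_enewick()` — extended-Newick I/O (hybrid
  written once with its subtree and `#H` tag, referenced once by bare tag),
  with canonical deterministic output;
* `count_labeled_histories()` — the recursive count, with
  `count_gall_histories(trace = TRUE)` exposing each arrangement's
  assignment count and inner sum;
* `build_event_poset()` / `count_linear_extensions()` /
  `enumerate_labeled_histories()` — an independent brute-force oracle that
  counts histories as linear extensions of the contracted event poset;
* `enumerate_galled()` / `enumerate_gallfree()` / `canonical_form()` /
  `max_histories_table()` — exhaustive enumeration of unlabeled galled
  trees with canonical deduplication;
* `remove_gall()` — the count-monotone gall-removal transform — and
  `random_galled_tree()`, a seeded generator for property tests;
* `exec/gallhistories` — a thin command-line front end
  (`count`, `oracle`, `enumerate`, `tables`, `random`, `strip-gall`,
  `fixtures`).

## A worked example

The 17-leaf, three-gall fixture ships with the package. Its root gall has
one non-hybridizing side node per side; the five gall subtrees have
(1, 1, 1, 2, 3) labeled histories:

```r
library(gallhistories)
t3 <- fig_worked_example_tree()
count_gall_histories(t3, trace = TRUE)
#> $count
#> [1] 23783760
#>
#> $subtree_product
#> [1] 6
#>
#> $trace
#>   sides order n_assignments inner_sum
#> 1    LR 19,29            30   1801800
#> 2    RL 29,19            45   2162160
```

Reading the trace: with the left side node ranked first (`LR`) the five
subtrees' events fit into the three time periods in 30 ways, summing to
1,801,800 orderings; with the right side node first (`RL`), 45 ways and
2,162,160. The total is the subtree product times the sum,
`6 * (1801800 + 2162160) = 23783760` labeled histories, and the
linear-extension oracle agrees:

```r
count_linear_extensions(build_event_poset(t3))
#> [1] 23783760
```

Exhaustive enumeration of unlabeled galled trees gives
1, 1, 2, 6, 20, 72 shapes for `n = 1..6`:

```r
sapply(1:6, function(n) length(enumerate_galled(n)))
#> [1]  1  1  2  6 20 72
```

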