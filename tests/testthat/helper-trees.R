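# Shared fixtures and small utilities, all built in code.

minimal_gall <- function() parse_enewick("((d,(e)#H2),(#H2,f));")

root_gall <- function(tree) {
  for (g in find_galls(tree)) if (g$top == tree$root) return(g)
  NULL
}

# fixed pool of random fixtures: (n, g) drawn deterministically per seed
random_fixture <- function(seed, n_max = 8L) {
  set.seed(seed * 7919L)
  n <- sample(3:n_max, 1L)
  g <- sample(0:((n - 1L) %/% 2L), 1L)
  random_galled_tree(n, g, seed = seed)
}

# re-store a tree with its edge rows permuted: children order at every node
# (and the parent order of every hybrid) is scrambled, i.e. an arbitrary
# reorientation / reflection of the same galled tree
shuffle_orientation <- function(tree, seed) {
  set.seed(seed)
  e <- tree$edges[sample(nrow(tree$edges)), , drop = FALSE]
  galled_tree(e, tree$labels, root = tree$root)
}

all_galled_upto <- function(n_max) {
  unlist(lapply(seq_len(n_max), enumerate_galled), recursive = FALSE)
}

# independent check of the labeled-history invariants for one history
expect_valid_history <- function(tree, hist) {
  n <- tree$n
  expect_length(hist, n)
  expect_identical(hist[[1L]], tree$root)
  expect_identical(sort(hist[[n]]), tree_leaves(tree))
  hybs <- sort(unique(tree$edges[duplicated(tree$edges[, 2L]), 2L]))
  for (i in seq_len(n - 1L)) {
    w <- hist[[i]]
    if (length(w) == 3L) {
      h <- intersect(w, hybs)
      expect_length(h, 1L)
      expect_setequal(setdiff(w, h), tree_parents(tree, h))
    } else {
      expect_length(w, 1L)
    }
  }
  # no node may be placed after any of its descendants
  below <- function(v) {
    out <- v
    repeat {
      nxt <- unique(tree$edges[tree$edges[, 1L] %in% out, 2L])
      if (all(nxt %in% out)) break
      out <- union(out, nxt)
    }
    setdiff(out, v)
  }
  for (i in seq_len(n - 1L)) for (j in seq_len(n)) {
    if (j <= i) next
    for (x in hist[[j]]) expect_false(any(hist[[i]] %in% below(x)))
  }
}
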