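#' Remove a gall while keeping every leaf
#'
#' Deletes the hybrid node and one hybridizing side node, then reconnects:
#' the surviving hybridizing node is joined to the hybrid's child, and the
#' parent of the deleted hybridizing node to that node's remaining child.
#' The result is a galled tree with the same leaf count and one gall fewer,
#' and it never has fewer labeled histories than the input (each history of
#' the input maps to one of the output, with the hybridization re-indexed as
#' the surviving node's coalescence).
#'
#' @param tree a valid `galled_tree`
#' @param gall a `gall` of `tree` (see [find_galls()])
#' @param side which hybridizing side node to delete (default `"right"`; the
#'   choice is arbitrary and both give valid, generally different, results)
#' @return a `galled_tree` with `g - 1` galls
#' @export
remove_gall <- function(tree, gall, side = c("right", "left")) {
  side <- match.arg(side)
  assert_galled_tree(tree)
  keep_h <- if (side == "right") gall$left_hybridizing else gall$right_hybridizing
  del_h <- if (side == "right") gall$right_hybridizing else gall$left_hybridizing
  a <- gall$hybrid
  roots <- gall_subtree_roots(tree, gall)
  c_root <- roots$C
  orphan <- if (side == "right") roots$R else roots$L
  del_parent <- setdiff(tree_parents(tree, del_h), a)  # cycle node above
  e <- tree$edges
  drop <- (e[, 1L] %in% c(a, del_h)) | (e[, 2L] %in% c(a, del_h))
  e <- e[!drop, , drop = FALSE]
  e <- rbind(e, c(keep_h, c_root), c(del_parent, orphan))
  galled_tree(e, tree$labels, root = tree$root)
}

#' The 11-leaf, one-gall gall-anatomy fixture
#'
#' A galled tree with leaves `A`-`K` and a single gall: top node `12`, one
#' left non-hybridizing side node (`8`), two right non-hybridizing side nodes
#' (`11` above `10`), hybridizing side nodes `6` (left) and `7` (right), and
#' hybrid node `5` whose subtree is the cherry `{C, D}`. Internal node ids
#' `1..12` follow the display convention (children numbered before parents,
#' the hybrid before its parents), so the id sequence
#' `12, 8, 11, 10, 2, (5,6,7), 3, 4, 9, 1` is one of its labeled histories.
#'
#' @return a valid `galled_tree` with `n = 11`, `g = 1`
#' @export
fig_gall_anatomy_tree <- function() {
  # leaves: A=13 B=14 C=15 D=16 E=17 F=18 G=19 H=20 I=21 J=22 K=23
  e <- rbind(
    c(12L, 8L), c(12L, 11L),
    c(8L, 19L), c(8L, 6L),          # T_l1 = leaf G
    c(6L, 3L), c(6L, 5L),           # T_L  = cherry (A,B), node 3
    c(3L, 13L), c(3L, 14L),
    c(7L, 4L), c(7L, 5L),           # T_R  = cherry (E,F), node 4
    c(4L, 17L), c(4L, 18L),
    c(5L, 1L),                      # T_C  = cherry (C,D), node 1
    c(1L, 15L), c(1L, 16L),
    c(11L, 2L), c(11L, 10L),        # T_r1 = cherry (J,K), node 2
    c(2L, 22L), c(2L, 23L),
    c(10L, 9L), c(10L, 7L),         # T_r2 = cherry (H,I), node 9
    c(9L, 20L), c(9L, 21L)
  )
  # put the left-hybridizing parent edge first so orientation matches ids
  labs <- stats::setNames(LETTERS[1:11], 13:23)
  galled_tree(e, labs, root = 12L)
}

#' The 17-leaf, three-gall worked-example fixture
#'
#' The root is the top node of a gall with one left non-hybridizing side
#' node (subtree: 3-leaf caterpillar) and one right non-hybridizing side
#' node (subtree: a root joining a 3-leaf single-gall tree and a cherry);
#' the left hybridizing subtree is a 3-leaf single-gall tree, the hybrid
#' subtree a cherry, and the right hybridizing subtree a balanced 4-leaf
#' tree. Its subtrees have (1, 1, 1, 2, 3) labeled histories and
#' (2, 2, 1, 3, 4) events, and the tree has 23,783,760 labeled histories.
#'
#' @return a valid `galled_tree` with `n = 17`, `g = 3`
#' @export
fig_worked_example_tree <- function() {
  parse_enewick(paste0(
    "((((a,b),c),(((d,(e)#H2),(#H2,f)),((g,h))#H1)),",
    "((((m,(n)#H3),(#H3,o)),(p,q)),(#H1,((i,j),(k,l)))));"))
}

#' Caterpillar tree
#'
#' The fully unbalanced shape: every internal node has at least one leaf
#' child. Caterpillars have exactly one labeled history.
#'
#' @param n leaf count (>= 1)
#' @return a gall-free `galled_tree`
#' @export
caterpillar_tree <- function(n) {
  t <- leaf_tree()
  if (n >= 2) for (i in 2:n) t <- join_trees(t, leaf_tree())
  t
}

#' Maximally balanced tree
#' @param n leaf count (>= 1)
#' @return a gall-free `galled_tree`
#' @export
balanced_tree <- function(n) {
  if (n == 1L) return(leaf_tree())
  h <- n %/% 2L
  join_trees(balanced_tree(n - h), balanced_tree(h))
}

#' Wide-gall family with k cherries per side
#'
#' The family used to illustrate the exponential cost of summing over side
#' node arrangements: a single root gall with `k` non-hybridizing side nodes
#' on each side, each bearing a 2-leaf cherry, and single leaves under both
#' hybridizing nodes and the hybrid (`4k + 3` leaves). Its root gall has
#' `choose(2k, k)` side-node arrangements.
#'
#' @param k cherries per side (>= 0)
#' @return a `galled_tree` whose root is the gall's top node
#' @export
wide_gall_tree <- function(k) {
  cherries <- function() lapply(seq_len(k), function(i)
    join_trees(leaf_tree(), leaf_tree()))
  make_gall(left_sides = cherries(),
            TL = leaf_tree(), TC = leaf_tree(), TR = leaf_tree(),
            right_sides = cherries())
}

#' Random galled tree with given leaf and gall counts
#'
#' Draws a valid galled tree top-down: the root opens a gall with
#' probability proportional to the remaining gall budget, side-node counts
#' and leaf allocations are drawn uniformly over feasible choices, and the
#' remaining galls are distributed feasibly among the subtrees. The sampler
#' favors simplicity over uniformity across shapes; it exists to feed
#' property tests. Output is deterministic for a fixed `seed`.
#'
#' @param n leaf count
#' @param g gall count, `0 <= g <= floor((n-1)/2)`
#' @param seed optional integer seed (RNG state is restored on exit)
#' @param max_side_nodes cap on non-hybridizing side nodes per gall side
#' @return a valid `galled_tree` with exactly `n` leaves and `g` galls
#' @export
random_galled_tree <- function(n, g, seed = NULL, max_side_nodes = Inf) {
  if (n < 2 * g + 1)
    stop(gt_error("INFEASIBLE",
                  sprintf("%d galls need at least %d leaves", g, 2 * g + 1)))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  # distribute `galls` among parts of sizes `sizes`, uniformly over a
  # feasible sequential allocation
  alloc_galls <- function(sizes, galls) {
    caps <- max_galls(sizes)
    out <- integer(length(sizes))
    rem <- galls
    for (i in seq_along(sizes)) {
      later <- if (i < length(sizes)) sum(caps[(i + 1L):length(sizes)]) else 0L
      lo <- max(0L, rem - later)
      hi <- min(caps[i], rem)
      out[i] <- pick(lo:hi)
      rem <- rem - out[i]
    }
    out
  }
  gen <- function(m, gg) {
    if (m == 1L) return(leaf_tree())
    can_top <- gg >= 1L && m >= 3L
    split_ok <- any(vapply(seq_len(m - 1L), function(k)
      max_galls(k) + max_galls(m - k) >= gg, TRUE))
    p_top <- if (!can_top) 0 else if (!split_ok) 1 else gg / (max_galls(m) + 1)
    if (can_top && (p_top >= 1 || stats::runif(1) < p_top)) {
      smax <- min(m - 3L, 2L * max_side_nodes)
      repeat {  # redraw until the remaining galls fit in the subtree sizes
        S <- pick(0:smax)
        N <- pick(max(0L, S - min(S, max_side_nodes)):min(S, max_side_nodes))
        M <- S - N
        P <- S + 3L
        cuts <- if (P > 1L) sort(sample(m - 1L, P - 1L)) else integer()
        sizes <- diff(c(0L, cuts, m))
        if (sum(max_galls(sizes)) >= gg - 1L) break
      }
      galls <- alloc_galls(sizes, gg - 1L)
      subs <- lapply(seq_len(P), function(i) gen(sizes[i], galls[i]))
      make_gall(left_sides = subs[seq_len(N)],
                TL = subs[[N + 1L]], TC = subs[[N + 2L]], TR = subs[[N + 3L]],
                right_sides = if (M) subs[N + 3L + seq_len(M)] else list())
    } else {
      repeat {
        k <- pick(1:(m - 1L))
        if (max_galls(k) + max_galls(m - k) >= gg) break
      }
      galls <- alloc_galls(c(k, m - k), gg)
      join_trees(gen(k, galls[1L]), gen(m - k, galls[2L]))
    }
  }
  relabel_leaves(gen(as.integer(n), as.integer(g)))
}
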