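#' Closed-form labeled-history count for a gall-free tree
#'
#' For a rooted binary tree with `n` leaves the number of labeled histories
#' is `(n-1)!` divided by the product, over all internal nodes `i`, of the
#' number of internal nodes of the subtree rooted at `i`. Division is exact;
#' all intermediates are guarded against exceeding the exact double range.
#'
#' @param tree a valid gall-free `galled_tree`
#' @return exact labeled-history count (numeric, integer-valued)
#' @export
count_histories_closed <- function(tree) {
  assert_galled_tree(tree)
  if (tree$g > 0L)
    stop(gt_error("HAS_GALLS",
                  "closed form applies only to trees without galls"))
  if (tree$n <= 2L) return(1)
  lc <- leaf_counts_below(tree)
  internal <- setdiff(tree$nodes, tree_leaves(tree))
  r <- exact_factorial(tree$n - 1L)
  for (v in internal) r <- r / (lc[v] - 1L)  # each step exact (see vignette)
  r
}

#' One step of the recursive labeled-history count
#'
#' The number of labeled histories of a tree whose root joins `left` and
#' `right` is the product of the two subtree counts times the number of ways
#' to interleave their events, `choose(v_l + v_r, v_r)`; a single leaf or a
#' cherry has exactly one labeled history.
#'
#' @param left,right the two child subtrees (`galled_tree` objects)
#' @return exact labeled-history count of the joined tree
#' @export
count_histories_recursive <- function(left, right) {
  vl <- left$n - 1L
  vr <- right$n - 1L
  exact_prod(
    exact_prod(count_labeled_histories(left), count_labeled_histories(right)),
    exact_choose(vl + vr, vr))
}

#' Orderings of a gall's non-hybridizing side nodes
#'
#' The left side nodes keep their ancestral order, as do the right side
#' nodes; an arrangement is one of the `choose(N + M, N)` ways to interleave
#' the two chains, most ancestral first.
#'
#' @param gall a `gall` (see [find_galls()])
#' @return list of arrangements, each a list with `order` (side-node ids,
#'   most ancestral first) and `sides` (matching `"L"`/`"R"` markers)
#' @export
side_arrangements <- function(gall) {
  N <- length(gall$left_side)
  M <- length(gall$right_side)
  if (N + M == 0L)
    return(list(list(order = integer(), sides = character())))
  pos_sets <- if (N == 0L) {
    list(integer())
  } else if (N == N + M) {
    list(seq_len(N))
  } else {
    cmb <- utils::combn(N + M, N)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  lapply(pos_sets, function(lp) {
    order <- integer(N + M)
    sides <- character(N + M)
    order[lp] <- gall$left_side
    sides[lp] <- "L"
    order[setdiff(seq_len(N + M), lp)] <- gall$right_side
    sides[sides == ""] <- "R"
    list(order = order, sides = sides)
  })
}

#' Periods available to each gall subtree under an arrangement
#'
#' With `N + M` ranked side nodes there are `N + M + 1` time periods: one
#' after each ranked side node (the last of these lying between the final
#' side node and the hybridization) plus one after the hybridization. The
#' subtree of the side node ranked `k` may use periods `k .. N+M+1`; the
#' subtrees of the hybridizing nodes and the hybrid only the final period.
#' Rows follow the fixed order left side, right side, `TL`, `TR`, `TC`.
#' @noRd
period_availability <- function(arrangement, subtrees) {
  N <- length(subtrees$left)
  M <- length(subtrees$right)
  P <- N + M + 1L
  rank_of <- function(v) match(v, arrangement$order)
  p <- c(
    if (N) vapply(subtrees$left_nodes, function(v) P + 1L - rank_of(v), 0L),
    if (M) vapply(subtrees$right_nodes, function(v) P + 1L - rank_of(v), 0L),
    1L, 1L, 1L)
  names(p) <- subtree_row_names(N, M)
  p
}

subtree_event_counts <- function(subtrees) {
  v <- vapply(subtrees$subtrees, function(s) s$n - 1L, 0L)
  names(v) <- names(subtrees$subtrees)
  v
}

#' Assignments of subtree events to time periods
#'
#' Materializes the full assignment set `X(s)` for one arrangement: the
#' cartesian product, over the `N + M + 3` gall subtrees, of the weak
#' compositions of each subtree's `v(T_i)` events into its `p(T_i)` available
#' (trailing) periods. Its cardinality is the stars-and-bars product
#' `prod choose(v_i + p_i - 1, v_i)`.
#'
#' @param arrangement one element of [side_arrangements()]
#' @param subtrees the matching [gall_subtrees()] object
#' @return list of integer assignment matrices, `N + M + 3` rows (fixed
#'   subtree order: left side, right side, `TL`, `TR`, `TC`) by `N + M + 1`
#'   period columns
#' @export
enumerate_assignments <- function(arrangement, subtrees) {
  v <- subtree_event_counts(subtrees)
  p <- period_availability(arrangement, subtrees)
  P <- length(subtrees$left) + length(subtrees$right) + 1L
  comps <- lapply(seq_along(v), function(i) {
    m <- weak_compositions(v[i], p[i])
    pad <- matrix(0, nrow(m), P - p[i])
    cbind(pad, m, deparse.level = 0)
  })
  idx <- lapply(comps, function(m) seq_len(nrow(m)))
  grid <- do.call(expand.grid, idx)
  lapply(seq_len(nrow(grid)), function(r) {
    A <- do.call(rbind, lapply(seq_along(comps), function(i)
      comps[[i]][grid[r, i], ]))
    rownames(A) <- names(v)
    A
  })
}

#' Orderings permitted by one assignment of events to periods
#'
#' The weight of an assignment matrix is the product over time periods
#' (columns) of the multinomial coefficient of that period's column: events
#' from different subtrees may interleave freely within a period, while each
#' subtree's own event order is already fixed by its labeled history.
#'
#' @param A an assignment matrix (see [enumerate_assignments()])
#' @return exact count of within-period orderings
#' @export
assignment_weight <- function(A) {
  r <- 1
  for (j in seq_len(ncol(A))) r <- exact_prod(r, exact_multinomial(A[, j]))
  r
}

#' Inner sum over assignments for one arrangement, without materializing
#' matrices: rows are added one subtree at a time, multiplying in
#' choose(S_j + c_j, c_j) per period (the incremental form of the column
#' multinomial).
#' @noRd
inner_assignment_sum <- function(v, p, P) {
  comps <- lapply(seq_along(v), function(i) {
    m <- weak_compositions(v[i], p[i])
    cbind(matrix(0, nrow(m), P - p[i]), m, deparse.level = 0)
  })
  m <- length(v)
  rec <- function(i, colsum, mult) {
    if (i > m) return(mult)
    total <- 0
    ci <- comps[[i]]
    for (r in seq_len(nrow(ci))) {
      row <- ci[r, ]
      f <- 1
      for (j in seq_len(P)) if (row[j] > 0)
        f <- exact_prod(f, exact_choose(colsum[j] + row[j], row[j]))
      total <- total + rec(i + 1L, colsum + row, exact_prod(mult, f))
      check_exact(total)
    }
    total
  }
  rec(1L, numeric(P), 1)
}

#' Labeled histories of a galled tree whose root is a gall's top node
#'
#' Implements the gall recursion: the count is the product of the labeled
#' histories of the gall's `N + M + 3` subtrees, times the sum over all
#' `choose(N + M, N)` side-node arrangements of the sum over all assignments
#' of subtree events to time periods of each assignment's product of
#' per-period multinomial coefficients.
#'
#' @param tree a valid `galled_tree` whose root is the top node of a gall
#' @param trace if `TRUE`, also return the per-arrangement breakdown
#' @return the exact count, or with `trace = TRUE` a list with elements
#'   `count`, `subtree_product`, and `trace`: a data frame with one row per
#'   arrangement (`sides` pattern, side-node `order`, `n_assignments`,
#'   `inner_sum`)
#' @export
count_gall_histories <- function(tree, trace = FALSE) {
  assert_galled_tree(tree)
  galls <- detect_galls(tree)$galls
  gl <- NULL
  for (g in galls) if (g$top == tree$root) gl <- g
  if (is.null(gl))
    stop(gt_error("NOT_GALL_TOP", "root is not the top node of a gall"))
  gs <- gall_subtrees(tree, gl)
  v <- subtree_event_counts(gs)
  P <- length(gs$left) + length(gs$right) + 1L
  lprod <- 1
  for (s in gs$subtrees)
    lprod <- exact_prod(lprod, count_labeled_histories(s))
  arrs <- side_arrangements(gl)
  rows <- lapply(arrs, function(a) {
    p <- period_availability(a, gs)
    n_assign <- 1
    for (i in seq_along(v))
      n_assign <- exact_prod(n_assign, exact_choose(v[i] + p[i] - 1, v[i]))
    data.frame(
      sides = paste(a$sides, collapse = ""),
      order = paste(a$order, collapse = ","),
      n_assignments = n_assign,
      inner_sum = inner_assignment_sum(v, p, P),
      stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, rows)
  rownames(tr) <- NULL
  count <- exact_prod(lprod, sum(tr$inner_sum))
  if (!trace) return(count)
  list(count = count, subtree_product = lprod, trace = tr)
}

#' Number of labeled histories of a galled tree
#'
#' Counts the temporal orderings of the coalescence and hybridization events
#' of a rooted binary galled tree, with each hybrid node simultaneous with
#' its two parents. The computation is the tree recursion at nodes that do
#' not open a gall (subtree counts times the binomial interleaving factor)
#' and the gall recursion (see [count_gall_histories()]) at each gall's top
#' node. Isomorphic subtrees are counted once via canonical-form
#' memoization. All arithmetic is exact.
#'
#' @param tree a valid `galled_tree`
#' @return exact labeled-history count (numeric, integer-valued; at least 1)
#' @examples
#' count_labeled_histories(parse_enewick("((a,b),(c,d));"))  # 2
#' @export
count_labeled_histories <- function(tree) {
  assert_galled_tree(tree)
  if (tree$n <= 2L) return(1)
  galls <- detect_galls(tree)$galls
  nk <- node_keys(tree, galls)
  lc <- leaf_counts_below(tree)
  memo <- new.env(parent = emptyenv())
  cnt <- function(v) {
    if (is_leaf(tree, v)) return(1)
    k <- nk$key[[as.character(v)]]
    hit <- memo[[k]]
    if (!is.null(hit)) return(hit)
    gl <- nk$top_map[[as.character(v)]]
    res <- if (!is.null(gl)) {
      gall_count_at(tree, gl, cnt, lc)
    } else {
      kids <- tree_children(tree, v)
      vl <- lc[kids[1L]] - 1L
      vr <- lc[kids[2L]] - 1L
      exact_prod(exact_prod(cnt(kids[1L]), cnt(kids[2L])),
                 exact_choose(vl + vr, vr))
    }
    memo[[k]] <- res
    res
  }
  cnt(tree$root)
}

#' Gall recursion on node ids inside the main traversal
#' @noRd
gall_count_at <- function(tree, gl, cnt, lc) {
  roots <- gall_subtree_roots(tree, gl)
  ordered_roots <- c(unlist(roots$left), unlist(roots$right),
                     roots$L, roots$R, roots$C)
  v <- lc[ordered_roots] - 1L
  N <- length(gl$left_side)
  M <- length(gl$right_side)
  P <- N + M + 1L
  lprod <- 1
  for (r in ordered_roots) lprod <- exact_prod(lprod, cnt(r))
  total <- 0
  for (a in side_arrangements(gl)) {
    rank_of <- function(nd) match(nd, a$order)
    p <- c(
      if (N) vapply(gl$left_side, function(nd) P + 1L - rank_of(nd), 0L),
      if (M) vapply(gl$right_side, function(nd) P + 1L - rank_of(nd), 0L),
      1L, 1L, 1L)
    total <- total + inner_assignment_sum(v, p, P)
    check_exact(total)
  }
  exact_prod(lprod, total)
}
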