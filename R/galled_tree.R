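#' Construct a galled tree
#'
#' A galled tree is a rooted binary phylogenetic network whose reticulation
#' cycles (galls) are vertex-disjoint and non-nested. Nodes are identified by
#' positive integers; edges are directed from parent to child. Reticulation
#' (hybrid) nodes are the nodes with in-degree 2; they are interpreted as
#' simultaneous in time with their two parents.
#'
#' The constructor performs only light structural bookkeeping (adjacency,
#' root, leaf labels). Full checking of the galled-tree conditions is done by
#' [validate_galled_tree()].
#'
#' @param edges two-column integer matrix of directed edges, `(parent, child)`
#'   per row. The row order of a node's out-edges fixes its (non-semantic)
#'   left/right child orientation.
#' @param leaf_labels named character vector mapping leaf node ids (names) to
#'   labels. Every out-degree-0 node must be labeled; labels must be unique.
#' @param root optional root node id; inferred as the unique in-degree-0 node
#'   when missing.
#' @return an object of class `galled_tree` with fields `edges`, `labels`,
#'   `root`, `nodes`, `n` (leaf count) and `g` (gall count).
#' @seealso [leaf_tree()], [join_trees()], [make_gall()], [parse_enewick()]
#' @examples
#' cherry <- galled_tree(rbind(c(3, 1), c(3, 2)), c("1" = "a", "2" = "b"))
#' cherry$n
#' @export
galled_tree <- function(edges, leaf_labels, root = NULL) {
  if (is.null(edges)) edges <- matrix(integer(), 0L, 2L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  labs <- as.character(leaf_labels)
  names(labs) <- names(leaf_labels)
  leaf_ids <- as.integer(names(labs))
  if (length(labs) && (anyNA(leaf_ids) || any(leaf_ids < 1L)))
    stop("leaf label names must be positive integer node ids")
  nodes <- sort(unique(c(as.vector(edges), leaf_ids)))
  if (!length(nodes)) stop("empty tree")
  if (any(nodes < 1L)) stop("node ids must be positive integers")
  indeg <- tabulate(edges[, 2L], nbins = max(nodes))
  if (is.null(root)) {
    cand <- nodes[indeg[nodes] == 0L]
    if (length(cand) != 1L)
      root <- NA_integer_  # recorded; validate() reports NOT_ROOTED_DAG
    else root <- cand
  }
  tr <- structure(
    list(edges = edges, labels = labs, root = as.integer(root), nodes = nodes),
    class = "galled_tree"
  )
  tr$n <- length(tree_leaves(tr))
  tr$g <- sum(indeg[nodes] == 2L)
  tr
}

#' A single-leaf galled tree
#'
#' @param label leaf label.
#' @return a `galled_tree` with one node and no edges.
#' @export
leaf_tree <- function(label = "t1") {
  galled_tree(matrix(integer(), 0L, 2L), stats::setNames(label, "1"))
}

gt_error <- function(code, message, data = NULL) {
  structure(
    class = c(code, "galled_tree_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, message), call = NULL, data = data)
  )
}

out_edges <- function(tree, v) which(tree$edges[, 1L] == v)

#' Children of a node, in stored orientation order
#' @param tree a `galled_tree`
#' @param v node id
#' @return integer vector of child ids (possibly empty)
#' @export
tree_children <- function(tree, v) tree$edges[out_edges(tree, v), 2L]

#' Parents of a node, in stored orientation order
#' @inheritParams tree_children
#' @return integer vector of parent ids (length 0 for the root, 2 for hybrids)
#' @export
tree_parents <- function(tree, v) tree$edges[tree$edges[, 2L] == v, 1L]

#' Leaf nodes of a galled tree
#' @param tree a `galled_tree`
#' @return integer vector of out-degree-0 node ids, ascending
#' @export
tree_leaves <- function(tree) {
  if (!nrow(tree$edges)) return(tree$nodes)
  outdeg <- tabulate(tree$edges[, 1L], nbins = max(tree$nodes))
  tree$nodes[outdeg[tree$nodes] == 0L]
}

is_leaf <- function(tree, v) !(v %in% tree$edges[, 1L])

hybrid_nodes <- function(tree) {
  if (!nrow(tree$edges)) return(integer())
  indeg <- tabulate(tree$edges[, 2L], nbins = max(tree$nodes))
  tree$nodes[indeg[tree$nodes] == 2L]
}

#' Nodes reachable from a node (inclusive)
#' @noRd
descendant_nodes <- function(tree, v) {
  seen <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- unique(tree$edges[tree$edges[, 1L] %in% frontier, 2L])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' Extract the subtree rooted at a node
#'
#' Returns the galled tree induced by all nodes reachable from `v`. In a
#' valid galled tree every gall lies entirely inside or outside such a
#' subtree, so the result is itself a galled tree. Node ids are preserved.
#'
#' @param tree a `galled_tree`
#' @param v root of the subtree
#' @return a `galled_tree`
#' @export
extract_subtree <- function(tree, v) {
  if (is_leaf(tree, v)) {
    lab <- tree$labels[as.character(v)]
    if (is.na(lab)) lab <- paste0("n", v)
    return(galled_tree(NULL, stats::setNames(lab, v), root = v))
  }
  keep <- descendant_nodes(tree, v)
  e <- tree$edges[tree$edges[, 1L] %in% keep & tree$edges[, 2L] %in% keep, ,
                  drop = FALSE]
  labs <- tree$labels[names(tree$labels) %in% as.character(keep)]
  galled_tree(e, labs, root = v)
}

#' Renumber node ids to 1..K
#'
#' Internal nodes and leaves are renumbered compactly (leaves keep labels);
#' edge row order, and hence orientation, is preserved.
#' @noRd
renumber_tree <- function(tree, offset = 0L) {
  map <- stats::setNames(seq_along(tree$nodes) + offset, tree$nodes)
  e <- tree$edges
  if (nrow(e)) e <- matrix(map[as.character(e)], ncol = 2L)
  labs <- tree$labels
  names(labs) <- map[names(labs)]
  galled_tree(e, labs, root = unname(map[as.character(tree$root)]))
}

relabel_leaves <- function(tree, prefix = "t") {
  lv <- tree_leaves(tree)
  labs <- stats::setNames(paste0(prefix, seq_along(lv)), lv)
  tree$labels <- labs
  tree
}

#' Join two galled trees under a new root
#'
#' Builds the galled tree whose root has `left` and `right` as its two child
#' subtrees. Node ids are renumbered; leaf labels are regenerated as
#' `t1..tn` unless `relabel = FALSE`.
#'
#' @param left,right `galled_tree` objects
#' @param relabel regenerate leaf labels (default `TRUE`; set `FALSE` to keep
#'   the originals, which must then be disjoint)
#' @return a `galled_tree`
#' @export
join_trees <- function(left, right, relabel = TRUE) {
  a <- renumber_tree(left)
  b <- renumber_tree(right, offset = length(a$nodes))
  root <- length(a$nodes) + length(b$nodes) + 1L
  e <- rbind(c(root, a$root), c(root, b$root), a$edges, b$edges)
  tr <- galled_tree(e, c(a$labels, b$labels), root = root)
  if (relabel) relabel_leaves(tr) else tr
}

#' Assemble a galled tree with a gall at the root
#'
#' Builds the gall anatomy explicitly: a top node, chains of non-hybridizing
#' side nodes down each side (most ancestral first), the two hybridizing side
#' nodes, and the hybrid node, each carrying the supplied subtree.
#'
#' @param left_sides,right_sides lists of `galled_tree` subtrees hanging off
#'   the non-hybridizing side nodes, most ancestral first (possibly empty)
#' @param TL,TR subtrees of the left and right hybridizing side nodes
#' @param TC subtree of the hybrid node
#' @param relabel regenerate leaf labels `t1..tn` (default `TRUE`)
#' @return a `galled_tree` whose root is the gall's top node
#' @export
make_gall <- function(left_sides = list(), TL, TC, TR, right_sides = list(),
                      relabel = TRUE) {
  subs <- c(left_sides, list(TL, TC, TR), right_sides)
  off <- 0L
  subs <- lapply(subs, function(s) {
    s2 <- renumber_tree(s, offset = off)
    off <<- off + length(s2$nodes)
    s2
  })
  N <- length(left_sides)
  M <- length(right_sides)
  nL <- subs[[N + 1L]]; nC <- subs[[N + 2L]]; nR <- subs[[N + 3L]]
  # cycle node ids after the subtree blocks
  left_chain <- if (N) off + seq_len(N) else integer()      # ancestral first
  lh <- off + N + 1L
  hyb <- off + N + 2L
  rh <- off + N + 3L
  right_chain <- if (M) off + N + 3L + seq_len(M) else integer()
  top <- off + N + M + 4L
  e <- NULL
  left_path <- c(left_chain, lh)
  right_path <- c(right_chain, rh)   # right_chain ancestral first
  e <- rbind(e, c(top, left_path[1L]), c(top, right_path[1L]))
  if (N) for (i in seq_len(N)) {
    e <- rbind(e, c(left_chain[i], subs[[i]]$root),
               c(left_chain[i], left_path[i + 1L]))
  }
  if (M) for (j in seq_len(M)) {
    e <- rbind(e, c(right_chain[j], subs[[N + 3L + j]]$root),
               c(right_chain[j], right_path[j + 1L]))
  }
  e <- rbind(e,
             c(lh, nL$root), c(lh, hyb),
             c(rh, hyb), c(rh, nR$root),
             c(hyb, nC$root))
  for (s in subs) e <- rbind(e, s$edges)
  labs <- do.call(c, lapply(subs, `[[`, "labels"))
  tr <- galled_tree(e, labs, root = top)
  if (relabel) relabel_leaves(tr) else tr
}

#' Number of coalescence and hybridization events
#'
#' Each tree node is one coalescence event; each hybridization is one event
#' represented by three simultaneous internal nodes (the hybrid and its two
#' parents). The event count is therefore the number of internal nodes minus
#' twice the number of hybrid nodes, which equals `n - 1` for `n` leaves.
#'
#' @param tree a `galled_tree`
#' @return integer event count
#' @export
event_count <- function(tree) {
  internal <- length(tree$nodes) - tree$n
  internal - 2L * tree$g
}

#' Leaf counts below every node
#'
#' Number of distinct leaves reachable from each node; paths reconverging at
#' a hybrid node are not double-counted.
#' @noRd
leaf_counts_below <- function(tree) {
  lv <- tree_leaves(tree)
  sets <- vector("list", max(tree$nodes))
  counts <- integer(max(tree$nodes))
  rec <- function(v) {
    if (!is.null(sets[[v]])) return(sets[[v]])
    if (is_leaf(tree, v)) s <- v
    else {
      kids <- tree_children(tree, v)
      s <- sort(unique(unlist(lapply(kids, rec))))
    }
    sets[[v]] <<- s
    counts[v] <<- length(s)
    s
  }
  rec(tree$root)
  counts
}

#' Display numbering of internal nodes
#'
#' Assigns the integers `1..(number of internal nodes)` so that every child
#' receives a smaller number than each of its parents; in particular a hybrid
#' node is numbered before its two hybridizing parents. This reproduces the
#' postorder-flavored display convention for figures; it is cosmetic only and
#' never used as node identity.
#'
#' @param tree a valid `galled_tree`
#' @return named integer vector, `names` = internal node id, value = number
#' @export
display_numbering <- function(tree) {
  internal <- setdiff(tree$nodes, tree_leaves(tree))
  if (!length(internal)) return(stats::setNames(integer(), character()))
  num <- stats::setNames(rep(NA_integer_, length(internal)),
                         as.character(internal))
  hybs <- hybrid_nodes(tree)
  done <- function(v) is_leaf(tree, v) || !is.na(num[as.character(v)])
  nxt <- 1L
  while (anyNA(num)) {
    ready <- internal[is.na(num[as.character(internal)])]
    ready <- ready[vapply(ready, function(v)
      all(vapply(tree_children(tree, v), done, TRUE)), TRUE)]
    # hybrids first, so the hybridization cluster stays consecutive
    pick <- if (any(ready %in% hybs)) min(ready[ready %in% hybs]) else min(ready)
    num[as.character(pick)] <- nxt
    nxt <- nxt + 1L
  }
  num
}

#' @export
print.galled_tree <- function(x, ...) {
  cat(sprintf("Galled tree: %d leaves, %d gall%s, %d nodes\n",
              x$n, x$g, if (x$g == 1L) "" else "s", length(x$nodes)))
  nw <- tryCatch(write_enewick(x), error = function(e) NULL)
  if (!is.null(nw)) {
    if (nchar(nw) > 70) nw <- paste0(substr(nw, 1, 67), "...")
    cat(" ", nw, "\n")
  }
  invisible(x)
}
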