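#' Validate the galled-tree conditions
#'
#' Checks, in order: that the graph is a rooted DAG with every node reachable
#' from a unique root; that node degrees match a rooted binary network (root
#' in 0 / out 2, leaves in 1 / out 0, tree nodes in 1 / out 2, reticulations
#' in 2 / out 1); that every reticulation node closes a gall via exactly two
#' non-overlapping root-to-hybrid paths, with no nesting and no shared cycle
#' vertices; and that a time function exists under the simultaneity rules
#' (hybrid node contemporaneous with its two parents), i.e. that the
#' contracted event poset is acyclic.
#'
#' @param tree a candidate `galled_tree`
#' @return a list with elements `valid` (logical), `code` (`"OK"` or the
#'   first violated condition: `NOT_ROOTED_DAG`, `DEGREE_VIOLATION`,
#'   `NESTED_CYCLES`, `SHARED_CYCLE_VERTICES`, `TEMPORALLY_INCONSISTENT`)
#'   and `message`.
#' @export
validate_galled_tree <- function(tree) {
  bad <- function(code, msg) list(valid = FALSE, code = code, message = msg)

  maxid <- max(tree$nodes)
  indeg <- tabulate(tree$edges[, 2L], nbins = maxid)
  outdeg <- tabulate(tree$edges[, 1L], nbins = maxid)

  roots <- tree$nodes[indeg[tree$nodes] == 0L]
  if (length(roots) != 1L)
    return(bad("NOT_ROOTED_DAG",
               sprintf("expected exactly 1 in-degree-0 node, found %d",
                       length(roots))))
  if (is.na(tree$root) || tree$root != roots)
    return(bad("NOT_ROOTED_DAG", "stored root is not the in-degree-0 node"))

  # acyclicity + reachability from the root
  if (nrow(tree$edges)) {
    color <- integer(maxid)  # 0 white, 1 grey, 2 black
    acyclic <- TRUE
    visit <- function(v) {
      stack <- list(c(v, 0L))
      path <- integer()
      while (length(stack)) {
        fr <- stack[[length(stack)]]
        u <- fr[1L]; i <- fr[2L]
        if (i == 0L) {
          if (color[u] == 1L) { acyclic <<- FALSE; return() }
          if (color[u] == 2L) { stack[[length(stack)]] <- NULL; next }
          color[u] <<- 1L
        }
        kids <- tree$edges[tree$edges[, 1L] == u, 2L]
        if (i < length(kids)) {
          stack[[length(stack)]] <- c(u, i + 1L)
          k <- kids[i + 1L]
          if (color[k] == 1L) { acyclic <<- FALSE; return() }
          if (color[k] == 0L) stack[[length(stack) + 1L]] <- c(k, 0L)
        } else {
          color[u] <<- 2L
          stack[[length(stack)]] <- NULL
        }
      }
    }
    visit(tree$root)
    if (!acyclic)
      return(bad("NOT_ROOTED_DAG", "directed cycle detected"))
    if (any(color[tree$nodes] == 0L))
      return(bad("NOT_ROOTED_DAG", "nodes unreachable from the root"))
  }

  # degrees
  if (length(tree$nodes) == 1L) {
    return(list(valid = TRUE, code = "OK", message = "valid galled tree"))
  }
  for (v in tree$nodes) {
    din <- indeg[v]; dout <- outdeg[v]
    ok <- (v == tree$root && din == 0L && dout == 2L) ||
      (v != tree$root && din == 1L && dout == 0L) ||
      (v != tree$root && din == 1L && dout == 2L) ||
      (v != tree$root && din == 2L && dout == 1L)
    if (!ok)
      return(bad("DEGREE_VIOLATION",
                 sprintf("node %d has in-degree %d, out-degree %d", v, din, dout)))
  }

  det <- detect_galls(tree)
  if (!is.null(det$error)) return(bad(det$error, det$message))

  # temporal consistency: the contracted event relation must be acyclic
  ep <- try(build_event_poset(tree, .checked = TRUE), silent = TRUE)
  if (inherits(ep, "try-error"))
    return(bad("TEMPORALLY_INCONSISTENT",
               "hybridization simultaneity induces a cycle among events"))

  list(valid = TRUE, code = "OK", message = "valid galled tree")
}

#' Stop unless a tree validates
#' @noRd
assert_galled_tree <- function(tree) {
  if (!inherits(tree, "galled_tree")) stop("not a galled_tree object")
  rep <- validate_galled_tree(tree)
  if (!rep$valid)
    stop(gt_error(rep$code, rep$message, data = rep))
  invisible(tree)
}

#' Locate every gall, or report why the network is not a galled tree
#'
#' For each hybrid node, walks up the unique parent chains from its two
#' parents until they meet at the top node. Hitting another reticulation
#' node on the way up means the cycles are nested or overlap (not a galled
#' tree); cycles sharing any vertex across two galls are likewise rejected.
#' @noRd
detect_galls <- function(tree) {
  maxid <- max(tree$nodes)
  indeg <- tabulate(tree$edges[, 2L], nbins = maxid)
  hybs <- sort(tree$nodes[indeg[tree$nodes] == 2L])
  galls <- list()
  cycle_sets <- list()
  for (a in hybs) {
    pars <- tree_parents(tree, a)  # orientation: first stored parent = left
    # walk up the unique-parent chain; stop (without error) at any
    # reticulation - galls strictly above the meeting point are legal
    walk_up <- function(v) {
      chain <- integer()
      repeat {
        if (indeg[v] == 2L) return(chain)
        chain <- c(chain, v)
        if (v == tree$root) return(chain)
        v <- tree_parents(tree, v)
      }
    }
    chains <- list(walk_up(pars[1L]), walk_up(pars[2L]))
    meet <- chains[[1L]][chains[[1L]] %in% chains[[2L]]][1L]
    if (is.na(meet))
      return(list(error = "NESTED_CYCLES",
                  message = sprintf(
                    "the two paths to hybrid %d do not close a free-standing cycle",
                    a)))
    side1 <- chains[[1L]][seq_len(match(meet, chains[[1L]]) - 1L)]
    side2 <- chains[[2L]][seq_len(match(meet, chains[[2L]]) - 1L)]
    gall <- structure(list(
      top = meet,
      hybrid = a,
      left_hybridizing = side1[1L],
      right_hybridizing = side2[1L],
      left_side = rev(side1[-1L]),    # ancestral first
      right_side = rev(side2[-1L])
    ), class = "gall")
    galls[[length(galls) + 1L]] <- gall
    cycle_sets[[length(cycle_sets) + 1L]] <- c(meet, a, side1, side2)
  }
  if (length(cycle_sets) > 1L) {
    for (i in seq_len(length(cycle_sets) - 1L))
      for (j in seq.int(i + 1L, length(cycle_sets))) {
        shared <- intersect(cycle_sets[[i]], cycle_sets[[j]])
        if (length(shared))
          return(list(error = "SHARED_CYCLE_VERTICES",
                      message = sprintf("galls %d and %d share node(s) %s",
                                        i, j, paste(shared, collapse = ", "))))
      }
  }
  list(galls = galls, error = NULL)
}

#' Find the galls of a valid galled tree
#'
#' Returns one `gall` object per reticulation node, each recording the top
#' node, the hybrid node, the two hybridizing side nodes, and the ordered
#' left and right non-hybridizing side nodes (most ancestral first). The
#' left/right assignment follows the stored edge orientation and carries no
#' meaning: every computation in the package is invariant under reflecting a
#' gall.
#'
#' @param tree a valid `galled_tree`
#' @return list of `gall` objects (empty for a gall-free tree)
#' @export
find_galls <- function(tree) {
  assert_galled_tree(tree)
  detect_galls(tree)$galls
}

#' @export
print.gall <- function(x, ...) {
  cat(sprintf(
    "Gall: top %d, hybrid %d, hybridizing (%d | %d), side nodes L=(%s) R=(%s)\n",
    x$top, x$hybrid, x$left_hybridizing, x$right_hybridizing,
    paste(x$left_side, collapse = ","), paste(x$right_side, collapse = ",")))
  invisible(x)
}

#' Subtrees hanging off a gall
#'
#' A gall with `N` left and `M` right non-hybridizing side nodes carries
#' `N + M + 3` subtrees: one off-cycle subtree per non-hybridizing side node,
#' one off-hybrid subtree per hybridizing side node (`TL`, `TR`), and the
#' subtree of the hybrid node itself (`TC`). Together they partition the
#' leaves below the gall's top node.
#'
#' @param tree a valid `galled_tree`
#' @param gall a `gall` belonging to `tree` (see [find_galls()])
#' @return a `gall_subtrees` list with fields `left`/`right` (lists of
#'   subtrees, most ancestral side node first), `L`, `C`, `R`, the matching
#'   side-node ids (`left_nodes`, `right_nodes`), and `subtrees`: all
#'   subtrees in the fixed row order used by assignment matrices
#'   (left side, right side, `TL`, `TR`, `TC`).
#' @export
gall_subtrees <- function(tree, gall) {
  roots <- gall_subtree_roots(tree, gall)
  grab <- function(v) extract_subtree(tree, v)
  out <- structure(list(
    left = lapply(roots$left, grab),
    right = lapply(roots$right, grab),
    L = grab(roots$L), C = grab(roots$C), R = grab(roots$R),
    left_nodes = gall$left_side,
    right_nodes = gall$right_side
  ), class = "gall_subtrees")
  out$subtrees <- c(out$left, out$right, list(out$L, out$R, out$C))
  names(out$subtrees) <- subtree_row_names(length(out$left), length(out$right))
  out
}

subtree_row_names <- function(N, M) {
  c(if (N) paste0("Tl", seq_len(N)),
    if (M) paste0("Tr", seq_len(M)),
    "TL", "TR", "TC")
}

#' Off-cycle child of each gall node, without extraction
#' @noRd
gall_subtree_roots <- function(tree, gall) {
  cyc <- c(gall$top, gall$hybrid, gall$left_hybridizing, gall$right_hybridizing,
           gall$left_side, gall$right_side)
  off <- function(v) {
    kids <- tree_children(tree, v)
    kids[!(kids %in% cyc)]
  }
  list(
    left = lapply(gall$left_side, off),
    right = lapply(gall$right_side, off),
    L = off(gall$left_hybridizing),
    R = off(gall$right_hybridizing),
    C = tree_children(tree, gall$hybrid)
  )
}
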