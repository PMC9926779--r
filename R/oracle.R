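#' Contracted event poset of a galled tree
#'
#' Events are the units that receive distinct times in a labeled history:
#' each non-hybridizing tree node is one coalescence event, and each
#' hybridization is one event made of three simultaneous nodes (the hybrid
#' and its two hybridizing parents). Event `a` precedes event `b` whenever
#' some node of `a` is a strict ancestor of some node of `b`; the relation is
#' transitively closed through the simultaneity classes. Leaves carry no
#' event (they form the final simultaneity set of every labeled history).
#'
#' @param tree a valid `galled_tree`
#' @param .checked internal: skip re-validation
#' @return an `event_poset`: list with `events` (list of node-id vectors),
#'   `n_events`, and `precedes` (logical matrix of the strict partial order)
#' @export
build_event_poset <- function(tree, .checked = FALSE) {
  if (!.checked) assert_galled_tree(tree)
  lv <- tree_leaves(tree)
  internal <- setdiff(tree$nodes, lv)
  hybs <- hybrid_nodes(tree)
  consumed <- integer()
  events <- list()
  for (a in sort(hybs)) {
    pars <- tree_parents(tree, a)
    events[[length(events) + 1L]] <- sort(c(a, pars))
    consumed <- c(consumed, a, pars)
  }
  for (v in sort(setdiff(internal, consumed)))
    events[[length(events) + 1L]] <- v
  # order events by their smallest node id, for reproducible indexing
  events <- events[order(vapply(events, min, 0L))]
  k <- length(events)

  # strict ancestry between nodes (reachability by >= 1 edge)
  maxid <- max(tree$nodes)
  desc <- matrix(FALSE, maxid, maxid)
  for (v in tree$nodes) {
    if (is_leaf(tree, v)) next
    d <- setdiff(descendant_nodes(tree, v), v)
    desc[v, d] <- TRUE
  }
  pre <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    pre[i, j] <- any(desc[events[[i]], events[[j]], drop = FALSE])
  }
  # transitive closure through simultaneity classes; a cycle means the
  # required time function cannot exist
  for (m in seq_len(k)) for (i in seq_len(k)) if (pre[i, m])
    pre[i, ] <- pre[i, ] | pre[m, ]
  if (any(diag(pre)))
    stop(gt_error("TEMPORALLY_INCONSISTENT",
                  "event precedence contains a cycle"))
  structure(list(events = events, n_events = k, precedes = pre,
                 leaves = lv, root = tree$root),
            class = "event_poset")
}

#' @export
print.event_poset <- function(x, ...) {
  cat(sprintf("Event poset: %d events, %d precedence pairs\n",
              x$n_events, sum(x$precedes)))
  invisible(x)
}

#' Count linear extensions of an event poset
#'
#' Exact dynamic programming over order ideals (downsets): the number of
#' extensions of a downset `S` is the sum over events addable to `S` (all
#' predecessors already in `S`) of the extensions of `S` plus that event.
#' This counts the labeled histories of the originating galled tree by their
#' definition, independently of the recursive gall algorithm, and is the
#' package's brute-force oracle.
#'
#' @param poset an `event_poset` (or any list with `n_events` and a logical
#'   `precedes` matrix)
#' @param max_states bound on the number of distinct downsets memoized;
#'   exceeding it raises a `SIZE_LIMIT` error
#' @return exact number of linear extensions
#' @export
count_linear_extensions <- function(poset, max_states = 1e6) {
  k <- poset$n_events
  if (k == 0L) return(1)
  if (k > 30L)
    stop(gt_error("SIZE_LIMIT", "more than 30 events (bitmask limit)"))
  pred_mask <- integer(k)
  for (j in seq_len(k)) {
    m <- 0L
    for (i in seq_len(k)) if (poset$precedes[i, j])
      m <- bitwOr(m, bitwShiftL(1L, i - 1L))
    pred_mask[j] <- m
  }
  full <- if (k == 31L) NA else bitwShiftL(1L, k) - 1L
  memo <- new.env(parent = emptyenv())
  states <- 0L
  rec <- function(S) {
    if (S == full) return(1)
    key <- as.character(S)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    states <<- states + 1L
    if (states > max_states)
      stop(gt_error("SIZE_LIMIT", "downset lattice exceeds max_states"))
    tot <- 0
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(S, bit) == 0L && bitwAnd(pred_mask[j], S) == pred_mask[j])
        tot <- tot + rec(bitwOr(S, bit))
    }
    memo[[key]] <- check_exact(tot)
    tot
  }
  rec(0L)
}

#' Enumerate labeled histories explicitly
#'
#' Lists every labeled history of a galled tree as its sequence of
#' simultaneity sets `W_1 .. W_n`: each of the first `n - 1` sets is a single
#' coalescing tree node or a hybridization triple (hybrid plus both parents),
#' and `W_n` is the set of leaves. Intended for small trees; refuse to
#' enumerate more than `limit` histories.
#'
#' @param tree a valid `galled_tree`
#' @param limit maximum number of histories to enumerate
#' @return list of histories; each history is a list of integer node-id sets
#'   of length `n`
#' @export
enumerate_labeled_histories <- function(tree, limit = 10000) {
  assert_galled_tree(tree)
  poset <- build_event_poset(tree, .checked = TRUE)
  total <- count_linear_extensions(poset)
  if (total > limit)
    stop(gt_error("SIZE_LIMIT",
                  sprintf("%.0f histories exceed limit %d", total, limit)))
  k <- poset$n_events
  leaves <- poset$leaves
  out <- list()
  seq_events <- function(done, acc) {
    if (length(acc) == k) {
      out[[length(out) + 1L]] <<- c(
        lapply(acc, function(i) poset$events[[i]]),
        list(leaves))
      return(invisible())
    }
    for (j in seq_len(k)) {
      if (j %in% acc) next
      preds <- which(poset$precedes[, j])
      if (all(preds %in% acc)) seq_events(done, c(acc, j))
    }
  }
  if (k == 0L) return(list(list(leaves)))
  seq_events(integer(), integer())
  out
}
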