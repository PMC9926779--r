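#' Parse an extended-Newick string into a galled tree
#'
#' Reads the common eNewick dialect for reticulate networks: each hybrid node
#' is written once with its subtree and a `#`-tag (e.g. `(x)#H1`) and
#' referenced once more by the bare tag (`#H1`); the two enclosing nodes
#' become the hybrid's parents. Branch lengths, if present, are parsed and
#' discarded with a warning (the model is topology-only). The parsed network
#' must satisfy the galled-tree conditions.
#'
#' @param text an eNewick string (trailing semicolon required)
#' @return a valid `galled_tree`
#' @section Errors:
#' `PARSE_ERROR` for malformed syntax, `UNMATCHED_HYBRID_TAG` when a hybrid
#' tag does not appear exactly twice, `DUPLICATE_LABELS` for repeated leaf
#' labels, and `NOT_A_GALLED_TREE` (with the validation report attached as
#' condition data) when the network parses but violates the galled-tree
#' conditions.
#' @examples
#' tr <- parse_enewick("((d,(e)#H2),(#H2,f));")
#' tr$n; tr$g
#' @export
parse_enewick <- function(text) {
  text <- trimws(text)
  if (!nzchar(text) || !grepl(";\\s*$", text))
    stop(gt_error("PARSE_ERROR", "eNewick string must end with ';'"))
  tags <- regmatches(text, gregexpr("#[A-Za-z0-9_.]+", text))[[1L]]
  if (length(tags)) {
    cnt <- table(tags)
    bad <- names(cnt)[cnt != 2L]
    if (length(bad))
      stop(gt_error("UNMATCHED_HYBRID_TAG",
                    sprintf("tag(s) %s must appear exactly twice",
                            paste(bad, collapse = ", "))))
  }
  # single leaf, e.g. "a;"
  if (grepl("^[A-Za-z0-9_.-]+\\s*;$", text)) {
    lab <- sub("\\s*;$", "", text)
    return(leaf_tree(lab))
  }
  net <- tryCatch(
    if (length(tags)) ape::read.evonet(text = text)
    else ape::read.tree(text = text),
    error = function(e) stop(gt_error("PARSE_ERROR", conditionMessage(e))),
    warning = function(w) stop(gt_error("PARSE_ERROR", conditionMessage(w))))
  if (is.null(net) || is.null(net$edge))
    stop(gt_error("PARSE_ERROR", "could not parse eNewick string"))
  if (!is.null(net$edge.length))
    warning("branch lengths present in input were discarded (topology-only model)")
  edges <- net$edge
  if (!is.null(net$reticulation)) edges <- rbind(edges, net$reticulation)
  labs <- net$tip.label
  if (any(grepl("^#", labs)))
    stop(gt_error("PARSE_ERROR", "unresolved hybrid tag among leaves"))
  if (anyDuplicated(labs))
    stop(gt_error("DUPLICATE_LABELS", "leaf labels must be unique"))
  tree <- galled_tree(edges, stats::setNames(labs, seq_along(labs)))
  rep <- validate_galled_tree(tree)
  if (!rep$valid)
    stop(gt_error("NOT_A_GALLED_TREE",
                  sprintf("parsed network is not a galled tree: %s (%s)",
                          rep$code, rep$message),
                  data = rep))
  tree
}

#' Write a galled tree as a canonical extended-Newick string
#'
#' Output is deterministic for a given shape and labeling: children of every
#' tree node are ordered by their canonical subtree keys (ties broken by the
#' smallest leaf label) and each gall is emitted in its canonical
#' orientation, so `parse_enewick(write_enewick(tr))` is isomorphic to `tr`
#' and writing is idempotent on its own output. The subtree-bearing
#' occurrence of each hybrid tag is attached to the first parent in
#' canonical order.
#'
#' @param tree a valid `galled_tree`
#' @return an eNewick string with trailing semicolon
#' @export
write_enewick <- function(tree) {
  assert_galled_tree(tree)
  if (tree$n == 1L)
    return(paste0(tree$labels[[1L]], ";"))
  nk <- node_keys(tree)
  minlab <- new.env(parent = emptyenv())
  ml <- function(v) {
    vk <- as.character(v)
    hit <- minlab[[vk]]
    if (!is.null(hit)) return(hit)
    res <- if (is_leaf(tree, v)) tree$labels[[vk]]
    else min(vapply(tree_children(tree, v), ml, ""))
    minlab[[vk]] <- res
    res
  }
  tag_no <- 0L
  emit <- function(v) {
    vk <- as.character(v)
    if (is_leaf(tree, v)) return(tree$labels[[vk]])
    gl <- nk$top_map[[vk]]
    if (!is.null(gl)) {
      roots <- gall_subtree_roots(tree, gl)
      flip <- isTRUE(nk$flip[[vk]])
      lroots <- if (flip) roots$right else roots$left
      rroots <- if (flip) roots$left else roots$right
      lh_root <- if (flip) roots$R else roots$L
      rh_root <- if (flip) roots$L else roots$R
      tag_no <<- tag_no + 1L
      tag <- paste0("#H", tag_no)
      hyb_str <- paste0("(", emit(roots$C), ")", tag)
      left_str <- paste0("(", emit(lh_root), ",", hyb_str, ")")
      for (i in rev(seq_along(lroots)))
        left_str <- paste0("(", emit(lroots[[i]]), ",", left_str, ")")
      right_str <- paste0("(", tag, ",", emit(rh_root), ")")
      for (j in rev(seq_along(rroots)))
        right_str <- paste0("(", emit(rroots[[j]]), ",", right_str, ")")
      return(paste0("(", left_str, ",", right_str, ")"))
    }
    kids <- tree_children(tree, v)
    ord <- order(vapply(kids, function(k) nk$key[[as.character(k)]], ""),
                 vapply(kids, ml, ""))
    kids <- kids[ord]
    paste0("(", emit(kids[1L]), ",", emit(kids[2L]), ")")
  }
  paste0(emit(tree$root), ";")
}

#' Read galled trees from an eNewick file
#'
#' One tree per line, UTF-8, trailing semicolons.
#' @param file path to an eNewick file
#' @return list of `galled_tree` objects
#' @export
read_enewick <- function(file) {
  lines <- trimws(readLines(file, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_enewick)
}

#' Write galled trees to an eNewick file, one per line
#' @param trees a `galled_tree` or list of them
#' @param file output path
#' @return invisibly, the vector of strings written
#' @export
write_enewick_file <- function(trees, file) {
  if (inherits(trees, "galled_tree")) trees <- list(trees)
  out <- vapply(trees, write_enewick, "")
  writeLines(out, file, useBytes = TRUE)
  invisible(out)
}
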