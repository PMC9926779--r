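#' Per-node canonical shape keys
#'
#' Recursively computed strings identifying each node's subtree up to
#' isomorphism of unlabeled galled trees: child order at tree nodes is
#' ignored (keys sorted), and each gall is identified with its reflection
#' (lexicographic minimum of the key and the mirrored key). Returns an
#' environment with `key[[as.character(v)]]` for every node and
#' `flip[[as.character(top)]]` = TRUE when the mirrored orientation of that
#' gall was chosen as canonical.
#' @noRd
node_keys <- function(tree, galls = NULL) {
  if (is.null(galls)) galls <- detect_galls(tree)$galls
  top_map <- new.env(parent = emptyenv())
  for (gl in galls) assign(as.character(gl$top), gl, envir = top_map)
  key <- new.env(parent = emptyenv())
  flip <- new.env(parent = emptyenv())
  rec <- function(v) {
    vk <- as.character(v)
    if (!is.null(key[[vk]])) return(key[[vk]])
    res <- if (is_leaf(tree, v)) {
      "L"
    } else if (!is.null(top_map[[vk]])) {
      gl <- top_map[[vk]]
      roots <- gall_subtree_roots(tree, gl)
      lk <- c(vapply(roots$left, rec, ""), rec(roots$L))
      rk <- c(vapply(roots$right, rec, ""), rec(roots$R))
      ck <- rec(roots$C)
      sA <- paste0("G{", paste(lk, collapse = "+"), ";", ck, ";",
                   paste(rk, collapse = "+"), "}")
      sB <- paste0("G{", paste(rk, collapse = "+"), ";", ck, ";",
                   paste(lk, collapse = "+"), "}")
      if (sB < sA) { flip[[vk]] <- TRUE; sB } else { flip[[vk]] <- FALSE; sA }
    } else {
      ks <- sort(vapply(tree_children(tree, v), rec, ""))
      paste0("(", ks[1L], ",", ks[2L], ")")
    }
    key[[vk]] <- res
    res
  }
  rec(tree$root)
  list(key = key, flip = flip, top_map = top_map)
}

#' Canonical form of a galled tree
#'
#' A string that two galled trees share exactly when they are isomorphic as
#' unlabeled galled trees, i.e. equal up to swapping the two children of any
#' tree node and reflecting (mirroring) any gall. Leaf labels are ignored.
#'
#' @param tree a valid `galled_tree`
#' @return character scalar key
#' @examples
#' a <- parse_enewick("((a,b),c);")
#' b <- parse_enewick("(c,(b,a));")
#' identical(canonical_form(a), canonical_form(b))
#' @export
canonical_form <- function(tree) {
  assert_galled_tree(tree)
  nk <- node_keys(tree)
  nk$key[[as.character(tree$root)]]
}
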