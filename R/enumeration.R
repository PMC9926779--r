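#' Wedderburn-Etherington numbers
#'
#' Number of unlabeled rooted binary trees with `n` leaves, by the standard
#' recursion with separate even and odd cases (`U_1 = 1`; for even `n`, the
#' `n/2` split contributes unordered pairs with repetition).
#'
#' @param n leaf count (integer >= 1)
#' @return `U_n` as an exact numeric
#' @examples
#' sapply(1:8, wedderburn_etherington)  # 1 1 1 2 3 6 11 23
#' @export
wedderburn_etherington <- function(n) {
  if (length(n) != 1L || is.na(n) || n != round(n) || n < 1)
    stop(gt_error("DOMAIN", "n must be a single integer >= 1"))
  U <- numeric(max(n, 1L))
  U[1L] <- 1
  if (n >= 2) for (m in 2:n) {
    if (m %% 2 == 0) {
      h <- m %/% 2L
      s <- if (h >= 2) sum(U[seq_len(h - 1L)] * U[m - seq_len(h - 1L)]) else 0
      U[m] <- s + U[h] * (U[h] + 1) / 2
    } else {
      h <- (m - 1L) %/% 2L
      U[m] <- sum(U[seq_len(h)] * U[m - seq_len(h)])
    }
  }
  check_exact(U[n])
}

with_ckey <- function(tree) {
  attr(tree, "ckey") <- canonical_form(tree)
  tree
}

ckey <- function(tree) {
  k <- attr(tree, "ckey")
  if (is.null(k)) k <- canonical_form(tree)
  k
}

#' Enumerate all unlabeled rooted binary trees (no galls)
#'
#' Generates one representative per shape by combining unordered pairs of
#' smaller trees (for an even split, unordered pairs with repetition). The
#' number of shapes is the Wedderburn-Etherington number `U_n`.
#'
#' @param n leaf count
#' @return list of `galled_tree` objects with `g = 0`, leaves labeled `t1..tn`
#' @export
enumerate_gallfree <- function(n) {
  if (length(n) != 1L || is.na(n) || n != round(n) || n < 1)
    stop(gt_error("DOMAIN", "n must be a single integer >= 1"))
  memo <- vector("list", n)
  rec <- function(m) {
    if (!is.null(memo[[m]])) return(memo[[m]])
    res <- if (m == 1L) list(with_ckey(leaf_tree())) else {
      out <- list()
      for (k in seq_len(m %/% 2L)) {
        A <- rec(k); B <- rec(m - k)
        if (k < m - k) {
          for (a in A) for (b in B)
            out[[length(out) + 1L]] <- with_ckey(join_trees(a, b))
        } else {
          for (i in seq_along(A)) for (j in i:length(A))
            out[[length(out) + 1L]] <- with_ckey(join_trees(A[[i]], A[[j]]))
        }
      }
      out
    }
    memo[[m]] <<- res
    res
  }
  rec(n)
}

max_galls <- function(n) (n - 1L) %/% 2L

#' Enumerate all unlabeled galled trees
#'
#' Exhaustively generates one representative per unlabeled galled tree with
#' `n` leaves (optionally restricted to exactly `g` galls). Generation is
#' recursive: either the root is not the top node of a gall (unordered pair
#' of smaller galled trees) or it is, in which case leaves are allocated to
#' the gall's `n_l + n_r + 3` subtree positions by integer compositions, with
#' `n_l >= n_r` non-hybridizing side nodes on the two sides. When
#' `n_l = n_r`, reflection symmetry is removed: of a non-palindromic
#' composition and its reversal only the lexicographically smaller is used,
#' and for a palindromic composition the two side-subtree lists (ordered by
#' canonical key) are required to be in non-decreasing order. The `"naive"`
#' method instead generates with duplicates over all orientations and
#' deduplicates by [canonical_form()]; it exists as an independent guard and
#' must produce the identical set.
#'
#' @param n leaf count (>= 1)
#' @param g optional gall count, `0 <= g <= floor((n-1)/2)`
#' @param method `"scheme"` (composition rules, no duplicates) or `"naive"`
#' @return list of `galled_tree` objects, leaves labeled `t1..tn`
#' @examples
#' length(enumerate_galled(4))  # 6
#' @export
enumerate_galled <- function(n, g = NULL, method = c("scheme", "naive")) {
  method <- match.arg(method)
  if (length(n) != 1L || is.na(n) || n != round(n) || n < 1)
    stop(gt_error("DOMAIN", "n must be a single integer >= 1"))
  if (!is.null(g) && (g < 0 || g > max_galls(n)))
    stop(gt_error("DOMAIN",
                  sprintf("gall count %d infeasible for %d leaves (max %d)",
                          g, n, max_galls(n))))
  memo <- vector("list", n)
  rec <- function(m) {
    if (!is.null(memo[[m]])) return(memo[[m]])
    out <- list()
    if (m == 1L) out <- list(with_ckey(leaf_tree()))
    else {
      # root is not a gall top: unordered pairs of smaller galled trees
      for (k in seq_len(m %/% 2L)) {
        A <- rec(k); B <- rec(m - k)
        if (method == "naive") {
          for (a in A) for (b in B)
            out[[length(out) + 1L]] <- with_ckey(join_trees(a, b))
          if (k < m - k)
            for (b in B) for (a in A)
              out[[length(out) + 1L]] <- with_ckey(join_trees(b, a))
        } else if (k < m - k) {
          for (a in A) for (b in B)
            out[[length(out) + 1L]] <- with_ckey(join_trees(a, b))
        } else {
          for (i in seq_along(A)) for (j in i:length(A))
            out[[length(out) + 1L]] <- with_ckey(join_trees(A[[i]], A[[j]]))
        }
      }
      # root is a gall top
      if (m >= 3L) out <- c(out, root_gall_trees(m, rec, method))
    }
    if (method == "naive") {
      keys <- vapply(out, ckey, "")
      out <- out[!duplicated(keys)]
    }
    memo[[m]] <<- out
    out
  }
  res <- rec(n)
  if (!is.null(g)) res <- res[vapply(res, function(t) t$g, 0L) == g]
  res
}

#' Root-is-gall-top case of the enumeration
#' @noRd
root_gall_trees <- function(m, rec, method) {
  out <- list()
  nl_range <- 0:(m - 3L)
  for (nl in nl_range) {
    nr_max <- if (method == "naive") m - 3L - nl else nl
    for (nr in 0:nr_max) {
      P <- nl + nr + 3L
      if (P > m) next
      comps <- compositions_positive(m, P)
      for (r in seq_len(nrow(comps))) {
        cc <- comps[r, ]
        pal <- all(cc == rev(cc))
        use_rules <- method == "scheme" && nl == nr
        if (use_rules && !pal) {
          # keep one of each (c, c') pair: the lexicographically smaller
          cp <- rev(cc)
          d <- which(cc != cp)[1L]
          if (cc[d] > cp[d]) next
        }
        opts <- lapply(cc, rec)
        left_pos <- c(seq_len(nl), nl + 1L)       # ancestral first + TL
        right_pos <- c(if (nr) seq.int(P, nl + 4L), nl + 3L)
        center_pos <- nl + 2L
        if (use_rules && pal) {
          lists <- side_lists(opts, left_pos)
          for (i in seq_along(lists$idx)) for (j in seq_along(lists$idx)) {
            if (list_key_leq(lists$keys[[i]], lists$keys[[j]])) {
              for (ctr in opts[[center_pos]]) {
                lt <- lists$trees[[i]]
                rt <- lists$trees[[j]]
                out[[length(out) + 1L]] <- with_ckey(make_gall(
                  left_sides = lt[seq_len(nl)],
                  TL = lt[[nl + 1L]], TC = ctr, TR = rt[[nl + 1L]],
                  right_sides = rt[seq_len(nl)]))
              }
            }
          }
        } else {
          grid <- do.call(expand.grid, lapply(opts, seq_along))
          for (rr in seq_len(nrow(grid))) {
            pick <- lapply(seq_len(P), function(t) opts[[t]][[grid[rr, t]]])
            out[[length(out) + 1L]] <- with_ckey(make_gall(
              left_sides = pick[seq_len(nl)],
              TL = pick[[nl + 1L]], TC = pick[[center_pos]],
              TR = pick[[nl + 3L]],
              right_sides = pick[right_pos[seq_len(nr)]]))
          }
        }
      }
    }
  }
  out
}

#' All ordered lists of subtrees for one side of a palindromic composition,
#' with their canonical-key vectors
#' @noRd
side_lists <- function(opts, positions) {
  grid <- do.call(expand.grid, lapply(opts[positions], seq_along))
  trees <- lapply(seq_len(nrow(grid)), function(r)
    lapply(seq_along(positions), function(t)
      opts[[positions[t]]][[grid[r, t]]]))
  keys <- lapply(trees, function(tl) vapply(tl, ckey, ""))
  list(idx = seq_len(nrow(grid)), trees = trees, keys = keys)
}

list_key_leq <- function(a, b) {
  d <- which(a != b)
  if (!length(d)) return(TRUE)
  a[d[1L]] <= b[d[1L]]
}

#' Summary of labeled-history counts over galled-tree strata
#'
#' For each gall count `g` feasible at `n` leaves, reports how many unlabeled
#' galled trees exist and the maximum number of labeled histories within the
#' stratum. By the gall-removal argument the overall maximum is always
#' attained in the gall-free stratum.
#'
#' @param n leaf count (exhaustive enumeration; intended for small `n`)
#' @return data frame with columns `n`, `g`, `trees`, `max_histories`
#' @export
max_histories_table <- function(n) {
  trees <- enumerate_galled(n)
  gs <- vapply(trees, function(t) t$g, 0L)
  counts <- vapply(trees, count_labeled_histories, 0)
  out <- do.call(rbind, lapply(sort(unique(gs)), function(g) {
    data.frame(n = n, g = g, trees = sum(gs == g),
               max_histories = max(counts[gs == g]))
  }))
  rownames(out) <- NULL
  out
}
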