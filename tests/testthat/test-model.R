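test_that("validation accepts galled trees and names the violated condition", {
  expect_true(validate_galled_tree(fig_gall_anatomy_tree())$valid)
  expect_true(validate_galled_tree(fig_worked_example_tree())$valid)
  expect_true(validate_galled_tree(leaf_tree())$valid)

  # two cycles sharing vertices (a galled network, not a galled tree):
  # node q is a side node of both hybrids' cycles
  shared <- galled_tree(rbind(
    c(1L, 2L), c(1L, 3L),          # root R -> r, s
    c(2L, 4L), c(2L, 5L),          # r -> p, q
    c(4L, 10L), c(4L, 6L),         # p -> leaf x, hybrid H1
    c(5L, 6L), c(5L, 7L),          # q -> H1, H2
    c(3L, 7L), c(3L, 11L),         # s -> H2, leaf y
    c(6L, 12L), c(7L, 13L)         # hybrid children
  ), c("10" = "x", "11" = "y", "12" = "a", "13" = "b"))
  expect_identical(validate_galled_tree(shared)$code, "SHARED_CYCLE_VERTICES")

  # a cycle whose side path runs through another cycle (nested)
  nested <- galled_tree(rbind(
    c(1L, 2L), c(1L, 3L),          # root -> H2, Y
    c(2L, 4L),                     # hybrid H2 -> A
    c(4L, 10L), c(4L, 5L),         # A -> leaf c, hybrid H1
    c(5L, 11L),                    # H1 -> leaf d
    c(3L, 5L), c(3L, 6L),          # Y -> H1, Z
    c(6L, 2L), c(6L, 12L)          # Z -> H2, leaf e
  ), c("10" = "c", "11" = "d", "12" = "e"))
  expect_identical(validate_galled_tree(nested)$code, "NESTED_CYCLES")

  poly <- galled_tree(rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L)),
                      c("1" = "a", "2" = "b", "3" = "c"))
  expect_identical(validate_galled_tree(poly)$code, "DEGREE_VIOLATION")

  two_roots <- galled_tree(rbind(c(3L, 1L), c(4L, 2L)),
                           c("1" = "a", "2" = "b"), root = 3L)
  expect_identical(validate_galled_tree(two_roots)$code, "NOT_ROOTED_DAG")
})

test_that("find_galls reports the gall anatomy with ancestral-first sides", {
  t2 <- fig_gall_anatomy_tree()
  galls <- find_galls(t2)
  expect_length(galls, 1L)
  g <- galls[[1L]]
  expect_identical(g$top, 12L)
  expect_identical(g$hybrid, 5L)
  expect_identical(g$left_side, 8L)          # N = 1
  expect_identical(g$right_side, c(11L, 10L)) # M = 2, ancestral first
  expect_identical(c(g$left_hybridizing, g$right_hybridizing), c(6L, 7L))

  expect_length(find_galls(fig_worked_example_tree()), 3L)
  expect_length(find_galls(caterpillar_tree(5)), 0L)

  mg <- find_galls(minimal_gall())[[1L]]
  expect_length(mg$left_side, 0L)
  expect_length(mg$right_side, 0L)
})

test_that("event counts equal n - 1 and follow the internal-node formula", {
  expect_identical(event_count(fig_gall_anatomy_tree()), 10L)
  expect_identical(event_count(join_trees(leaf_tree(), leaf_tree())), 1L)
  t3 <- fig_worked_example_tree()
  gs <- gall_subtrees(t3, root_gall(t3))
  expect_identical(event_count(gs$right[[1L]]), 4L)  # the 5-leaf side subtree
  for (tr in c(all_galled_upto(5), lapply(1:60, random_fixture))) {
    internal <- length(tr$nodes) - tr$n
    expect_identical(internal, tr$n - 1L + 2L * tr$g)
    expect_identical(event_count(tr), tr$n - 1L)
    expect_lte(tr$g, (tr$n - 1L) %/% 2L)
  }
})

test_that("gall subtrees partition the leaves below the gall", {
  t3 <- fig_worked_example_tree()
  gs <- gall_subtrees(t3, root_gall(t3))
  sizes <- vapply(gs$subtrees, function(s) s$n, 0L)
  # fixed row order: left side, right side, TL, TR, TC
  expect_identical(unname(sizes), c(3L, 5L, 3L, 4L, 2L))
  events <- vapply(gs$subtrees, function(s) s$n - 1L, 0L)
  expect_identical(unname(events), c(2L, 4L, 2L, 3L, 1L))
  expect_identical(sum(sizes), t3$n)

  t2 <- fig_gall_anatomy_tree()
  gs2 <- gall_subtrees(t2, find_galls(t2)[[1L]])
  expect_setequal(unname(gs2$C$labels), c("C", "D"))

  mgs <- gall_subtrees(minimal_gall(), find_galls(minimal_gall())[[1L]])
  expect_identical(vapply(mgs$subtrees, function(s) s$n, 0L),
                   c(TL = 1L, TR = 1L, TC = 1L))

  for (tr in lapply(1:25, random_fixture)) {
    for (gl in find_galls(tr)) {
      gs <- gall_subtrees(tr, gl)
      expect_identical(sum(vapply(gs$subtrees, function(s) s$n, 0L)),
                       extract_subtree(tr, gl$top)$n)
    }
  }
})

test_that("validation accepts exactly the enumerated trees", {
  for (tr in all_galled_upto(5)) expect_true(validate_galled_tree(tr)$valid)
})

test_that("display numbering places children before parents", {
  for (tr in list(fig_gall_anatomy_tree(), fig_worked_example_tree(),
                  random_fixture(3), random_fixture(11))) {
    num <- display_numbering(tr)
    for (e in seq_len(nrow(tr$edges))) {
      p <- as.character(tr$edges[e, 1L]); c_ <- as.character(tr$edges[e, 2L])
      if (!is.na(num[c_]) && !is.na(num[p]))
        expect_lt(num[c_], num[p])
    }
  }
})

test_that("infeasible gall counts are rejected", {
  expect_error(random_galled_tree(4, 2, seed = 1), class = "INFEASIBLE")
  expect_error(enumerate_galled(5, g = 3), class = "DOMAIN")
})
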