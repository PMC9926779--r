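test_that("closed form matches hand computations on gall-free trees", {
  expect_identical(count_histories_closed(caterpillar_tree(6)), 1)
  expect_identical(count_histories_closed(balanced_tree(4)), 2)
  # root joining a balanced 4-leaf tree and a cherry: 5!/(5*3*1*1*1)
  expect_identical(count_histories_closed(
    join_trees(balanced_tree(4), join_trees(leaf_tree(), leaf_tree()))), 8)
  expect_error(count_histories_closed(minimal_gall()), class = "HAS_GALLS")
})

test_that("the tree recursion and the closed form agree", {
  for (n in 1:8) for (tr in enumerate_gallfree(n)) {
    expect_identical(count_labeled_histories(tr), count_histories_closed(tr))
  }
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:10, 1L)
    tr <- random_galled_tree(n, 0, seed = 5000L + i)
    expect_identical(count_labeled_histories(tr), count_histories_closed(tr))
  }
  a <- balanced_tree(4); b <- join_trees(leaf_tree(), leaf_tree())
  expect_identical(count_histories_recursive(a, b),
                   count_histories_closed(join_trees(a, b)))
})

test_that("side arrangements interleave the two chains order-preservingly", {
  t3 <- fig_worked_example_tree()
  gl <- root_gall(t3)
  arrs <- side_arrangements(gl)
  expect_length(arrs, 2L)
  expect_setequal(vapply(arrs, function(a) paste(a$sides, collapse = ""), ""),
                  c("LR", "RL"))

  mg <- find_galls(minimal_gall())[[1L]]
  expect_length(side_arrangements(mg), 1L)
  expect_length(side_arrangements(mg)[[1L]]$order, 0L)

  w3 <- wide_gall_tree(3)
  ga <- find_galls(w3)[[1L]]
  arrs3 <- side_arrangements(ga)
  expect_length(arrs3, choose(6, 3))
  seqs <- vapply(arrs3, function(a) paste(a$order, collapse = ","), "")
  expect_identical(anyDuplicated(seqs), 0L)
  for (a in arrs3) {
    expect_identical(a$order[a$sides == "L"], ga$left_side)
    expect_identical(a$order[a$sides == "R"], ga$right_side)
  }
})

test_that("assignment sets have stars-and-bars cardinality", {
  t3 <- fig_worked_example_tree()
  gl <- root_gall(t3)
  gs <- gall_subtrees(t3, gl)
  arrs <- side_arrangements(gl)
  sides <- vapply(arrs, function(a) paste(a$sides, collapse = ""), "")
  n_rl <- length(enumerate_assignments(arrs[[which(sides == "RL")]], gs))
  n_lr <- length(enumerate_assignments(arrs[[which(sides == "LR")]], gs))
  expect_identical(n_rl, 45L)
  expect_identical(n_lr, 30L)

  # all-zero event counts: a single empty assignment
  mg <- minimal_gall()
  mgs <- gall_subtrees(mg, find_galls(mg)[[1L]])
  only <- enumerate_assignments(side_arrangements(find_galls(mg)[[1L]])[[1L]], mgs)
  expect_length(only, 1L)
  expect_true(all(only[[1L]] == 0))
  expect_identical(assignment_weight(only[[1L]]), 1)

  # property: cardinality == prod choose(v+p-1, v) across varied galls
  for (seed in c(2, 9, 14, 21, 33)) {
    tr <- random_galled_tree(sample(5:9, 1L), 1, seed = seed)
    gl <- find_galls(tr)[[1L]]
    top <- extract_subtree(tr, gl$top)
    gl2 <- find_galls(top)[[1L]]
    gs2 <- gall_subtrees(top, gl2)
    v <- vapply(gs2$subtrees, function(s) s$n - 1L, 0L)
    for (a in side_arrangements(gl2)) {
      P <- length(gl2$left_side) + length(gl2$right_side) + 1L
      rank <- function(nd) match(nd, a$order)
      p <- c(vapply(gl2$left_side, function(nd) P + 1L - rank(nd), 0L),
             vapply(gl2$right_side, function(nd) P + 1L - rank(nd), 0L),
             1L, 1L, 1L)
      X <- enumerate_assignments(a, gs2)
      expect_identical(length(X), as.integer(prod(choose(v + p - 1, v))))
      for (A in X) expect_identical(unname(rowSums(A)), as.numeric(v))
    }
  }
})

test_that("assignment weights are products of per-period multinomials", {
  # the worked-example assignment: one caterpillar event and one right-side
  # event in the middle period; 1,2,1,3,3 events in the final period
  A <- rbind(
    Tl1 = c(0, 1, 1),
    Tr1 = c(0, 1, 3),
    TL  = c(0, 0, 2),
    TR  = c(0, 0, 3),
    TC  = c(0, 0, 1))
  expect_identical(assignment_weight(A), 100800)
  expect_identical(assignment_weight(A[, 3, drop = FALSE]), 50400)
  # all twelve events of a (2,2,1,3,4) profile in a single period
  B <- matrix(c(2, 2, 1, 3, 4), ncol = 1)
  expect_identical(assignment_weight(B), 831600)  # 12!/(2!2!1!3!4!)
  expect_identical(assignment_weight(matrix(0, 5, 3)), 1)
})

test_that("the gall recursion reproduces the worked example", {
  t3 <- fig_worked_example_tree()
  res <- count_gall_histories(t3, trace = TRUE)
  expect_identical(res$subtree_product, 6)
  expect_identical(res$trace$inner_sum[res$trace$sides == "RL"], 2162160)
  expect_identical(res$trace$inner_sum[res$trace$sides == "LR"], 1801800)
  expect_identical(res$trace$n_assignments[res$trace$sides == "RL"], 45)
  expect_identical(res$trace$n_assignments[res$trace$sides == "LR"], 30)
  expect_identical(res$count, 23783760)
  expect_identical(count_labeled_histories(t3), 23783760)

  # the naive assignment enumeration agrees with the incremental inner sums
  gl <- root_gall(t3)
  gs <- gall_subtrees(t3, gl)
  arrs <- side_arrangements(gl)
  for (a in arrs) {
    s <- sum(vapply(enumerate_assignments(a, gs), assignment_weight, 0))
    sides <- paste(a$sides, collapse = "")
    expect_identical(s, res$trace$inner_sum[res$trace$sides == sides])
  }

  expect_identical(count_labeled_histories(minimal_gall()), 1)
  expect_error(count_gall_histories(caterpillar_tree(3)), class = "NOT_GALL_TOP")
})

test_that("subtree counts of the worked example are 1, 1, 1, 2, 3", {
  t3 <- fig_worked_example_tree()
  gs <- gall_subtrees(t3, root_gall(t3))
  counts <- vapply(gs$subtrees, count_labeled_histories, 0)
  # fixed order: left side, right side, TL, TR, TC
  expect_identical(unname(counts), c(1, 3, 1, 2, 1))
  expect_identical(count_labeled_histories(gs$right[[1L]]), 3)
})

test_that("counts are invariant under reorientation and gall reflection", {
  pool <- c(list(fig_worked_example_tree(), fig_gall_anatomy_tree()),
            lapply(1:20, random_fixture))
  for (tr in pool) {
    want <- count_labeled_histories(tr)
    for (s in 1:3) {
      sh <- shuffle_orientation(tr, seed = s)
      expect_identical(count_labeled_histories(sh), want)
      expect_identical(canonical_form(sh), canonical_form(tr))
    }
  }
})

test_that("exact arithmetic refuses to overflow silently", {
  expect_error(count_histories_closed(balanced_tree(24)), class = "OVERFLOW")
})
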