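test_that("Wedderburn-Etherington recursion", {
  expect_identical(vapply(1:8, wedderburn_etherington, 0),
                   c(1, 1, 1, 2, 3, 6, 11, 23))
  expect_error(wedderburn_etherington(0), class = "DOMAIN")
  expect_error(wedderburn_etherington(-2), class = "DOMAIN")
})

test_that("gall-free enumeration produces U_n distinct valid shapes", {
  for (n in 1:8) {
    shapes <- enumerate_gallfree(n)
    expect_length(shapes, as.integer(wedderburn_etherington(n)))
    keys <- vapply(shapes, canonical_form, "")
    expect_identical(anyDuplicated(keys), 0L)
    expect_true(all(vapply(shapes, function(t) t$g == 0L, TRUE)))
  }
  expect_length(enumerate_gallfree(3), 1L)
})

test_that("galled-tree enumeration counts and strata", {
  expect_identical(vapply(1:6, function(n) length(enumerate_galled(n)), 0L),
                   c(1L, 1L, 2L, 6L, 20L, 72L))
  strata <- function(n) {
    gs <- vapply(enumerate_galled(n), function(t) t$g, 0L)
    vapply(0:max(gs), function(g) sum(gs == g), 0L)
  }
  expect_identical(strata(4), c(2L, 4L))
  expect_identical(strata(5), c(3L, 15L, 2L))
  expect_identical(strata(6), c(6L, 48L, 18L))
  # the g = 0 stratum is exactly the unlabeled binary trees
  for (n in 1:8) {
    expect_identical(length(enumerate_galled(n, g = 0)),
                     as.integer(wedderburn_etherington(n)))
  }
  # every output is a valid galled tree with a distinct canonical form
  all5 <- all_galled_upto(5)
  keys <- vapply(all5, canonical_form, "")
  expect_identical(anyDuplicated(keys), 0L)
  for (tr in all5) expect_true(validate_galled_tree(tr)$valid)
})

test_that("composition scheme and naive canonical dedup generate the same sets", {
  for (n in 1:6) {
    k1 <- sort(vapply(enumerate_galled(n), canonical_form, ""))
    k2 <- sort(vapply(enumerate_galled(n, method = "naive"), canonical_form, ""))
    expect_identical(k1, k2)
  }
})

test_that("canonical forms are invariant under mirroring and reflection", {
  mirrored <- function(s) parse_enewick(s)
  expect_identical(canonical_form(mirrored("((a,b),c);")),
                   canonical_form(mirrored("(c,(b,a));")))
  expect_identical(canonical_form(mirrored("((d,(e)#H2),(#H2,f));")),
                   canonical_form(mirrored("((f,(e)#H2),(#H2,d));")))
  for (seed in 1:15) {
    tr <- random_fixture(seed)
    expect_identical(canonical_form(shuffle_orientation(tr, seed + 100L)),
                     canonical_form(tr))
  }
})

test_that("minimum leaves for g galls is 2g + 1", {
  for (n in 1:6) for (g in 0:((n - 1L) %/% 2L)) {
    stratum <- enumerate_galled(n, g = g)
    if (n >= 2L * g + 1L) expect_gt(length(stratum), 0L)
  }
  expect_error(enumerate_galled(6, g = 3), class = "DOMAIN")
  expect_error(enumerate_galled(2, g = 1), class = "DOMAIN")
})

test_that("stratum maxima: removing galls never helps and g=0 leads", {
  for (n in 3:6) {
    tab <- max_histories_table(n)
    gs <- vapply(enumerate_galled(n), function(t) t$g, 0L)
    expect_identical(tab$trees,
                     vapply(tab$g, function(g) sum(gs == g), 0L))
    expect_identical(max(tab$max_histories), tab$max_histories[tab$g == 0])
    # maxima are non-increasing in the number of galls
    expect_true(all(diff(tab$max_histories) <= 0))
  }
  t4 <- max_histories_table(4)
  expect_identical(t4$trees, c(2L, 4L))
  t3 <- max_histories_table(3)
  expect_identical(t3$max_histories, c(1, 1))
})
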