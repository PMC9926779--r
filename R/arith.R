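# Exact integer arithmetic on doubles.
#
# Labeled-history counts are exact integers that grow super-exponentially.
# All products, binomials and factorials here are computed by integer-valued
# double arithmetic with a hard guard: any intermediate exceeding 2^53 (the
# largest range in which doubles represent every integer exactly) raises an
# OVERFLOW error instead of silently losing precision. Every problem size
# the package targets (exhaustive enumeration for n <= 8, the 17-leaf worked
# example and its gall-removal chain) stays well inside the guard.

.MAX_EXACT <- 2^53

check_exact <- function(x) {
  if (x > .MAX_EXACT)
    stop(gt_error("OVERFLOW",
                  "exact integer range of double precision (2^53) exceeded"))
  x
}

exact_prod <- function(a, b) check_exact(a * b)

#' Exact binomial coefficient with overflow guard
#' @noRd
exact_choose <- function(n, k) {
  if (k < 0 || k > n) return(0)
  k <- min(k, n - k)
  r <- 1
  for (i in seq_len(k)) {
    r <- check_exact(r * (n - k + i)) / i  # each step is an exact integer
  }
  r
}

#' Exact multinomial coefficient of a vector of counts
#' @noRd
exact_multinomial <- function(counts) {
  tot <- 0
  r <- 1
  for (c_i in counts) {
    tot <- tot + c_i
    r <- exact_prod(r, exact_choose(tot, c_i))
  }
  r
}

exact_factorial <- function(n) {
  r <- 1
  for (i in seq_len(n)) r <- check_exact(r * i)
  r
}

#' All weak compositions of v into k non-negative parts
#' @return matrix with k columns, one composition per row
#' @noRd
weak_compositions <- function(v, k) {
  if (k == 0L) {
    if (v == 0) return(matrix(numeric(), 1L, 0L)) else
      return(matrix(numeric(), 0L, 0L))
  }
  if (k == 1L) return(matrix(v, 1L, 1L))
  out <- NULL
  for (first in 0:v) {
    rest <- weak_compositions(v - first, k - 1L)
    out <- rbind(out, cbind(first, rest, deparse.level = 0))
  }
  out
}

#' All compositions of n into k positive parts
#' @noRd
compositions_positive <- function(n, k) {
  if (k > n) return(matrix(integer(), 0L, k))
  weak_compositions(n - k, k) + 1
}
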