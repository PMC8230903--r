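# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Run an expression under a local RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so generators are pure functions of their arguments.
#'
#' @param seed integer seed, or `NULL` to leave the RNG stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a base seed and an index, staying well
# inside 32-bit integer range.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483629)
}

#' Pool-adjacent-violators for a non-increasing fit
#'
#' Solves `min_a 0.5 * sum((a - y)^2)` subject to
#' `a[1] >= a[2] >= ... >= a[n]` (no sign restriction).
#'
#' @param y numeric vector.
#' @return the isotonic (non-increasing) projection of `y`.
#' @keywords internal
pav_nonincreasing <- function(y) {
  n <- length(y)
  if (n <= 1L) return(y)
  # standard PAV on -y for a non-decreasing fit
  vals <- -y
  w <- rep(1, n)
  # block representation
  bv <- numeric(n); bw <- numeric(n); bn <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    bv[m] <- vals[i]; bw[m] <- 1; bn[m] <- 1L
    while (m > 1L && bv[m - 1L] > bv[m]) {
      tot <- bw[m - 1L] + bw[m]
      bv[m - 1L] <- (bw[m - 1L] * bv[m - 1L] + bw[m] * bv[m]) / tot
      bw[m - 1L] <- tot
      bn[m - 1L] <- bn[m - 1L] + bn[m]
      m <- m - 1L
    }
  }
  out <- numeric(n)
  pos <- 1L
  for (b in seq_len(m)) {
    out[pos:(pos + bn[b] - 1L)] <- bv[b]
    pos <- pos + bn[b]
  }
  -out
}

#' Adjusted Rand index between two labellings
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("labellings differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
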