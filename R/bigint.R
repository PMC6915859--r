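# Exact non-negative integer arithmetic for the counting formulas.
#
# Counts reach well beyond 2^53 (e.g. the factorial terms of the
# closed forms at n = 20), so no floating point is used anywhere in
# the counting module.  A bigint is a little-endian vector of base-1e6
# limbs; all limb products stay far below 2^53.  Only the operations
# the recurrences need are implemented: addition, subtraction (the
# formulas never go negative), multiplication, and comparison.

BIGBASE <- 1e6

#' Arbitrary-precision non-negative integers
#'
#' Construct a `bigint` from a non-negative integer-valued numeric
#' (exact up to 2^53) or a decimal string.  `bigint`s support `+`,
#' `-`, `*`, comparison operators, `as.character()` and
#' `as.numeric()`; they are used for all exact counts.
#'
#' @param x Non-negative integer-valued numeric, decimal string, or a
#'   `bigint` (returned unchanged).
#' @return A `bigint`.
#' @examples
#' as.character(bigint("123456789012345678901234") + bigint(1))
#' @export
bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    s <- gsub(",", "", x, fixed = TRUE)
    if (!grepl("^[0-9]+$", s))
      stop_tcnet("parameter", "bigint string must be a non-negative integer")
    digs <- nchar(s)
    nl <- ceiling(digs / 6)
    limbs <- numeric(nl)
    for (i in seq_len(nl)) {
      hi <- digs - 6 * (i - 1)
      lo <- max(1, hi - 5)
      limbs[i] <- as.numeric(substr(s, lo, hi))
    }
    return(big_norm(limbs))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != round(x) || x > 2^53)
    stop_tcnet("parameter", "bigint requires a non-negative integer value")
  limbs <- numeric(0)
  x <- as.numeric(x)
  repeat {
    limbs <- c(limbs, x %% BIGBASE)
    x <- x %/% BIGBASE
    if (x == 0) break
  }
  big_norm(limbs)
}

big_norm <- function(limbs) {
  # carry-propagate and strip leading zero limbs
  carry <- 0
  for (i in seq_along(limbs)) {
    v <- limbs[i] + carry
    limbs[i] <- v %% BIGBASE
    carry <- v %/% BIGBASE
  }
  while (carry > 0) {
    limbs <- c(limbs, carry %% BIGBASE)
    carry <- carry %/% BIGBASE
  }
  while (length(limbs) > 1 && limbs[length(limbs)] == 0)
    limbs <- limbs[-length(limbs)]
  structure(limbs, class = "bigint")
}

big_add <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- max(la, lb)
  big_norm(c(unclass(a), numeric(n - la)) + c(unclass(b), numeric(n - lb)))
}

big_sub <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (big_cmp(a, b) < 0)
    stop_tcnet("parameter", "bigint subtraction would be negative")
  n <- max(la, lb)
  x <- c(unclass(a), numeric(n - la)) - c(unclass(b), numeric(n - lb))
  for (i in seq_len(n)) {
    if (x[i] < 0) {
      x[i] <- x[i] + BIGBASE
      x[i + 1] <- x[i + 1] - 1
    }
  }
  big_norm(x)
}

big_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  out <- numeric(length(a) + length(b))
  # schoolbook with interleaved carrying so partial sums stay < 2^53
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    carry <- 0
    for (j in seq_along(b)) {
      v <- out[i + j - 1] + a[i] * b[j] + carry
      out[i + j - 1] <- v %% BIGBASE
      carry <- v %/% BIGBASE
    }
    k <- i + length(b)
    while (carry > 0) {
      v <- out[k] + carry
      out[k] <- v %% BIGBASE
      carry <- v %/% BIGBASE
      k <- k + 1
    }
  }
  big_norm(out)
}

big_cmp <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

#' @export
Ops.bigint <- function(e1, e2) {
  a <- bigint(e1)
  b <- bigint(e2)
  switch(.Generic,
    "+" = big_add(a, b),
    "-" = big_sub(a, b),
    "*" = big_mul(a, b),
    "==" = big_cmp(a, b) == 0,
    "!=" = big_cmp(a, b) != 0,
    "<" = big_cmp(a, b) < 0,
    "<=" = big_cmp(a, b) <= 0,
    ">" = big_cmp(a, b) > 0,
    ">=" = big_cmp(a, b) >= 0,
    stop_tcnet("parameter",
               sprintf("operation %s is not defined for bigint", .Generic))
  )
}

#' @export
as.character.bigint <- function(x, ...) {
  limbs <- rev(unclass(x))
  paste0(limbs[1], paste(sprintf("%06d", limbs[-1]), collapse = ""))
}

#' @export
as.double.bigint <- function(x, ...) {
  limbs <- unclass(x)
  sum(limbs * BIGBASE^(seq_along(limbs) - 1))
}

#' @export
format.bigint <- function(x, ...) as.character(x)

#' @export
print.bigint <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

# product of the integers in `v` as a bigint
big_prod <- function(v) {
  out <- bigint(1)
  for (x in v) out <- big_mul(out, bigint(x))
  out
}

big_factorial <- function(n) if (n <= 1) bigint(1) else big_prod(2:n)

# (2n - 1)!! = 1 * 3 * ... * (2n - 1); the number of phylogenetic
# trees on n + 1 taxa is (2n - 1)!!
big_double_factorial_odd <- function(m) {
  if (m <= 0) return(bigint(1))
  big_prod(seq(1, m, by = 2))
}

big_pow2 <- function(n) big_prod(rep(2, n))
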