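# Minimal exact nonnegative integer arithmetic for ensemble counting.
#
# Numbers are little-endian numeric vectors of base-1e6 limbs. With <= ~500
# accumulated limb products per digit (each < 1e12) every intermediate stays
# far below 2^53, so plain doubles are exact. Only the operations the
# inclusion-exclusion counter needs are provided.

.BIG_BASE <- 1e6

.bigNorm <- function(x) {
  carry <- 0
  i <- 1L
  while (i <= length(x) || carry > 0) {
    if (i > length(x)) x[i] <- 0
    v <- x[i] + carry
    carry <- floor(v / .BIG_BASE)
    x[i] <- v - carry * .BIG_BASE
    i <- i + 1L
  }
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

.bigZero <- function() 0

.bigFromInt <- function(x) {
  stopifnot(x >= 0, x < 2^53)
  .bigNorm(x)
}

.bigAdd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  .bigNorm(a + b)
}

# requires a >= b
.bigSub <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  r <- a - b
  for (i in seq_len(n)) {
    if (r[i] < 0) {
      r[i] <- r[i] + .BIG_BASE
      if (i == n) stop("bignum subtraction underflow")
      r[i + 1L] <- r[i + 1L] - 1
    }
  }
  .bigNorm(r)
}

.bigMul <- function(a, b) {
  if ((length(a) == 1L && a[1] == 0) || (length(b) == 1L && b[1] == 0))
    return(0)
  # limbs < 1e6 so each accumulated digit stays < length(a) * 1e12 << 2^53
  # for the ~15-limb numbers this counter manipulates
  r <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    r[idx] <- r[idx] + a[i] * b
  }
  .bigNorm(r)
}

.bigPow <- function(base, e) {
  e <- as.integer(e)
  if (e == 0L) return(.bigFromInt(1))
  r <- .bigFromInt(1)
  b <- base
  while (e > 0L) {
    if (e %% 2L == 1L) r <- .bigMul(r, b)
    e <- e %/% 2L
    if (e > 0L) b <- .bigMul(b, b)
  }
  r
}

.bigCmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

.bigToString <- function(x) {
  digs <- vapply(rev(seq_along(x)), function(i)
    formatC(x[i], width = 6, flag = "0", format = "d"), "")
  s <- sub("^0+", "", paste(digs, collapse = ""))
  if (s == "") "0" else s
}

.bigLog10 <- function(x) {
  if (length(x) == 1L && x[1] == 0) return(-Inf)
  top <- 0
  n <- length(x)
  # use up to three leading limbs for the mantissa
  for (i in seq_len(min(3L, n))) top <- top + x[n - i + 1L] * .BIG_BASE^(-i + 1L)
  log10(top) + (n - 1L) * log10(.BIG_BASE)
}

# Pascal-triangle cache for exact binomials
.bigCache <- new.env(parent = emptyenv())

.bigBinom <- function(n, k) {
  if (k < 0 || k > n) return(0)
  key <- paste0("C", n)
  if (is.null(.bigCache[[key]])) {
    row <- list(.bigFromInt(1))
    if (n > 0) {
      prev <- .bigBinomRow(n - 1L)
      for (j in seq_len(n + 1L) - 1L) {
        a <- if (j > 0) prev[[j]] else 0
        b <- if (j < n) prev[[j + 1L]] else 0
        row[[j + 1L]] <- .bigAdd(a, b)
      }
    }
    .bigCache[[key]] <- row
  }
  .bigCache[[key]][[k + 1L]]
}

.bigBinomRow <- function(n) {
  .bigBinom(n, 0L)  # ensures the row is built
  .bigCache[[paste0("C", n)]]
}
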