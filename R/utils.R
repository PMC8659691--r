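## Internal numerical helpers.

# Pairwise log(exp(a) + exp(b)), vectorized, stable for large |a - b|.
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  # if both are -Inf, m is -Inf and the above yields NaN
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log(p / (1 - p)) for a probability
logodds <- function(p) log(p) - log1p(-p)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a finite number")
  if (open && (x <= 0 || x >= 1)) stop_domain(name, " must be in (0, 1)")
  if (!open && (x < 0 || x > 1)) stop_domain(name, " must be in [0, 1]")
  x
}

# Halton low-discrepancy sequence in [0,1)^d (bases = first d primes).
# `skip` drops initial points so independent scans can use disjoint blocks.
halton <- function(n, d, skip = 0L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  stopifnot(d <= length(primes))
  idx <- seq_len(n) + skip
  out <- matrix(0, n, d)
  for (j in seq_len(d)) {
    b <- primes[j]
    x <- numeric(n)
    f <- 1
    i <- idx
    while (any(i > 0)) {
      f <- f / b
      x <- x + f * (i %% b)
      i <- i %/% b
    }
    out[, j] <- x
  }
  out
}

# Convert +/-1 to {0,1}
as01 <- function(choice) (choice + 1) / 2
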