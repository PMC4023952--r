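#' Decile bin of a rating value
#'
#' Maps rating values on the 1--1000 scale to their decile interval,
#' using the closed bins \[1,100\], \[101,200\], ..., \[901,1000\].
#'
#' @param x integer-valued ratings in \[1, 1000\].
#' @return integer bin indices in 1..10.
#' @export
decile_of <- function(x) {
  if (any(x < 1 | x > 1000)) {
    stop("values must lie in [1, 1000]", call. = FALSE)
  }
  as.integer((x - 1) %/% 100) + 1L
}

#' Empirical decile proportions of a set of ratings
#'
#' @param values ratings in \[1, 1000\]; must be non-empty.
#' @return numeric vector of length 10 summing to 1.
#' @export
decile_proportions <- function(values) {
  if (length(values) == 0L) stop("empty value set", call. = FALSE)
  tabulate(decile_of(values), nbins = 10L) / length(values)
}

# Integerize `total * p` by largest-remainder rounding, optionally capping
# each cell at `cap`. Ties on the fractional part are broken by bin index,
# so the result is deterministic.
largest_remainder <- function(p, total, cap = Inf) {
  stopifnot(length(p) >= 1L, all(p >= 0), total >= 0)
  if (sum(p) <= 0) stop("probabilities sum to zero", call. = FALSE)
  p <- p / sum(p)
  target <- p * total
  counts <- pmin(floor(target), cap)
  short <- total - sum(counts)
  if (short > 0) {
    frac <- target - floor(target)
    frac[counts >= cap] <- -Inf
    ord <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE), method = "radix")
    i <- 0L
    while (short > 0) {
      i <- i + 1L
      if (i > length(ord)) stop("cap too tight to reach the requested total", call. = FALSE)
      b <- ord[i]
      if (counts[b] < cap) {
        counts[b] <- counts[b] + 1L
        short <- short - 1L
      }
    }
  }
  as.integer(counts)
}

# Deterministic per-participant seed derived from a run seed, kept inside
# the 32-bit integer range.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 9973
  as.integer(s %% 2147483629 + 1)
}

# Run `expr` with a local RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
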