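#' Generate a decile-constrained uniform stimulus set
#'
#' Draws `n` integer ratings uniformly from \[1, 1000\] under the constraint
#' that each decile interval \[1,100\], \[101,200\], ..., \[901,1000\]
#' contains exactly `per_decile` values. Values are drawn without
#' replacement within each decile, so all values are distinct at the
#' default sizes. The returned sequence is in a random presentation order
#' with half/condition tags unassigned (see [order_by_condition()]).
#'
#' @param n total number of values; must equal `10 * per_decile`.
#' @param per_decile values per decile; at most 100.
#' @param seed integer seed; identical seeds give bit-identical sets.
#' @param exclude values to avoid, e.g. the exposure set E when drawing
#'   the withheld set T so the two are disjoint.
#' @return a stimulus-set tibble with columns `value`, `order_index`,
#'   `half` (NA until assigned), `condition` (NA until assigned), `decile`.
#' @export
#' @examples
#' E <- generate_uniform_set(120, 12, seed = 1)
#' table(E$decile)
generate_uniform_set <- function(n = 120, per_decile = 12, seed = 1,
                                 exclude = integer(0)) {
  if (n != 10 * per_decile) {
    stop("n must equal 10 * per_decile", call. = FALSE)
  }
  if (per_decile > 100) {
    stop("per_decile cannot exceed the 100 integers available per decile", call. = FALSE)
  }
  values <- with_seed(seed, {
    v <- unlist(lapply(0:9, function(d) {
      pool <- setdiff((d * 100 + 1):(d * 100 + 100), exclude)
      if (length(pool) < per_decile) {
        stop("not enough unexcluded integers left in decile ", d + 1, call. = FALSE)
      }
      sample(pool, per_decile, replace = FALSE)
    }))
    sample(v)
  })
  new_stimulus_set(values, half = NA_character_, condition = NA_character_,
                   seed = seed)
}

new_stimulus_set <- function(values, half, condition, seed) {
  out <- tibble::tibble(
    value = as.integer(values),
    order_index = seq_along(values),
    half = half,
    condition = condition,
    decile = decile_of(values)
  )
  attr(out, "seed") <- seed
  class(out) <- c("stimulus_set", class(out))
  out
}

#' Validate stimulus-set invariants
#'
#' Checks the design counts: `n` values in \[1, 1000\], equal per-decile
#' counts, and (once half tags are assigned) an even split into halves A
#' and B. Invisibly returns the set; errors otherwise.
#'
#' @param x a stimulus-set tibble.
#' @param per_decile expected count per decile.
#' @export
validate_stimulus_set <- function(x, per_decile = nrow(x) / 10) {
  stopifnot(is.data.frame(x), all(c("value", "order_index", "half", "decile") %in% names(x)))
  if (any(x$value < 1 | x$value > 1000)) stop("values outside [1, 1000]", call. = FALSE)
  counts <- tabulate(x$decile, nbins = 10L)
  if (!all(counts == per_decile)) {
    stop("per-decile counts are not all ", per_decile, call. = FALSE)
  }
  if (!anyNA(x$half)) {
    h <- table(factor(x$half, levels = c("A", "B")))
    if (h[["A"]] != h[["B"]]) stop("halves A and B are not of equal size", call. = FALSE)
  }
  invisible(x)
}

#' Decile probabilities of a Beta distribution
#'
#' Discretizes Beta(`alpha`, `beta`) on (0, 1) into the ten decile bins:
#' bin i holds CDF(i/10) - CDF((i-1)/10). Beta(1, 1) gives the uniform
#' profile; equal shape parameters give a palindromic profile, peaked for
#' shapes above 1 and U-shaped (bimodal) below 1.
#'
#' @param alpha,beta positive shape parameters.
#' @return numeric vector of length 10 summing to 1.
#' @export
#' @examples
#' beta_decile_probabilities(2.4, 2.4)
beta_decile_probabilities <- function(alpha, beta = alpha) {
  if (alpha <= 0 || beta <= 0) stop("shape parameters must be positive", call. = FALSE)
  p <- diff(stats::pbeta(seq(0, 1, by = 0.1), alpha, beta))
  p / sum(p)
}

#' Partition a uniform set into unimodal and bimodal halves
#'
#' Splits the 120-value exposure set E into E_a (unimodal, Beta-shaped)
#' and E_b, the reflection of E_a with respect to the uniform
#' distribution: per decile, E_a receives `c_i` values — the Beta(alpha,
#' alpha) decile probabilities scaled to 60 and integerized by
#' largest-remainder rounding — and E_b receives the complementary
#' `per_decile - c_i`, so the two count profiles mirror each other about
#' the uniform count vector. Which specific members of a decile go to E_a
#' is decided uniformly at random.
#'
#' @param E a stimulus set from [generate_uniform_set()].
#' @param alpha shape parameter of the symmetric Beta target (default 2.4).
#' @param seed integer seed for the within-decile assignment.
#' @return list with integer vectors `E_a`, `E_b` (60 values each at the
#'   default design) and `counts_a`, the per-decile target counts of E_a.
#' @export
partition_unimodal_bimodal <- function(E, alpha = 2.4, seed = 1) {
  validate_stimulus_set(E)
  per_decile <- nrow(E) / 10
  half_n <- nrow(E) / 2
  probs <- beta_decile_probabilities(alpha, alpha)
  counts_a <- largest_remainder(probs, half_n, cap = per_decile)
  picks <- with_seed(seed, {
    lapply(1:10, function(d) {
      members <- E$value[E$decile == d]
      if (counts_a[d] > length(members)) {
        stop("target count exceeds the values available in decile ", d, call. = FALSE)
      }
      idx <- sample(length(members), counts_a[d])
      list(a = members[idx], b = members[-idx])
    })
  })
  list(
    E_a = as.integer(unlist(lapply(picks, `[[`, "a"))),
    E_b = as.integer(unlist(lapply(picks, `[[`, "b"))),
    counts_a = counts_a
  )
}

#' Arrange the two halves into a presentation order
#'
#' Builds the ordered exposure sequence for one participant. In the
#' unimodal-bimodal condition (`"UB"`) a random permutation of E_a fills
#' positions 1--60 and of E_b positions 61--120; `"BU"` is the reverse;
#' in the uniform condition (`"UN"`) all 120 values are permuted jointly
#' so the half tags interleave at random.
#'
#' @param E_a,E_b integer value vectors of equal length.
#' @param condition one of `"UB"`, `"BU"`, `"UN"` (the forms `"U-B"`,
#'   `"B-U"` are accepted and canonicalized).
#' @param seed integer seed.
#' @return a stimulus-set tibble with `half` and `condition` assigned.
#' @export
order_by_condition <- function(E_a, E_b, condition, seed = 1) {
  condition <- canonical_condition(condition)
  if (length(E_a) != length(E_b)) stop("halves must be of equal size", call. = FALSE)
  with_seed(seed, {
    a <- sample(E_a)
    b <- sample(E_b)
    if (condition == "UB") {
      values <- c(a, b)
      half <- rep(c("A", "B"), each = length(a))
    } else if (condition == "BU") {
      values <- c(b, a)
      half <- rep(c("B", "A"), each = length(a))
    } else {
      pos <- sample(2L * length(a))
      values <- c(a, b)[pos]
      half <- rep(c("A", "B"), each = length(a))[pos]
    }
    new_stimulus_set(values, half = half, condition = condition, seed = seed)
  })
}

canonical_condition <- function(condition) {
  key <- toupper(gsub("-", "", condition))
  if (!key %in% c("UB", "BU", "UN")) {
    stop("unknown condition: ", condition, " (expected UB, BU or UN)", call. = FALSE)
  }
  key
}

#' Build the eight sampling-task matrices
#'
#' Produces 8 trials of 30 values each: 4 "old" matrices drawn from the
#' exposed set E and 4 "new" matrices from the withheld set T. Each
#' matrix holds exactly 3 values per decile, and the four same-provenance
#' matrices partition their 120-value source set (no value is reused), so
#' together they exhaust it. The order of the 8 trials is randomized.
#'
#' @param E,T stimulus sets; disjoint value multisets.
#' @param seed integer seed.
#' @return tibble with columns `trial_index` (1--8), `provenance`
#'   (`"old"`/`"new"`), `value`, `decile`; 240 rows.
#' @export
generate_matrices <- function(E, T, seed = 1) {
  validate_stimulus_set(E); validate_stimulus_set(T)
  if (length(intersect(E$value, T$value)) > 0) {
    stop("E and T must be disjoint", call. = FALSE)
  }
  per_matrix_decile <- nrow(E) / 10 / 4
  if (per_matrix_decile != round(per_matrix_decile)) {
    stop("per-decile count must split evenly across 4 matrices", call. = FALSE)
  }
  with_seed(seed, {
    deal <- function(set, provenance) {
      cols <- lapply(1:10, function(d) {
        m <- sample(set$value[set$decile == d])
        matrix(m, nrow = 4)  # row = matrix id, 3 values per decile each
      })
      vals <- do.call(cbind, cols)
      do.call(rbind, lapply(1:4, function(i) {
        tibble::tibble(provenance = provenance, value = as.integer(vals[i, ]))
      }))
    }
    trials <- rbind(deal(E, "old"), deal(T, "new"))
    trial_of <- rep(1:8, each = 30)
    shuffled <- sample(8)
    trials <- trials[order(match(trial_of, shuffled)), ]
    trials$trial_index <- rep(1:8, each = 30)
    trials$decile <- decile_of(trials$value)
    tibble::as_tibble(trials[, c("trial_index", "provenance", "value", "decile")])
  })
}

#' Construct the seven identification-task histogram prototypes
#'
#' One uniform histogram plus three unimodal prototypes of strictly
#' decreasing variance and three bimodal prototypes of strictly
#' increasing variance, all built as symmetric Beta(a, a) decile
#' profiles: shapes above 1 are single-peaked, shapes below 1 are
#' valley-shaped, and Beta(1, 1) is the uniform prototype.
#'
#' @param unimodal_shapes three shape values > 1, strictly increasing
#'   (larger shape = smaller variance).
#' @param bimodal_shapes three shape values < 1, strictly decreasing
#'   (smaller shape = larger variance).
#' @return list of 7 prototypes, each a list with `profile` (10
#'   proportions), `shape` (`"uniform"`, `"unimodal"`, `"bimodal"`),
#'   `variance_rank` (NA for uniform) and `variance` (on the unit scale,
#'   from bin midpoints). The uniform prototype is first.
#' @export
generate_prototypes <- function(unimodal_shapes = c(2, 4, 8),
                                bimodal_shapes = c(0.8, 0.5, 0.3)) {
  if (length(unimodal_shapes) != 3 || any(unimodal_shapes <= 1) ||
      any(diff(unimodal_shapes) <= 0)) {
    stop("unimodal shapes must be three values > 1, strictly increasing", call. = FALSE)
  }
  if (length(bimodal_shapes) != 3 || any(bimodal_shapes >= 1) ||
      any(diff(bimodal_shapes) >= 0)) {
    stop("bimodal shapes must be three values < 1, strictly decreasing", call. = FALSE)
  }
  mids <- seq(0.05, 0.95, by = 0.1)
  proto <- function(a, shape, rank) {
    p <- beta_decile_probabilities(a, a)
    mu <- sum(p * mids)
    list(profile = p, shape = shape, variance_rank = rank,
         variance = sum(p * (mids - mu)^2))
  }
  out <- c(
    list(proto(1, "uniform", NA_integer_)),
    lapply(1:3, function(i) proto(unimodal_shapes[i], "unimodal", i)),
    lapply(1:3, function(i) proto(bimodal_shapes[i], "bimodal", i))
  )
  uni_var <- vapply(out[2:4], `[[`, numeric(1), "variance")
  bi_var <- vapply(out[5:7], `[[`, numeric(1), "variance")
  stopifnot(all(diff(uni_var) < 0), all(diff(bi_var) > 0))
  class(out) <- "histogram_prototypes"
  out
}
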