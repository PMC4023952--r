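#' Encode a stimulus sequence into exemplar memory
#'
#' The lazy model stores every presented value verbatim in long-term
#' memory together with its presentation position; no statistics are
#' computed at encoding time. Encoding is lossless: [decode()] returns
#' the presented values in order.
#'
#' @param sequence a stimulus-set tibble, or a plain vector of values in
#'   presentation order.
#' @return list of class `exemplar_memory` with `value` and `t`
#'   (encoding index, 1..N).
#' @export
encode <- function(sequence) {
  values <- if (is.data.frame(sequence)) {
    sequence$value[order(sequence$order_index)]
  } else {
    sequence
  }
  if (any(values < 1 | values > 1000)) stop("values must lie in [1, 1000]", call. = FALSE)
  structure(list(value = as.numeric(values), t = seq_along(values)),
            class = "exemplar_memory")
}

#' @rdname encode
#' @param memory an `exemplar_memory`.
#' @export
decode <- function(memory) {
  stopifnot(inherits(memory, "exemplar_memory"))
  memory$value
}

#' Retrieval policy and short-term memory capacity
#'
#' Describes how exemplars are retrieved at judgment time. Under the
#' `uniform` policy every exemplar has equal retrieval weight — the
#' random-sampling assumption of the lazy model. The `recency` policy
#' weights the exemplar at position t by `decay^(N - t)` and `primacy`
#' by `decay^(t - 1)`, so weights fall off geometrically away from the
#' favored end; `decay = 1` recovers uniform weighting.
#'
#' @param policy `"uniform"`, `"recency"` or `"primacy"`.
#' @param decay weight ratio per step, in (0, 1\].
#' @param k short-term memory sample size (default 4, the usual 4 +/- 2
#'   capacity estimate).
#' @param k_jitter if TRUE, simulated participants draw their own k
#'   uniformly from {2, ..., 6}.
#' @param n_pools number of independent retrievals pooled when a task
#'   needs a full profile (production, identification, sampling tasks).
#' @param with_replacement sample exemplars with replacement within one
#'   retrieval (default FALSE: a value active in STM is not re-retrieved).
#' @param response_noise_sd SD (rating units) of optional zero-mean
#'   Gaussian noise added to descriptive estimates; 0 disables it.
#' @return list of class `sampling_scheme`.
#' @export
sampling_scheme <- function(policy = c("uniform", "recency", "primacy"),
                            decay = 1, k = 4, k_jitter = FALSE, n_pools = 5,
                            with_replacement = FALSE, response_noise_sd = 0) {
  policy <- match.arg(policy)
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (n_pools < 1) stop("n_pools must be at least 1", call. = FALSE)
  structure(list(policy = policy, decay = decay, k = as.integer(k),
                 k_jitter = isTRUE(k_jitter), n_pools = as.integer(n_pools),
                 with_replacement = isTRUE(with_replacement),
                 response_noise_sd = response_noise_sd),
            class = "sampling_scheme")
}

retrieval_weights <- function(memory, scheme) {
  n <- length(memory$value)
  switch(scheme$policy,
    uniform = rep(1, n),
    recency = scheme$decay^(n - memory$t),
    primacy = scheme$decay^(memory$t - 1)
  )
}

#' Retrieve one short-term memory sample
#'
#' Draws `k` exemplars from memory under the scheme's retrieval weights.
#' Without replacement (the default) the draw is a sequence of successive
#' weighted picks, each among the exemplars not yet retrieved.
#'
#' @param memory an [encode()]d exemplar memory.
#' @param scheme a [sampling_scheme()].
#' @param k sample size; defaults to the scheme's k.
#' @return numeric vector of `k` retrieved values.
#' @export
draw_sample <- function(memory, scheme = sampling_scheme(), k = scheme$k) {
  stopifnot(inherits(memory, "exemplar_memory"))
  n <- length(memory$value)
  if (!scheme$with_replacement && k > n) {
    stop("k exceeds the number of stored exemplars", call. = FALSE)
  }
  w <- retrieval_weights(memory, scheme)
  idx <- sample.int(n, k, replace = scheme$with_replacement, prob = w)
  memory$value[idx]
}

#' Descriptive statistics of an STM sample
#'
#' The three statistics probed by the descriptive task: the arithmetic
#' mean, the median (midpoint convention for even sizes), and the mean
#' absolute deviation — the mean of the distances of each value from
#' their common mean.
#'
#' @param sample non-empty numeric vector of retrieved values.
#' @return list with `mean`, `median`, `mad`.
#' @export
#' @examples
#' estimate_descriptives(c(4, 8, 12))  # mean 8, median 8, mad 8/3
estimate_descriptives <- function(sample) {
  if (length(sample) == 0) stop("empty sample", call. = FALSE)
  m <- mean(sample)
  list(mean = m, median = stats::median(sample), mad = mean(abs(sample - m)))
}

participant_k <- function(scheme) {
  if (scheme$k_jitter) sample(2:6, 1) else scheme$k
}

pooled_values <- function(memory, scheme, n_pools = scheme$n_pools) {
  k <- min(participant_k(scheme), length(memory$value))
  unlist(lapply(seq_len(n_pools), function(i) draw_sample(memory, scheme, k = k)))
}

#' Simulate a production-task response
#'
#' Pools `n_pools` independent STM retrievals, bins the pooled values
#' into the ten decile intervals, and scales the empirical proportions
#' up to the required `total` by largest-remainder rounding, so the
#' returned frequencies sum to `total` exactly as the task demands.
#'
#' @inheritParams draw_sample
#' @param total required sum of the produced frequencies (120 in the
#'   standard design).
#' @param n_pools number of pooled retrievals.
#' @return integer vector of 10 frequencies summing to `total`.
#' @export
simulate_production <- function(memory, scheme = sampling_scheme(), total = 120,
                                n_pools = scheme$n_pools) {
  pooled <- pooled_values(memory, scheme, n_pools)
  largest_remainder(decile_proportions(pooled), total)
}

#' Simulate an identification-task choice
#'
#' Compares the pooled-sample decile profile with each prototype profile
#' and returns the index of the prototype at minimal Euclidean distance;
#' exact ties are broken toward the uniform prototype, then toward the
#' lowest index.
#'
#' @inheritParams simulate_production
#' @param prototypes a [generate_prototypes()] list.
#' @return integer prototype index.
#' @export
simulate_identification <- function(memory, scheme = sampling_scheme(),
                                    prototypes = generate_prototypes(),
                                    n_pools = scheme$n_pools) {
  profile <- decile_proportions(pooled_values(memory, scheme, n_pools))
  d <- vapply(prototypes, function(p) sqrt(sum((p$profile - profile)^2)), numeric(1))
  best <- which(d <= min(d) + 1e-12)
  uniform_idx <- which(vapply(prototypes, `[[`, character(1), "shape") == "uniform")
  if (length(uniform_idx) && uniform_idx[1] %in% best) uniform_idx[1] else best[1]
}

#' Simulate a sampling-task selection
#'
#' Greedily picks 10 of the 30 matrix values: at each step the value
#' whose inclusion brings the selection's decile proportion profile
#' closest (Euclidean) to the remembered pooled profile is added. The
#' selection depends only on the remembered profile, never on whether
#' the matrix is old or new.
#'
#' @inheritParams simulate_production
#' @param matrix_values the 30 candidate values of one matrix trial.
#' @param n_select number of values to pick (10 in the standard design).
#' @return numeric vector of selected values.
#' @export
simulate_sampling_task <- function(memory, scheme = sampling_scheme(),
                                   matrix_values, n_pools = scheme$n_pools,
                                   n_select = 10) {
  if (length(matrix_values) < n_select) {
    stop("matrix has fewer values than the selection size", call. = FALSE)
  }
  target <- decile_proportions(pooled_values(memory, scheme, n_pools))
  remaining <- matrix_values
  selected <- numeric(0)
  for (step in seq_len(n_select)) {
    d <- vapply(remaining, function(v) {
      sqrt(sum((decile_proportions(c(selected, v)) - target)^2))
    }, numeric(1))
    pick <- which.min(d)
    selected <- c(selected, remaining[pick])
    remaining <- remaining[-pick]
  }
  selected
}

#' Eager on-line running estimates
#'
#' The eager comparator maintains running summaries during exposure and
#' never revisits raw data: after each value x the mean updates as
#' m <- m + eta (x - m) and then the variance as
#' v <- v + eta ((x - m)^2 - v), with the freshly updated mean. With the
#' default schedule eta_t = 1/t the mean trajectory is the exact running
#' sample mean; a fixed eta in (0, 1] gives an exponentially weighted
#' estimator that forgets early data.
#'
#' @param sequence values in presentation order (stimulus set or vector).
#' @param learning_rate fixed eta in (0, 1\], or NULL (default) for the
#'   eta_t = 1/t schedule.
#' @return tibble with columns `t`, `value`, `mean`, `variance`
#'   (trajectories of length N).
#' @export
eager_running_estimates <- function(sequence, learning_rate = NULL) {
  values <- if (is.data.frame(sequence)) sequence$value[order(sequence$order_index)] else sequence
  if (length(values) == 0) stop("empty sequence", call. = FALSE)
  if (!is.null(learning_rate) && (learning_rate <= 0 || learning_rate > 1)) {
    stop("learning_rate must be in (0, 1]", call. = FALSE)
  }
  n <- length(values)
  # estimates initialize at the first observation; there is no summary to
  # update before any data has been seen
  m <- values[1]; v <- 0
  means <- numeric(n); vars <- numeric(n)
  means[1] <- m
  for (t in seq_len(n)[-1]) {
    eta <- if (is.null(learning_rate)) 1 / t else learning_rate
    m <- m + eta * (values[t] - m)
    v <- v + eta * ((values[t] - m)^2 - v)
    means[t] <- m; vars[t] <- v
  }
  tibble::tibble(t = seq_len(n), value = values, mean = means, variance = vars)
}
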