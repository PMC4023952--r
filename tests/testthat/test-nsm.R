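test_that("encoding is lossless and preserves presentation order", {
  E <- generate_uniform_set(seed = 21)
  part <- partition_unimodal_bimodal(E, seed = 22)
  sq <- order_by_condition(part$E_a, part$E_b, "UB", seed = 23)

  mem <- encode(sq)
  expect_length(mem$value, 120)
  expect_equal(mem$t, 1:120)
  expect_equal(decode(mem), sq$value[order(sq$order_index)])

  half <- encode(sq$value[1:60])  # intermediate-test memory
  expect_length(half$value, 60)
  expect_equal(decode(half), sq$value[1:60])

  expect_error(encode(c(5, 2000)), "\\[1, 1000\\]")
})

test_that("sampling schemes validate their parameters", {
  expect_error(sampling_scheme(decay = 0), "decay")
  expect_error(sampling_scheme(decay = 1.5), "decay")
  expect_error(sampling_scheme(k = 0), "k must be")
  expect_error(sampling_scheme(n_pools = 0), "n_pools")
  expect_equal(sampling_scheme("recency", decay = 0.5)$policy, "recency")
})

test_that("an exhaustive draw returns the full memory under any policy", {
  mem <- encode(c(100, 300, 500, 700, 900))
  for (policy in c("uniform", "recency", "primacy")) {
    set.seed(24)
    s <- draw_sample(mem, sampling_scheme(policy, decay = 0.5, k = 5))
    expect_setequal(s, mem$value)
  }
  expect_error(draw_sample(mem, sampling_scheme(k = 6)), "exceeds")
})

test_that("uniform retrieval gives equal inclusion probability", {
  mem <- encode(c(100, 300, 500, 700))
  scheme <- sampling_scheme("uniform", k = 1)
  set.seed(25)
  draws <- replicate(20000, draw_sample(mem, scheme))
  freq <- table(factor(draws, levels = mem$value)) / 20000
  se3 <- 3 * sqrt(0.25 * 0.75 / 20000)
  expect_true(all(abs(freq - 0.25) < se3))
})

test_that("recency weights follow the enumerated geometric law", {
  mem <- encode(c(100, 500, 900))  # positions 1, 2, 3
  scheme <- sampling_scheme("recency", decay = 0.5, k = 1)
  # exact inclusion probabilities: decay^(N-t) normalized = (1/7, 2/7, 4/7)
  set.seed(26)
  draws <- replicate(30000, draw_sample(mem, scheme))
  freq <- as.numeric(table(factor(draws, levels = mem$value)) / 30000)
  expected <- c(1, 2, 4) / 7
  se3 <- 3 * sqrt(expected * (1 - expected) / 30000)
  expect_true(all(abs(freq - expected) < se3))

  # primacy mirrors recency
  pscheme <- sampling_scheme("primacy", decay = 0.5, k = 1)
  set.seed(27)
  pdraws <- replicate(30000, draw_sample(mem, pscheme))
  pfreq <- as.numeric(table(factor(pdraws, levels = mem$value)) / 30000)
  expect_true(all(abs(pfreq - rev(expected)) < se3))
})

test_that("descriptive estimates follow their verbal definitions", {
  d <- estimate_descriptives(c(4, 8, 12))
  expect_identical(d$mean, 8)
  expect_identical(d$median, 8)
  expect_equal(d$mad, 8 / 3, tolerance = 1e-15)

  s <- estimate_descriptives(7)
  expect_equal(s$mean, 7)
  expect_equal(s$median, 7)
  expect_equal(s$mad, 0)

  even <- estimate_descriptives(c(2, 4, 6, 10))
  expect_equal(even$median, 5)  # midpoint convention

  expect_error(estimate_descriptives(numeric(0)), "empty")
})

test_that("simulated production frequencies sum to the total and converge", {
  E <- generate_uniform_set(seed = 28)
  mem <- encode(E$value)

  set.seed(29)
  counts <- simulate_production(mem, sampling_scheme(n_pools = 1000), total = 120)
  expect_equal(sum(counts), 120)
  expect_true(all(abs(counts - 12) <= 2))  # law of large numbers at 4000 pooled values

  # full-information limit: one exhaustive retrieval reproduces the truth
  exhaustive <- sampling_scheme(k = 120, n_pools = 1)
  set.seed(30)
  expect_equal(simulate_production(mem, exhaustive, total = 120), rep(12L, 10))

  set.seed(31)
  a <- simulate_production(mem, sampling_scheme(), total = 120)
  set.seed(31)
  b <- simulate_production(mem, sampling_scheme(), total = 120)
  expect_identical(a, b)
})

test_that("identification self-matches under exhaustive sampling and distorts at k = 4", {
  protos <- generate_prototypes()
  # memory whose decile counts follow the most-peaked unimodal prototype
  counts <- lazystat:::largest_remainder(protos[[4]]$profile, 120)
  values <- unlist(mapply(function(d, n) rep((d - 1) * 100 + 50, n), 1:10, counts))
  mem <- encode(values)
  set.seed(32)
  pick <- simulate_identification(mem, sampling_scheme(k = 120, n_pools = 1), protos)
  expect_equal(pick, 4L)

  # uniform memory, well-pooled profile: uniform prototype wins the majority
  E <- generate_uniform_set(seed = 33)
  umem <- encode(E$value)
  set.seed(34)
  pooled_picks <- replicate(100, simulate_identification(umem, sampling_scheme(n_pools = 50), protos))
  expect_gt(mean(pooled_picks == 1), 0.5)

  # a single STM sample of 4 makes the profile lumpy: uniform wins far less often
  set.seed(35)
  single_picks <- replicate(300, simulate_identification(umem, sampling_scheme(k = 4, n_pools = 1), protos))
  expect_lt(mean(single_picks == 1), mean(pooled_picks == 1))
})

test_that("greedy matrix selection tracks the remembered profile, blind to provenance", {
  E <- generate_uniform_set(seed = 36)
  T_set <- generate_uniform_set(seed = 37, exclude = E$value)
  mats <- generate_matrices(E, T_set, seed = 38)
  m1 <- mats[mats$trial_index == 1, ]

  umem <- encode(E$value)
  set.seed(39)
  sel <- simulate_sampling_task(umem, sampling_scheme(n_pools = 50), m1$value)
  expect_length(sel, 10)
  expect_true(all(sel %in% m1$value))
  expect_gte(length(unique(decile_of(sel))), 8)  # near-uniform spread

  # memory concentrated in [401, 600]: every central candidate is taken
  cmem <- encode(rep(c(450, 550), 30))
  set.seed(40)
  csel <- simulate_sampling_task(cmem, sampling_scheme(n_pools = 50), m1$value)
  central_candidates <- m1$value[m1$decile %in% c(5, 6)]
  expect_true(all(central_candidates %in% csel))

  expect_error(simulate_sampling_task(umem, sampling_scheme(), m1$value[1:5]),
               "fewer values")
})

test_that("eager running estimates update as specified", {
  const <- eager_running_estimates(rep(42, 50), learning_rate = 0.2)
  expect_true(all(const$mean == 42))
  expect_lt(const$variance[50], 1e-10)

  exact <- eager_running_estimates(c(4, 8, 12))  # eta_t = 1/t schedule
  expect_equal(exact$mean[3], 8)
  expect_equal(exact$mean, cumsum(c(4, 8, 12)) / 1:3)

  # a forgetful eager learner reflects late (second-half) dispersion
  E <- generate_uniform_set(seed = 41)
  part <- partition_unimodal_bimodal(E, seed = 42)
  ub <- order_by_condition(part$E_a, part$E_b, "UB", seed = 43)
  traj <- eager_running_estimates(ub, learning_rate = 0.1)
  var_a <- mean((part$E_a - mean(part$E_a))^2)
  var_b <- mean((part$E_b - mean(part$E_b))^2)
  v_end <- traj$variance[120]
  expect_lt(abs(v_end - var_b), abs(v_end - var_a))

  expect_error(eager_running_estimates(1:3, learning_rate = 0), "learning_rate")
  expect_error(eager_running_estimates(1:3, learning_rate = 1.2), "learning_rate")
  expect_error(eager_running_estimates(numeric(0)), "empty")
})

test_that("per-participant k jitter stays inside the 4 +/- 2 band", {
  scheme <- sampling_scheme(k_jitter = TRUE)
  set.seed(44)
  ks <- replicate(200, lazystat:::participant_k(scheme))
  expect_true(all(ks %in% 2:6))
  expect_gt(length(unique(ks)), 1)
})
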