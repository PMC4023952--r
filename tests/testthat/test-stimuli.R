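test_that("uniform set generation honors the decile constraint and the contract", {
  E <- generate_uniform_set(120, 12, seed = 1)
  expect_equal(nrow(E), 120)
  expect_true(all(E$value >= 1 & E$value <= 1000))
  expect_equal(unname(tabulate(E$decile, 10)), rep(12L, 10))
  expect_equal(anyDuplicated(E$value), 0L)
  expect_equal(sort(E$order_index), 1:120)

  tiny <- generate_uniform_set(10, 1, seed = 99)
  expect_equal(unname(tabulate(tiny$decile, 10)), rep(1L, 10))
  expect_equal(anyDuplicated(tiny$value), 0L)

  expect_error(generate_uniform_set(121, 12), "10 \\* per_decile")
  expect_error(generate_uniform_set(1010, 101), "100 integers")
})

test_that("seeds control uniform sets: identical seeds reproduce, different seeds vary", {
  a <- generate_uniform_set(seed = 1)
  b <- generate_uniform_set(seed = 1)
  c <- generate_uniform_set(seed = 2)
  expect_identical(a$value, b$value)
  expect_false(identical(sort(a$value), sort(c$value)))
  expect_equal(tabulate(a$decile, 10), tabulate(c$decile, 10))
})

test_that("excluded values never enter a generated set", {
  E <- generate_uniform_set(seed = 3)
  T_set <- generate_uniform_set(seed = 4, exclude = E$value)
  expect_length(intersect(E$value, T_set$value), 0)
  expect_equal(unname(tabulate(T_set$decile, 10)), rep(12L, 10))
})

test_that("Beta decile probabilities match a quadrature oracle and the stated shapes", {
  expect_equal(beta_decile_probabilities(1, 1), rep(0.1, 10), tolerance = 1e-12)

  p <- beta_decile_probabilities(2.4, 2.4)
  expect_equal(p, rev(p), tolerance = 1e-12)  # palindromic
  expect_equal(sum(p), 1, tolerance = 1e-12)

  oracle <- vapply(1:10, function(i) {
    integrate(function(u) dbeta(u, 2.4, 2.4), (i - 1) / 10, i / 10,
              rel.tol = 1e-12)$value
  }, numeric(1))
  expect_equal(p, oracle, tolerance = 1e-8)

  expect_error(beta_decile_probabilities(0, 1), "positive")
  expect_error(beta_decile_probabilities(2.4, -1), "positive")
})

test_that("the unimodal/bimodal partition conserves E and mirrors about uniform", {
  E <- generate_uniform_set(seed = 5)
  part <- partition_unimodal_bimodal(E, alpha = 2.4, seed = 6)
  expect_length(part$E_a, 60)
  expect_length(part$E_b, 60)
  expect_setequal(c(part$E_a, part$E_b), E$value)

  counts_a <- tabulate(decile_of(part$E_a), 10)
  counts_b <- tabulate(decile_of(part$E_b), 10)
  expect_equal(counts_a + counts_b, rep(12L, 10))
  expect_equal(counts_a, part$counts_a)

  si_a <- si_from_production(counts_a, 60)$si
  si_b <- si_from_production(counts_b, 60)$si
  expect_gt(si_a, 0)
  expect_lt(si_b, 0)
  expect_equal(si_a, -si_b, tolerance = 1e-12)

  even <- partition_unimodal_bimodal(E, alpha = 1, seed = 6)
  expect_equal(tabulate(decile_of(even$E_a), 10), rep(6L, 10))
})

test_that("condition orderings place the halves as designed", {
  E <- generate_uniform_set(seed = 7)
  part <- partition_unimodal_bimodal(E, seed = 8)

  ub <- order_by_condition(part$E_a, part$E_b, "U-B", seed = 9)
  expect_true(all(ub$half[1:60] == "A"))
  expect_true(all(ub$half[61:120] == "B"))
  expect_identical(unique(ub$condition), "UB")

  bu <- order_by_condition(part$E_a, part$E_b, "BU", seed = 9)
  expect_true(all(bu$half[1:60] == "B"))
  first_quarter_si <- si_from_sample(bu$value[1:30])$si
  expect_lt(first_quarter_si, 0)  # early items are bimodal in B-U

  un <- order_by_condition(part$E_a, part$E_b, "UN", seed = 9)
  expect_setequal(un$value, ub$value)
  expect_gt(length(rle(un$half)$lengths), 2)  # halves interleave

  expect_error(order_by_condition(part$E_a, part$E_b, "XX"), "unknown condition")
  expect_error(order_by_condition(part$E_a, part$E_b[-1], "UB"), "equal size")
})

test_that("sampling matrices partition their sources, 3 values per decile", {
  E <- generate_uniform_set(seed = 10)
  T_set <- generate_uniform_set(seed = 11, exclude = E$value)
  mats <- generate_matrices(E, T_set, seed = 12)

  expect_equal(nrow(mats), 240)
  expect_equal(sort(unique(mats$trial_index)), 1:8)
  expect_equal(as.integer(table(mats$provenance)), c(120L, 120L))
  for (tr in 1:8) {
    m <- mats[mats$trial_index == tr, ]
    expect_equal(nrow(m), 30)
    expect_equal(unname(tabulate(m$decile, 10)), rep(3L, 10))
    expect_length(unique(m$provenance), 1)
  }
  expect_setequal(mats$value[mats$provenance == "old"], E$value)
  expect_setequal(mats$value[mats$provenance == "new"], T_set$value)
  expect_length(intersect(mats$value[mats$provenance == "new"], E$value), 0)

  expect_error(generate_matrices(E, E, seed = 1), "disjoint")
})

test_that("the seven histogram prototypes have the stated shapes and variance order", {
  protos <- generate_prototypes()
  expect_length(protos, 7)
  shapes <- vapply(protos, `[[`, character(1), "shape")
  expect_equal(sum(shapes == "uniform"), 1)
  expect_equal(sum(shapes == "unimodal"), 3)
  expect_equal(sum(shapes == "bimodal"), 3)

  vars <- vapply(protos, `[[`, numeric(1), "variance")
  expect_true(all(diff(vars[shapes == "unimodal"]) < 0))
  expect_true(all(diff(vars[shapes == "bimodal"]) > 0))

  si <- vapply(protos, function(p) shape_index(p$profile), numeric(1))
  expect_equal(si[shapes == "uniform"], 0, tolerance = 1e-12)
  expect_true(all(si[shapes == "unimodal"] > 0))
  expect_true(all(si[shapes == "bimodal"] < 0))

  expect_error(generate_prototypes(unimodal_shapes = c(0.5, 4, 8)), "> 1")
  expect_error(generate_prototypes(bimodal_shapes = c(0.3, 0.5, 0.8)), "< 1")
})

test_that("stimulus-set validation catches broken designs", {
  E <- generate_uniform_set(seed = 13)
  expect_silent(validate_stimulus_set(E))
  bad <- E
  bad$value[1] <- if (bad$decile[1] == 10) 1L else 1000L  # unbalances deciles
  bad$decile <- decile_of(bad$value)
  expect_error(validate_stimulus_set(bad), "per-decile")
})
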