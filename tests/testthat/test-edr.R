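test_that("Sorensen similarity matches direct set counts", {
  expect_equal(sorensen(c("a", "b"), c("a", "b")), 1)
  expect_equal(sorensen(c("a", "b"), c("c", "d")), 0)
  expect_equal(sorensen(c("a", "b", "c"), c("b", "c", "d")), 2 / 3, tolerance = 1e-12)
  expect_equal(sorensen(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE)), 0.5)
  expect_error(sorensen(character(0), character(0)), class = "geochipr_error_degenerate")
  expect_error(sorensen(c(FALSE, FALSE), c(FALSE, FALSE)),
               class = "geochipr_error_degenerate")
})

test_that("pair table enumerates all unordered pairs with the 0.01 substitution", {
  sim <- simulate_geochip(synthetic_design(n_probes = 300, rng_seed = 1))
  ab <- preprocess_geochip(sim$signals, sim$samples)
  pt <- pair_table(ab)
  expect_identical(nrow(pt), 66L)                       # C(12, 2)
  expect_identical(sum(pt$substituted), 12L)            # 4 * C(3, 2)
  expect_true(all(pt$distance[pt$substituted] == 0.01))
  expect_true(all(pt$raw_distance[pt$substituted] == 0))
  expect_true(all(pt$sorensen >= 0 & pt$sorensen <= 1))
  pe <- pair_table(ab, level = "elevation")
  expect_identical(nrow(pe), 6L)
  expect_error(pair_table(ab, category = "no_such_category"),
               class = "geochipr_error_empty")
})

test_that("noiseless power-law pairs are fitted exactly", {
  D <- c(rep(0.01, 12), rep(200, 27), rep(400, 18), rep(600, 9))
  for (z0 in c(0.01, 0.0042)) {
    S <- 0.8 * D^(-2 * z0)
    pairs <- tibble::tibble(distance = D, raw_distance = D, substituted = FALSE,
                            sorensen = S)
    fit <- fit_edr(pairs)
    expect_equal(fit$z, z0, tolerance = 1e-10)
    expect_equal(fit$r, -1, tolerance = 1e-10)
    expect_equal(10^fit$constant, 0.8, tolerance = 1e-9)
  }
  # constant similarity: zero slope
  flat <- tibble::tibble(distance = c(1, 10, 100), raw_distance = c(1, 10, 100),
                         substituted = FALSE, sorensen = 0.5)
  expect_equal(fit_edr(flat)$z, 0)
})

test_that("three-point fit matches the hand normal-equations oracle", {
  D <- c(10, 100, 1000); S <- c(0.9, 0.8, 0.7)
  hand <- edr_normal_equations(D, S)
  fit <- fit_edr(tibble::tibble(distance = D, raw_distance = D,
                                substituted = FALSE, sorensen = S))
  expect_equal(fit$slope, hand$slope, tolerance = 1e-12)
  expect_equal(fit$z, hand$z, tolerance = 1e-12)
  expect_equal(round(fit$z, 4), 0.0273)
})

test_that("fit matches the normal-equations oracle on random small pair tables", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:15, 1)
    D <- sample(c(0.01, 200, 400, 600), n, replace = TRUE)
    if (length(unique(D)) < 2) next
    S <- runif(n, 0.2, 0.99)
    hand <- edr_normal_equations(D, S)
    fit <- fit_edr(tibble::tibble(distance = D, raw_distance = D,
                                  substituted = FALSE, sorensen = S))
    expect_equal(fit$z, hand$z, tolerance = 1e-10)
    expect_equal(fit$constant, hand$intercept, tolerance = 1e-10)
  }
})

test_that("zero-similarity pairs are dropped and counted; degenerate fits error", {
  pairs <- tibble::tibble(distance = c(1, 10, 100, 1000),
                          raw_distance = c(1, 10, 100, 1000),
                          substituted = FALSE, sorensen = c(0.5, 0.4, 0, 0.3))
  fit <- fit_edr(pairs)
  expect_identical(fit$n_zero_dropped, 1L)
  expect_identical(fit$n_pairs, 3L)
  same_d <- tibble::tibble(distance = rep(5, 4), raw_distance = rep(5, 4),
                           substituted = FALSE, sorensen = runif(4))
  expect_error(fit_edr(same_d), class = "geochipr_error_degenerate")
})

test_that("bootstrap is deterministic under seed and degenerate-safe", {
  pairs <- make_null_pairs(3)
  fit <- fit_edr(pairs)
  b1 <- bootstrap_edr(fit, n_boot = 199, seed = 7)
  b2 <- bootstrap_edr(fit, n_boot = 199, seed = 7)
  expect_identical(b1$boot_slopes, b2$boot_slopes)
  b3 <- bootstrap_edr(fit, n_boot = 199, seed = 8)
  expect_false(identical(b1$boot_slopes, b3$boot_slopes))
  expect_length(b1$boot_slopes, 199)

  # noiseless input: every bootstrap slope equals the observed slope,
  # the t statistic is the 0/undefined case, handled as p = 1
  D <- c(rep(0.01, 6), rep(200, 6), rep(400, 6))
  S <- 0.9 * D^(-0.02)
  nl <- bootstrap_edr(fit_edr(tibble::tibble(distance = D, raw_distance = D,
                                             substituted = FALSE, sorensen = S)),
                      n_boot = 99, seed = 1)
  expect_true(all(abs(nl$boot_slopes - nl$slope) < 1e-12))
  expect_identical(nl$t_vs_observed, 0)
  expect_identical(nl$p_vs_observed, 1)
  expect_true(nl$reject_zero)
})

test_that("per-category family applies BH across the family", {
  sim <- simulate_geochip(synthetic_design(n_probes = 1500, rng_seed = 5))
  ab <- preprocess_geochip(sim$signals, sim$samples)
  fam <- category_edr_family(ab, n_boot = 49, seed = 2)
  expect_true(all(is.na(fam$error)))
  expect_equal(fam$p_slope_adj, bh_stepup(fam$p_slope), tolerance = 1e-12)
  expect_true(all(fam$p_slope_adj >= fam$p_slope - 1e-12))
  # all categories share one occupancy process: z values cluster near the truth
  expect_true(all(abs(fam$z - 0.01) < 0.006))

  # a family of one: adjusted p equals raw p
  one <- category_edr_family(ab, groups = "stress", n_boot = 0)
  expect_equal(one$p_slope_adj, one$p_slope)

  # unknown categories surface as flagged rows, not errors
  mix <- category_edr_family(ab, groups = c("stress", "nope"), n_boot = 0)
  expect_identical(sum(!is.na(mix$error)), 1L)
})

test_that("the substitution-distance diagnostic varies z continuously", {
  sim <- simulate_geochip(synthetic_design(n_probes = 500, rng_seed = 6))
  ab <- preprocess_geochip(sim$signals, sim$samples)
  sens <- edr_sensitivity(ab, d_zero_grid = c(0.01, 0.1, 1, 10, 100))
  expect_identical(nrow(sens), 5L)
  expect_true(all(is.finite(sens$z)))
  expect_gt(length(unique(sens$z)), 1)          # z responds to the substitution
  # moving the substituted distance closer to the real distances compresses
  # the log-distance axis and steepens the fitted slope
  expect_gt(abs(sens$z[5]), abs(sens$z[1]))
})

test_that("z and r are invariant to the logarithm base", {
  pairs <- make_null_pairs(9)
  f10 <- fit_edr(pairs, log_base = "10")
  fe <- fit_edr(pairs, log_base = "e")
  expect_equal(f10$z, fe$z, tolerance = 1e-12)
  expect_equal(f10$r, fe$r, tolerance = 1e-12)
})
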