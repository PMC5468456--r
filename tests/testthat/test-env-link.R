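test_that("Mantel test recovers identity and is permutation-deterministic", {
  set.seed(2)
  d <- dist(matrix(rnorm(8 * 4), 8))
  res <- mantel_test(d, d, n_perm = 199, seed = 5)
  expect_equal(res$statistic, 1)
  expect_equal(res$p.value, 1 / 200, tolerance = 1e-12)
  res2 <- mantel_test(d, d, n_perm = 199, seed = 5)
  expect_identical(res, res2)
  expect_error(mantel_test(dist(matrix(rnorm(6), 3)), dist(matrix(rnorm(6), 3))),
               class = "geochipr_error_config")
})

test_that("Mantel p at n = 4 matches full permutation enumeration", {
  set.seed(7)
  m1 <- as.matrix(dist(matrix(rnorm(8), 4)))
  m2 <- as.matrix(dist(matrix(rnorm(8), 4)))
  ut <- upper.tri(m1)
  r_obs <- cor(m1[ut], m2[ut])
  perms <- gtools_permutations_4()
  r_perm <- apply(perms, 1, function(p) cor(m1[ut], m2[p, p][ut]))
  p_exact <- mean(r_perm >= r_obs - 1e-12)
  res <- mantel_test(as.dist(m1), as.dist(m2), n_perm = 5000, seed = 3)
  # vegan enumerates all permutations for tiny n; allow one permutation of slack
  expect_lt(abs(res$p.value - p_exact), 1.5 / 24)
})

test_that("PERMANOVA matches a hand sum-of-squares decomposition on a toy", {
  set.seed(9)
  X <- matrix(rnorm(6 * 3), 6)
  d <- dist(X)
  g <- factor(rep(c("a", "b"), each = 3))
  dm2 <- as.matrix(d)^2
  n <- 6
  ss_t <- sum(dm2[upper.tri(dm2)]) / n
  ss_w <- sum(dm2[1:3, 1:3][upper.tri(dm2[1:3, 1:3])]) / 3 +
    sum(dm2[4:6, 4:6][upper.tri(dm2[4:6, 4:6])]) / 3
  ss_a <- ss_t - ss_w
  f_hand <- (ss_a / 1) / (ss_w / 4)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  expect_equal(res$pseudo_F, f_hand, tolerance = 1e-10)
  expect_equal(res$R2, ss_a / ss_t, tolerance = 1e-10)
})

test_that("PERMANOVA guards degenerate groupings and perfect separation", {
  d <- dist(matrix(rnorm(12), 6))
  expect_error(permanova(d, factor(rep("a", 6))), class = "geochipr_error_config")
  expect_error(permanova(d, factor(c("a", rep("b", 5)))),
               class = "geochipr_error_config")
  # perfect separation: zero within-group distance, positive between
  X <- rbind(matrix(0, 3, 2), matrix(1, 3, 2))
  res <- permanova(dist(X), gl(2, 3), n_perm = 999, seed = 2)
  expect_true(!is.finite(res$pseudo_F) || res$pseudo_F > 1e6)
  expect_lt(res$p.value, 0.15)
})

test_that("null Mantel and PERMANOVA p-values are roughly uniform (quick check)", {
  rej_m <- vapply(1:60, function(s) {
    set.seed(s)
    d1 <- dist(matrix(rnorm(12 * 5), 12))
    d2 <- dist(matrix(rnorm(12 * 3), 12))
    mantel_test(d1, d2, n_perm = 199, seed = s)$p.value <= 0.05
  }, logical(1))
  expect_lte(mean(rej_m), 0.15)
  expect_gte(mean(rej_m), 0)
})

test_that("VIF screening matches the closed form and drops collinear variables", {
  # exactly orthonormal, mean-zero predictors via QR against the intercept
  set.seed(3)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 3), 40))))[, -1]
  df <- tibble::tibble(x1 = Q[, 1], x2 = Q[, 2], x3 = Q[, 3])
  scr <- vif_screen(df, c("x1", "x2", "x3"))
  expect_equal(unname(scr$vifs), rep(1, 3), tolerance = 1e-10)
  expect_identical(nrow(scr$dropped), 0L)

  # sample correlation exactly 0.9 between x1 and x2, x3 orthogonal
  df2 <- tibble::tibble(x1 = Q[, 1], x2 = 0.9 * Q[, 1] + sqrt(1 - 0.81) * Q[, 2],
                        x3 = Q[, 3])
  scr2 <- vif_screen(df2, c("x1", "x2", "x3"), threshold = 20)
  expect_equal(unname(scr2$vifs[c("x1", "x2")]), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-8)

  # perfect collinearity: one of the pair is dropped with infinite VIF
  df3 <- tibble::tibble(x1 = rnorm(30), x3 = rnorm(30))
  df3$x2 <- 2 * df3$x1
  scr3 <- vif_screen(df3, c("x1", "x2", "x3"), threshold = 20)
  expect_identical(nrow(scr3$dropped), 1L)
  expect_true(is.infinite(scr3$dropped$vif[1]))
  expect_true(scr3$dropped$variable[1] %in% c("x1", "x2"))
})

test_that("Pearson screen reports BH-adjusted p-values and untested pairs", {
  sim <- simulate_geochip(synthetic_design(n_probes = 600, rng_seed = 4))
  ab <- preprocess_geochip(sim$signals, sim$samples)
  ca <- category_abundance(ab)
  expect_equal(sum(ca$rel_abundance[ca$sample_id == ca$sample_id[1]]), 1,
               tolerance = 1e-9)
  scr <- pearson_fdr_screen(ca, ab$samples)
  tested <- scr[scr$tested, ]
  expect_equal(tested$p_adj, bh_stepup(tested$p.value), tolerance = 1e-12)
  # gas fluxes missing at one elevation: reduced n reported
  expect_true(all(scr$n[scr$variable == "CO2_flux"] == 9))
  # an all-missing variable is flagged untested
  sheet2 <- ab$samples; sheet2$dead <- NA_real_
  scr2 <- pearson_fdr_screen(ca, sheet2, vars = c("T", "dead"))
  expect_true(all(!scr2$tested[scr2$variable == "dead"]))
  expect_true(all(scr2$tested[scr2$variable == "T"]))

  # a perfectly linear pair: r = 1 and a minimal raw p
  ca_lin <- tibble::tibble(group = "g", sample_id = ab$samples$sample_id,
                           rel_abundance = ab$samples$T)
  scr3 <- pearson_fdr_screen(ca_lin, ab$samples, vars = "T")
  expect_equal(scr3$estimate, 1, tolerance = 1e-12)
  expect_lt(scr3$p.value, 1e-12)
})

test_that("constrained ordination recovers a constructed gradient and flags rank problems", {
  set.seed(6)
  n <- 40; nsp <- 25
  grad <- rnorm(n)
  opt <- seq(-2, 2, length.out = nsp)
  Y <- sapply(opt, function(o) exp(-(grad - o)^2) * 30 + 0.05)
  sheet <- tibble::tibble(sample_id = paste0("s", 1:n),
                          elevation = rep(1:4, each = 10), replicate = rep(1:10, 4),
                          grad = grad, junk = rnorm(n))
  ab <- make_abund(norm = t(Y), detected = t(Y) > 0, sheet = sheet,
                   values = t(Y))
  colnames(ab$values) <- colnames(ab$norm) <- sheet$sample_id
  fit <- constrained_ordination(ab, c("grad", "junk"), n_perm = 99, seed = 1)
  eig <- fit$model$CCA$eig
  expect_gte(eig[1] / sum(eig), 0.99)
  expect_lt(fit$p.value, 0.05)

  sheet$dup <- sheet$grad
  ab$samples <- sheet
  expect_error(constrained_ordination(ab, c("grad", "dup"), n_perm = 0),
               class = "geochipr_error_rank")
  expect_error(constrained_ordination(ab, paste0("v", 1:45), n_perm = 0),
               class = "geochipr_error_rank")
})

test_that("variation partitioning satisfies inclusion-exclusion and group rules", {
  set.seed(8)
  n <- 40
  sheet <- tibble::tibble(sample_id = paste0("s", 1:n), elevation = 1,
                          replicate = 1, A1 = rnorm(n), B1 = rnorm(n),
                          C1 = rnorm(n))
  Y <- matrix(rexp(n * 20), n)
  ab <- make_abund(norm = t(Y), detected = t(Y) > 0, sheet = sheet, values = t(Y))
  colnames(ab$values) <- colnames(ab$norm) <- sheet$sample_id
  vp <- variation_partition(ab, list(A = "A1", B = "B1", C = "C1"))
  comp <- vp$components
  expect_equal(sum(comp$fraction[comp$component != "residual"]),
               vp$total_explained, tolerance = 1e-10)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-10)

  expect_error(variation_partition(ab, list(A = "A1", B = "B1")),
               class = "geochipr_error_config")
  expect_error(variation_partition(ab, list(A = "A1", B = "A1", C = "C1")),
               class = "geochipr_error_config")
})

test_that("whole-community environment linkage runs on synthetic data", {
  sim <- simulate_geochip(synthetic_design(n_probes = 800, rng_seed = 10))
  ab <- preprocess_geochip(sim$signals, sim$samples)
  mant <- mantel_env(ab, vars = c("elevation", "T", "CO2_flux"),
                     n_perm = 199, seed = 2)
  expect_identical(nrow(mant), 3L)
  expect_identical(mant$n[mant$variable == "CO2_flux"], 9L)
  expect_true(all(mant$p.value >= 1 / 200 & mant$p.value <= 1, na.rm = TRUE))
  perm <- permanova_elevation(ab, n_perm = 199, seed = 2)
  expect_true(perm$p.value <= 1 && perm$pseudo_F > 0)
})
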