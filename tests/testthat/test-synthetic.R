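test_that("design validation rejects impossible parameters", {
  expect_error(synthetic_design(n_replicates = 1), class = "geochipr_error_design")
  expect_error(synthetic_design(true_z = -0.01), class = "geochipr_error_design")
  expect_error(synthetic_design(occupancy_base = 1.2), class = "geochipr_error_design")
  expect_error(synthetic_design(elevations = 3200), class = "geochipr_error_design")
})

test_that("occupancy calibration is infeasible when occupancy exceeds its ceiling", {
  expect_error(generate_presence_truth(synthetic_design(occupancy_base = 0.9,
                                                        n_probes = 100)),
               class = "geochipr_error_infeasible")
})

test_that("expected similarity decays log-linearly with slope -2z", {
  for (z in c(0.005, 0.02)) {
    tr <- generate_presence_truth(synthetic_design(true_z = z, n_probes = 100))
    es <- unique(tr$expected_similarity[tr$expected_similarity$distance > 0,
                                        c("distance", "expected_sorensen")])
    fit <- lm(log10(expected_sorensen) ~ log10(distance), data = es)
    expect_equal(unname(coef(fit)[2]), -2 * z, tolerance = 1e-8)
  }
  # within-elevation pairs sit on the same line under the within anchor
  tr <- generate_presence_truth(synthetic_design(true_z = 0.01, n_probes = 100))
  expect_identical(tr$anchor, "within")
  es <- tr$expected_similarity
  line <- function(D) es$expected_sorensen[es$distance == 200][1] * (D / 200)^(-0.02)
  expect_equal(es$expected_sorensen[es$distance == 0][1], line(0.01),
               tolerance = 1e-10)
})

test_that("true_z = 0 gives equal expected similarity for every elevation pair", {
  tr <- generate_presence_truth(synthetic_design(true_z = 0, n_probes = 100))
  expect_identical(tr$anchor, "ref")
  between <- tr$expected_similarity$expected_sorensen[tr$expected_similarity$distance > 0]
  expect_lt(diff(range(between)), 1e-12)
})

test_that("a saturated pool makes every probe present at every elevation", {
  d <- synthetic_design(true_z = 0, occupancy_base = 1, n_probes = 200)
  tr <- generate_presence_truth(d)
  expect_true(all(tr$presence))
  expect_error(generate_presence_truth(synthetic_design(true_z = 0.01,
                                                        occupancy_base = 1,
                                                        n_probes = 50)),
               class = "geochipr_error_infeasible")
})

test_that("generation is deterministic under rng_seed, and varies across seeds", {
  d <- synthetic_design(n_probes = 200, rng_seed = 42)
  s1 <- simulate_geochip(d)
  s2 <- simulate_geochip(d)
  expect_identical(s1$signals, s2$signals)
  expect_identical(s1$truth$presence, s2$truth$presence)
  expect_identical(s1$samples, s2$samples)
  s3 <- simulate_geochip(synthetic_design(n_probes = 200, rng_seed = 43))
  expect_false(identical(s1$signals, s3$signals))
})

test_that("planted singleton detections are removed at the binomial rate", {
  # replicate detection made certain so every replicate-filter removal is a
  # planted singleton
  d <- synthetic_design(n_probes = 3000, singleton_rate = 0.2,
                        replicate_dropout = 0,
                        snr_shape = c(meanlog = log(50), sdlog = 0.3),
                        anchor = "ref", sorensen_ref = 0.7, rng_seed = 9)
  tr <- generate_presence_truth(d)
  tab <- generate_signal_table(d, tr)
  filt <- filter_replicate_singletons(filter_snr(tab), make_sheet(d$elevations, 3))
  prov <- attr(filt, "geochip_prov")
  removed <- prov[[length(prov)]]$removed_by_elevation
  nY <- colSums(tr$presence)
  for (j in seq_along(d$elevations)) {
    r <- removed$removed[removed$elevation == d$elevations[j]]
    expect_gt(r, qbinom(0.0005, nY[j], 0.2))
    expect_lt(r, qbinom(0.9995, nY[j], 0.2))
  }
  # and with no planting, the replicate filter removes nothing
  d0 <- synthetic_design(n_probes = 500, singleton_rate = 0, replicate_dropout = 0,
                         snr_shape = c(meanlog = log(50), sdlog = 0.3),
                         anchor = "ref", sorensen_ref = 0.7, rng_seed = 9)
  t0 <- generate_presence_truth(d0)
  f0 <- filter_replicate_singletons(filter_snr(generate_signal_table(d0, t0)),
                                    make_sheet(d0$elevations, 3))
  prov0 <- attr(f0, "geochip_prov")
  expect_identical(prov0[[length(prov0)]]$removed, 0L)
})

test_that("sample sheet follows the configured gradient trends", {
  d <- synthetic_design(n_probes = 10)
  sheet <- generate_sample_sheet(d, env_noise = 0)
  expect_identical(nrow(sheet), 12L)
  means <- aggregate(cbind(T, pH, moisture, NO3, TN_10_20) ~ elevation,
                     sheet, mean)
  expect_true(all(diff(means$T) < 0))
  expect_true(all(diff(means$pH) < 0))
  expect_true(all(diff(means$moisture) > 0))
  expect_true(all(diff(means$NO3) > 0))
  expect_true(all(diff(means$TN_10_20) > 0))
  # noise = 0: replicates sit exactly on the per-elevation trend lines
  expect_true(all(tapply(sheet$T, sheet$elevation, function(v) diff(range(v))) == 0))
  # temperature correlates negatively with elevation by construction
  noisy <- generate_sample_sheet(d, env_noise = 1)
  expect_lt(cor(noisy$T, noisy$elevation), 0)
  # gas fluxes missing at the third elevation only
  gap <- d$elevations[3]
  expect_true(all(is.na(noisy$CO2_flux[noisy$elevation == gap])))
  expect_true(all(!is.na(noisy$CO2_flux[noisy$elevation != gap])))
})

test_that("synthetic richness gradient produces an increasing diversity trend", {
  pos <- vapply(1:10, function(s) {
    d <- synthetic_design(n_probes = 1200, richness_slope = 0.1, rng_seed = s)
    ab <- preprocess_geochip(simulate_geochip(d)$signals,
                             generate_sample_sheet(d))
    trend_vs_elevation(diversity_profile(ab), "shannon",
                       method = "spearman")$estimate > 0
  }, logical(1))
  expect_gte(sum(pos), 9)
})

test_that("truth files round-trip through write_simulation", {
  dir <- withr::local_tempdir()
  sim <- simulate_geochip(synthetic_design(n_probes = 60, rng_seed = 3))
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_probe_table(paths[["signals"]])
  expect_equal(nrow(back), nrow(sim$signals))
  expect_equal(sort(unique(back$sample_id)), sort(unique(sim$signals$sample_id)))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$true_z, sim$design$true_z)
})
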