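test_that("SNR filter removes exactly the sub-threshold spots (strict <)", {
  sheet <- make_sheet(c(100, 200), 2)
  sig <- matrix(10, 10, 4, dimnames = list(sprintf("p%02d", 1:10), sheet$sample_id))
  snr <- matrix(5, 10, 4, dimnames = dimnames(sig))
  tab <- make_probe_table(sig, snr)

  out <- filter_snr(tab)
  expect_true(all(out$detected))

  snr2 <- snr; snr2[3, 2] <- 1.99; snr2[4, 2] <- 2.0
  out2 <- filter_snr(make_probe_table(sig, snr2))
  expect_identical(sum(!out2$detected), 1L)
  expect_false(out2$detected[out2$probe_id == "p03" & out2$sample_id == sheet$sample_id[2]])
  expect_true(out2$detected[out2$probe_id == "p04" & out2$sample_id == sheet$sample_id[2]])

  # toy of 10 spots with snr 1,1,2,2,3,3,4,4,5,5 -> 2 removed
  tab3 <- make_probe_table(matrix(10, 10, 1, dimnames = list(NULL, "s1")),
                           matrix(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5), 10, 1))
  expect_identical(sum(!filter_snr(tab3)$detected), 2L)

  expect_error(filter_snr(dplyr::select(tab, -snr)), class = "geochipr_error_format")
})

test_that("replicate filter removes singletons per elevation group only", {
  sheet <- make_sheet(c(100, 200), 3)
  sig <- matrix(10, 2, 6, dimnames = list(c("pA", "pB"), sheet$sample_id))
  snr <- matrix(5, 2, 6, dimnames = dimnames(sig))
  # pA: detected 1/3 at 100 m, 2/3 at 200 m; pB: 3/3 everywhere
  snr[1, c(2, 3)] <- 1      # pA missing in reps 2,3 at 100 m
  snr[1, 6] <- 1            # pA missing in rep 3 at 200 m
  out <- filter_replicate_singletons(filter_snr(make_probe_table(sig, snr)), sheet)
  det <- out$detected[out$probe_id == "pA"]
  names(det) <- out$sample_id[out$probe_id == "pA"]
  expect_false(det[[sheet$sample_id[1]]])              # singleton removed at 100 m
  expect_true(det[[sheet$sample_id[4]]])               # 2/3 kept at 200 m
  expect_true(det[[sheet$sample_id[5]]])
  expect_true(all(out$detected[out$probe_id == "pB"]))

  # a group with < 2 replicates is a configuration error
  bad_sheet <- make_sheet(100, 1)
  tabb <- make_probe_table(matrix(1, 2, 1, dimnames = list(NULL, bad_sheet$sample_id)),
                           matrix(5, 2, 1))
  expect_error(filter_replicate_singletons(filter_snr(tabb), bad_sheet),
               class = "geochipr_error_config")
})

test_that("filters are idempotent on their own output", {
  set.seed(1)
  sheet <- make_sheet(c(100, 200), 3)
  sig <- matrix(rlnorm(120), 20, 6, dimnames = list(NULL, sheet$sample_id))
  snr <- matrix(runif(120, 0, 5), 20, 6, dimnames = dimnames(sig))
  f1 <- filter_snr(make_probe_table(sig, snr))
  expect_identical(filter_snr(f1)$detected, f1$detected)
  f2 <- filter_replicate_singletons(f1, sheet)
  expect_identical(filter_replicate_singletons(f2, sheet)$detected, f2$detected)
})

test_that("the pipeline order is enforced", {
  sheet <- make_sheet(c(100, 200), 2)
  sig <- matrix(1, 4, 4, dimnames = list(NULL, sheet$sample_id))
  tab <- make_probe_table(sig, matrix(5, 4, 4))
  expect_error(normalize_total_signal(tab), class = "geochipr_error_order")
  expect_error(log_transform(tab), class = "geochipr_error_order")
  expect_error(filter_replicate_singletons(tab, sheet), class = "geochipr_error_order")
  snr_done <- filter_snr(tab)
  expect_error(normalize_total_signal(snr_done), class = "geochipr_error_order")
})

test_that("total-signal normalization equalizes totals and scales correctly", {
  sheet <- make_sheet(100, 2)
  # totals 100 and 200 -> mean constant 150 -> scale 1.5 and 0.75
  sig <- matrix(c(40, 60, 120, 80), 2, 2, dimnames = list(NULL, sheet$sample_id))
  tab <- filter_replicate_singletons(filter_snr(make_probe_table(sig, sig * 0 + 5)),
                                     sheet)
  out <- normalize_total_signal(tab)
  s1 <- out$signal[out$sample_id == sheet$sample_id[1]]
  s2 <- out$signal[out$sample_id == sheet$sample_id[2]]
  expect_equal(s1, c(40, 60) * 1.5)
  expect_equal(s2, c(120, 80) * 0.75)
  expect_equal(sum(s1), sum(s2), tolerance = 1e-12)

  out_fixed <- normalize_total_signal(tab, constant_rule = "fixed", constant = 1000)
  expect_equal(sum(out_fixed$signal[out_fixed$sample_id == sheet$sample_id[1]]), 1000)

  # degenerate sample: all spots filtered out
  snr0 <- matrix(c(5, 5, 1, 1), 2, 2, dimnames = list(NULL, sheet$sample_id))
  tab0 <- filter_replicate_singletons(filter_snr(make_probe_table(sig, snr0)), sheet)
  expect_error(normalize_total_signal(tab0), class = "geochipr_error_degenerate")
})

test_that("Shannon diversity is invariant to the normalization step", {
  set.seed(4)
  sheet <- make_sheet(c(100, 200), 3)
  sig <- matrix(rlnorm(180, 5), 30, 6, dimnames = list(NULL, sheet$sample_id))
  snr <- matrix(runif(180, 1, 6), 30, 6, dimnames = dimnames(sig))
  tab <- filter_replicate_singletons(filter_snr(make_probe_table(sig, snr)), sheet)
  h_before <- vapply(sheet$sample_id, function(s) {
    shannon(tab$signal[tab$sample_id == s & tab$detected])
  }, numeric(1))
  out <- normalize_total_signal(tab)
  h_after <- vapply(sheet$sample_id, function(s) {
    shannon(out$signal[out$sample_id == s & out$detected])
  }, numeric(1))
  expect_equal(h_after, h_before, tolerance = 1e-12)
})

test_that("log transform applies the offset rule and keeps detection flags", {
  sheet <- make_sheet(100, 3)
  sig <- matrix(rep(c(2, 4, 8), 3), 3, 3, dimnames = list(NULL, sheet$sample_id))
  tab <- normalize_total_signal(
    filter_replicate_singletons(filter_snr(make_probe_table(sig, sig * 0 + 9)), sheet),
    constant_rule = "fixed", constant = 14)  # totals are 14 -> values unchanged
  ab_plain <- log_transform(tab, offset = "none")
  expect_equal(unname(ab_plain$values[, 1]), log(c(2, 4, 8)), tolerance = 1e-12)
  expect_equal(unname(ab_plain$values[2, 1]), log(4))
  ab1 <- log_transform(tab, offset = "plus1")
  expect_equal(unname(ab1$values[, 1]), log1p(c(2, 4, 8)), tolerance = 1e-12)
  expect_true(all(ab1$detected))

  # value of exactly 1 maps to 0 under plain ln but stays detected
  sig1 <- matrix(c(1, 13), 2, 1, dimnames = list(NULL, "E100_R1"))
  sheet1 <- make_sheet(100, 2)
  sig2 <- cbind(sig1, E100_R2 = c(1, 13)); colnames(sig2) <- sheet1$sample_id
  tab1 <- normalize_total_signal(
    filter_replicate_singletons(filter_snr(make_probe_table(sig2, sig2 * 0 + 9)), sheet1),
    constant_rule = "fixed", constant = 14)
  ab <- log_transform(tab1, offset = "none")
  expect_equal(unname(ab$values[1, 1]), 0)
  expect_true(ab$detected[1, 1])
})

test_that("detection matrix equals the brute-force oracle on random toy tables", {
  set.seed(99)
  for (i in 1:100) {
    n_probes <- sample(3:15, 1)
    elevs <- seq(100, by = 100, length.out = sample(2:3, 1))
    reps <- sample(2:4, 1)
    sheet <- make_sheet(elevs, reps)
    ns <- nrow(sheet)
    sig <- matrix(rlnorm(n_probes * ns, 3), n_probes, ns,
                  dimnames = list(NULL, sheet$sample_id))
    snr <- matrix(runif(n_probes * ns, 0, 4), n_probes, ns, dimnames = dimnames(sig))
    tab <- make_probe_table(sig, snr)
    ab <- tryCatch(preprocess_geochip(tab, sheet),
                   geochipr_error_degenerate = function(e) NULL)
    oracle <- detect_bruteforce(tab, sheet)
    if (is.null(ab)) {
      expect_true(any(colSums(oracle) == 0))
    } else {
      expect_identical(ab$detected[rownames(oracle), colnames(oracle)], oracle)
    }
  }
})

test_that("preprocessing provenance logs removal counts and the constant", {
  sim <- simulate_geochip(synthetic_design(n_probes = 300, rng_seed = 2))
  ab <- preprocess_geochip(sim$signals, sim$samples)
  steps <- vapply(ab$provenance, function(p) p$step, character(1))
  expect_identical(steps, c("filter_snr", "filter_replicate_singletons",
                            "normalize_total_signal", "log_transform"))
  expect_gt(ab$provenance[[1]]$removed, 0)
  expect_identical(ab$provenance[[3]]$constant, ab$norm_constant)
  # per-sample pre-log normalized totals are equal
  totals <- colSums(ab$norm)
  expect_lt(diff(range(totals)) / mean(totals), 1e-9)
})
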