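#' Draw the true probe occupancy pattern for a synthetic design
#'
#' Samples, for every probe, which elevations it truly occupies, using the
#' calibrated niche-mixture occupancy model: each probe is either present
#' everywhere (regional generalist) or carries a triangular elevation niche of
#' random width, followed by elevation-level thinning.  The calibration
#' guarantees that the *expected* post-preprocessing Sorensen similarity of
#' sample pairs follows `log(S) = const - 2 z log(D)` exactly at the design's
#' pairwise elevation distances.
#'
#' @param design A [synthetic_design()].
#' @return A `synthetic_truth` object: realized presence matrix
#'   (probes x elevations), probe annotation, expected pairwise similarities,
#'   expected per-sample richness, the true decay exponent and the calibration
#'   details.
#' @export
generate_presence_truth <- function(design) {
  validate_design(design)
  cal <- calibrate_occupancy(design)
  elev <- design$elevations
  n <- design$n_probes
  nE <- length(elev)

  set.seed(design$rng_seed)
  annot <- sample_probe_annotation(design)

  K <- length(cal$widths)
  cls <- sample.int(K + 1, n, replace = TRUE, prob = c(cal$pi_fin, cal$pi_inf))
  cover <- matrix(TRUE, n, nE)
  fin <- which(cls <= K)
  if (length(fin)) {
    w <- cal$widths[cls[fin]]
    centre <- runif(length(fin), min(elev) - w, max(elev) + w)
    for (j in seq_len(nE)) {
      cover[fin, j] <- abs(elev[j] - centre) <= w
    }
  }
  pool <- runif(n) < cal$g
  thin <- matrix(runif(n * nE) < cal$ell, n, nE)
  presence <- cover & pool & thin
  dimnames(presence) <- list(annot$probe_id, as.character(elev))

  pairs <- t(utils::combn(seq_len(nE), 2))
  exp_sim <- tibble(
    elev_a = elev[pairs[, 1]], elev_b = elev[pairs[, 2]],
    distance = abs(elev_b - elev_a)
  ) %>%
    mutate(expected_sorensen = cal$ell * cal$G(.data$distance) *
             (1 - design$singleton_rate) *
             2 * cal$rho_e[pairs[, 1]] * cal$rho_e[pairs[, 2]] /
             (cal$rho_e[pairs[, 1]] + cal$rho_e[pairs[, 2]]))
  within <- tibble(elev_a = elev, elev_b = elev, distance = 0,
                   expected_sorensen = cal$s_within)
  exp_sim <- bind_rows(within, exp_sim) %>% arrange(.data$distance)

  richness <- tibble(
    elevation = elev,
    expected_richness = n * design$occupancy_base *
      (1 - design$singleton_rate) * cal$rho_e
  )

  structure(list(
    design = design,
    annotation = annot,
    presence = presence,
    expected_similarity = exp_sim,
    expected_richness = richness,
    true_z = design$true_z,
    anchor = cal$anchor,
    calibration = cal
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat("  probes x elevations:", nrow(x$presence), "x", ncol(x$presence), "\n")
  cat("  true z             :", format(x$true_z), "(anchor:", x$anchor, ")\n")
  cat("  expected richness  :",
      paste(round(x$expected_richness$expected_richness), collapse = ", "), "\n")
  invisible(x)
}

sample_probe_annotation <- function(design) {
  pool <- gene_pool()
  cats <- design$categories
  pool <- pool[pool$category %in% cats$category, , drop = FALSE]
  n <- design$n_probes
  cat_draw <- sample(cats$category, n, replace = TRUE, prob = cats$share)
  genera <- c("Nitrosospira", "Shewanella", "Bradyrhizobium", "Methanosarcina",
              "Pseudomonas", "Geobacter", "Synechococcus", "Mycobacterium",
              "Comamonas", "Roseobacter", "uncultured bacterium")
  idx <- integer(n)
  for (cc in unique(cat_draw)) {
    sub <- which(pool$category == cc)
    sel <- cat_draw == cc
    idx[sel] <- sub[sample.int(length(sub), sum(sel), replace = TRUE)]
  }
  tibble(
    probe_id = sprintf("probe_%05d", seq_len(n)),
    gene = pool$gene[idx],
    category = pool$category[idx],
    subcategory = pool$subcategory[idx],
    organism = sample(genera, n, replace = TRUE)
  )
}

#' Generate a raw probe signal table from a sampled occupancy truth
#'
#' Produces the tab-delimited-style probe table the preprocessing chain
#' consumes: per replicate, truly present spots are detected with probability
#' `(1 - replicate_dropout) * P(SNR >= threshold)`, detected spots carry
#' log-normal intensities and log-normal SNR, and a `singleton_rate` fraction
#' of probe-by-elevation detections is planted in exactly one replicate so the
#' replicate filter has real work to do.  Absent or missed spots carry
#' sub-threshold SNR and faint background signal.
#'
#' @param design A [synthetic_design()].
#' @param truth The matching [generate_presence_truth()] result.
#' @return A long tibble (one row per probe x sample) with columns
#'   `probe_id`, `gene`, `category`, `subcategory`, `organism`, `sample_id`,
#'   `signal`, `snr`.
#' @export
generate_signal_table <- function(design, truth) {
  validate_design(design)
  if (!inherits(truth, "synthetic_truth") || !identical(truth$design, design)) {
    abort("truth was not generated from this design", class = "geochipr_error_design")
  }
  cal <- truth$calibration
  elev <- design$elevations
  nE <- length(elev)
  R <- design$n_replicates
  n <- design$n_probes
  snr_pass <- 1 - plnorm(design$snr_threshold,
                         design$snr_shape[["meanlog"]], design$snr_shape[["sdlog"]])
  dropout_e <- pmax(0, 1 - cal$d_e / snr_pass)

  set.seed(design$rng_seed + 1L)
  Y <- truth$presence

  planted <- Y & matrix(runif(n * nE) < design$singleton_rate, n, nE)
  planted_rep <- matrix(sample.int(R, n * nE, replace = TRUE), n, nE)

  # latent co-abundance modules: probes in a module share a per-sample
  # log-intensity factor, partly tracking the elevation gradient
  module <- sample.int(design$n_modules, n, replace = TRUE)
  elev_score <- rep(scale(elev)[, 1], each = R)
  w_mod <- runif(design$n_modules, 0, 0.8)
  Fmat <- w_mod %o% elev_score +
    sqrt(1 - w_mod^2) * matrix(rnorm(design$n_modules * nE * R),
                               design$n_modules, nE * R)

  snr <- matrix(0, n, nE * R)
  signal <- matrix(0, n, nE * R)
  sample_id <- character(nE * R)
  ml <- design$snr_shape[["meanlog"]]; sl <- design$snr_shape[["sdlog"]]
  thr <- design$snr_threshold

  for (j in seq_len(nE)) {
    for (r in seq_len(R)) {
      col <- (j - 1) * R + r
      sample_id[col] <- sprintf("E%d_R%d", as.integer(elev[j]), r)
      attempt <- Y[, j] & !planted[, j] & (runif(n) < 1 - dropout_e[j])
      plant_here <- planted[, j] & planted_rep[, j] == r
      spot <- attempt | plant_here
      s <- numeric(n); v <- numeric(n)
      # real spots: full intensity (module factor + residual), SNR from the
      # spot distribution
      mu_spot <- design$signal_mu + design$module_sd * Fmat[module[spot], col]
      s[spot] <- rlnorm(sum(spot), mu_spot, design$signal_sigma)
      v[attempt] <- rlnorm(sum(attempt), ml, sl)
      # planted singletons must survive the SNR filter: truncated draw
      if (any(plant_here)) {
        u <- runif(sum(plant_here), plnorm(thr, ml, sl), 1)
        v[plant_here] <- qlnorm(u, ml, sl)
      }
      # background: faint signal, sub-threshold SNR
      bg <- !spot
      s[bg] <- rlnorm(sum(bg), design$signal_mu - 3, 0.5)
      v[bg] <- runif(sum(bg), 0, 0.95 * thr)
      snr[, col] <- v
      signal[, col] <- s
    }
  }

  annot <- truth$annotation
  out <- tibble(
    probe_id = rep(annot$probe_id, times = nE * R),
    gene = rep(annot$gene, times = nE * R),
    category = rep(annot$category, times = nE * R),
    subcategory = rep(annot$subcategory, times = nE * R),
    organism = rep(annot$organism, times = nE * R),
    sample_id = rep(sample_id, each = n),
    signal = as.vector(signal),
    snr = as.vector(snr)
  )
  attr(out, "geochip_stage") <- "raw"
  out
}

#' Generate a synthetic sample sheet with gradient-shaped covariates
#'
#' Builds the per-sample metadata sheet: elevation, replicate index and a set
#' of environmental covariates whose per-elevation means follow smooth trends
#' along the gradient (temperature and pH strictly decreasing; moisture,
#' nitrate and deep total nitrogen increasing; several hump-shaped variables),
#' with replicate-level Gaussian noise.  Greenhouse-gas fluxes are optionally
#' missing at the third elevation, emulating a site where flux chambers could
#' not be deployed.
#'
#' @param design A [synthetic_design()].
#' @param env_noise Multiplier on the per-variable replicate noise standard
#'   deviations; `0` puts every replicate exactly on the trend line.
#' @return A tibble with one row per sample.
#' @export
generate_sample_sheet <- function(design, env_noise = 1) {
  validate_design(design)
  elev <- design$elevations
  R <- design$n_replicates
  x_of <- function(e) (e - min(elev)) / max(max(elev) - min(elev), 1)

  set.seed(design$rng_seed + 2L)
  grid <- tidyr::expand_grid(elevation = elev, replicate = seq_len(R))
  x <- x_of(grid$elevation)

  trends <- list(
    T           = list(mean = 12.4 - 5.6 * x,               sd = 0.30),
    pH          = list(mean = 7.9 - 0.8 * x,                sd = 0.12),
    moisture    = list(mean = 26 + 20 * x,                  sd = 2.50),
    NO3         = list(mean = 0.9 + 0.65 * x,               sd = 0.20),
    NH4         = list(mean = 2.5 + 1.6 * x - 2.8 * x^2,    sd = 0.20),
    TOC_0_10    = list(mean = 6.2 + 3.2 * x - 4.0 * x^2,    sd = 0.08),
    TOC_10_20   = list(mean = 2.3 + 9.0 * x - 6.5 * x^2,    sd = 0.08),
    TN_0_10     = list(mean = 4.6 + 3.4 * x - 3.4 * x^2,    sd = 0.05),
    TN_10_20    = list(mean = 3.0 + 1.25 * x,               sd = 0.05),
    TP_0_10     = list(mean = 0.55 + 1.0 * x - 1.05 * x^2,  sd = 0.02),
    TP_10_20    = list(mean = 0.40 + 0.4 * x - 0.35 * x^2,  sd = 0.02),
    veg_biomass = list(mean = 450 - 230 * x,                sd = 18),
    veg_diversity = list(mean = 1.9 + 2.2 * x - 2.1 * x^2,  sd = 0.07),
    veg_species = list(mean = 22 + 12 * x - 14 * x^2,       sd = 1.0),
    CH4_flux    = list(mean = -30 + 15 * x,                 sd = 10),
    CO2_flux    = list(mean = 880 - 600 * x,                sd = 70),
    N2O_flux    = list(mean = 15 - 11 * x,                  sd = 5)
  )

  vals <- purrr::imap(trends, function(tr, nm) {
    tr$mean + rnorm(nrow(grid), 0, tr$sd * env_noise)
  })
  sheet <- dplyr::bind_cols(
    tibble(
      sample_id = sprintf("E%d_R%d", as.integer(grid$elevation), grid$replicate),
      elevation = grid$elevation,
      replicate = grid$replicate
    ),
    as_tibble(vals)
  ) %>%
    mutate(SIN = .data$NO3 + .data$NH4, .after = "TP_10_20")

  if (design$gas_gap && length(elev) >= 3) {
    gap <- elev[3]
    gas <- c("CH4_flux", "CO2_flux", "N2O_flux")
    sheet[sheet$elevation == gap, gas] <- NA_real_
  }
  sheet
}

#' Simulate a complete synthetic GeoChip study
#'
#' Convenience wrapper: occupancy truth, raw signal table and sample sheet
#' from one design, all deterministic under the design's `rng_seed`.
#'
#' @param design A [synthetic_design()].
#' @param env_noise Passed to [generate_sample_sheet()].
#' @return A list with class `geochip_sim`: `design`, `truth`, `signals`,
#'   `samples`.
#' @export
simulate_geochip <- function(design = synthetic_design(), env_noise = 1) {
  truth <- generate_presence_truth(design)
  signals <- generate_signal_table(design, truth)
  samples <- generate_sample_sheet(design, env_noise = env_noise)
  structure(list(design = design, truth = truth,
                 signals = signals, samples = samples),
            class = "geochip_sim")
}

#' @export
print.geochip_sim <- function(x, ...) {
  cat("<geochip_sim>:", x$design$n_probes, "probes,",
      nrow(x$samples), "samples, true z =", format(x$design$true_z), "\n")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the probe table as tab-delimited text (paired per-sample
#' signal/SNR columns), the sample sheet as CSV and the generator truth
#' (expected similarities, richness, decay exponent) as JSON.
#'
#' @param sim A [simulate_geochip()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "geochip_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    signals = file.path(dir, "probe_table.tsv"),
    samples = file.path(dir, "sample_sheet.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_probe_table(sim$signals, paths[["signals"]])
  readr::write_csv(sim$samples, paths[["samples"]])
  truth <- sim$truth
  jsonlite::write_json(list(
    true_z = truth$true_z,
    anchor = truth$anchor,
    expected_similarity = truth$expected_similarity,
    expected_richness = truth$expected_richness
  ), paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
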