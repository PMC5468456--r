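#' Describe a synthetic GeoChip study design
#'
#' Builds the parameter set for the synthetic-data generator.  The defaults
#' emulate a four-elevation alpine pasture transect (3200--3800 m asl) with
#' biological triplicates hybridised on a functional gene array: probes carry
#' elevation niches so that expected between-sample Sorensen similarity decays
#' as a power law of elevation difference with exponent `2 * true_z`, signal
#' intensities are log-normal, and each spot carries a signal-to-noise ratio
#' (SNR) so the preprocessing filters have something to do.
#'
#' @param elevations Numeric vector of site elevations (m asl).
#' @param n_replicates Biological replicates per elevation (>= 2).
#' @param n_probes Number of array probes.
#' @param true_z True decay exponent of the elevation-decay relationship
#'   (dimensionless, >= 0).
#' @param occupancy_base Probability that a probe is present at a given
#'   elevation (marginal occupancy).
#' @param richness_slope Change in expected per-sample detected richness per
#'   metre of elevation.  `0` keeps all elevations exchangeable.
#' @param signal_mu,signal_sigma Meanlog and residual sdlog of log-normal
#'   spot intensities for detected spots (arbitrary fluorescence units).
#' @param n_modules Number of latent co-abundance modules; probes in one
#'   module share a per-sample intensity factor, part of which follows the
#'   elevation gradient.  This is what gives co-occurrence networks and
#'   abundance-environment correlations real structure to find.
#' @param module_sd Log-scale standard deviation of the module factor
#'   (`0` switches module structure off).
#' @param snr_shape Named numeric vector `c(meanlog =, sdlog =)` of the
#'   log-normal SNR distribution for real spots.
#' @param replicate_dropout Probability that a truly present spot fails to
#'   show in a given replicate (independent per replicate).
#' @param singleton_rate Probability that a probe-by-elevation detection is
#'   planted in exactly one replicate (and is therefore removed by the
#'   replicate filter).
#' @param categories Tibble with columns `category`, `share` giving functional
#'   category proportions; `NULL` for the built-in default.
#' @param anchor How the expected-similarity decay line is anchored:
#'   `"auto"` anchors at the within-elevation replicate similarity when that
#'   is feasible and falls back to `sorensen_ref`; `"within"` and `"ref"`
#'   force one behaviour.
#' @param sorensen_ref Expected Sorensen similarity at the smallest nonzero
#'   elevation difference, used by the `"ref"` anchor.
#' @param d_zero Substituted distance for within-elevation pairs (m); the
#'   same value the decay fit uses for zero elevation differences.
#' @param snr_threshold SNR detection threshold the calibration assumes
#'   (matches the preprocessing default).
#' @param gas_gap If `TRUE`, greenhouse-gas fluxes are missing at the third
#'   elevation of the sample sheet (emulating an unmeasurable site).
#' @param rng_seed Integer seed; all generation is deterministic given it.
#'
#' @return A `synthetic_design` object (a validated list).
#' @seealso [generate_presence_truth()], [generate_signal_table()],
#'   [generate_sample_sheet()], [simulate_geochip()]
#' @export
synthetic_design <- function(elevations = c(3200, 3400, 3600, 3800),
                             n_replicates = 3,
                             n_probes = 5000,
                             true_z = 0.01,
                             occupancy_base = 0.35,
                             richness_slope = 0,
                             signal_mu = log(2000),
                             signal_sigma = 0.6,
                             n_modules = 25,
                             module_sd = 1.2,
                             snr_shape = c(meanlog = log(8), sdlog = 0.6),
                             replicate_dropout = 0.09,
                             singleton_rate = 0.05,
                             categories = NULL,
                             anchor = c("auto", "within", "ref"),
                             sorensen_ref = 0.7,
                             d_zero = 0.01,
                             snr_threshold = 2,
                             gas_gap = TRUE,
                             rng_seed = 1L) {
  anchor <- arg_match(anchor)
  if (is.null(categories)) categories <- default_categories()

  design <- structure(list(
    elevations = sort(as.numeric(elevations)),
    n_replicates = as.integer(n_replicates),
    n_probes = as.integer(n_probes),
    true_z = true_z,
    occupancy_base = occupancy_base,
    richness_slope = richness_slope,
    signal_mu = signal_mu,
    signal_sigma = signal_sigma,
    n_modules = as.integer(n_modules),
    module_sd = module_sd,
    snr_shape = snr_shape,
    replicate_dropout = replicate_dropout,
    singleton_rate = singleton_rate,
    categories = categories,
    anchor = anchor,
    sorensen_ref = sorensen_ref,
    d_zero = d_zero,
    snr_threshold = snr_threshold,
    gas_gap = gas_gap,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_design")
  validate_design(design)
  design
}

validate_design <- function(design) {
  with(design, {
    if (length(elevations) < 2) {
      abort("need at least 2 elevations", class = "geochipr_error_design")
    }
    if (anyDuplicated(elevations)) {
      abort("elevations must be distinct", class = "geochipr_error_design")
    }
    if (n_replicates < 2) {
      abort("need at least 2 replicates per elevation (the replicate filter is undefined otherwise)",
            class = "geochipr_error_design")
    }
    if (true_z < 0) abort("true_z must be >= 0", class = "geochipr_error_design")
    probs <- c(occupancy_base, replicate_dropout, singleton_rate, sorensen_ref)
    if (any(probs < 0 | probs > 1)) {
      abort("occupancy_base, replicate_dropout, singleton_rate and sorensen_ref must lie in [0, 1]",
            class = "geochipr_error_design")
    }
    if (n_probes < 1) abort("n_probes must be positive", class = "geochipr_error_design")
    if (n_modules < 1 || module_sd < 0) {
      abort("n_modules must be >= 1 and module_sd >= 0", class = "geochipr_error_design")
    }
    if (d_zero <= 0) abort("d_zero must be positive", class = "geochipr_error_design")
    if (!all(c("meanlog", "sdlog") %in% names(snr_shape))) {
      abort("snr_shape needs meanlog and sdlog entries", class = "geochipr_error_design")
    }
    if (abs(sum(categories$share) - 1) > 1e-6) {
      abort("category shares must sum to 1", class = "geochipr_error_design")
    }
  })
  invisible(design)
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("<synthetic_design>\n")
  cat("  elevations   :", paste(x$elevations, collapse = ", "), "m asl\n")
  cat("  replicates   :", x$n_replicates, "per elevation\n")
  cat("  probes       :", x$n_probes, "in", nrow(x$categories), "categories\n")
  cat("  true z       :", format(x$true_z), "\n")
  cat("  occupancy    :", format(x$occupancy_base), "\n")
  cat("  seed         :", x$rng_seed, "\n")
  invisible(x)
}

# Built-in functional category table: shares loosely shaped like a
# biogeochemical-cycling gene array, with per-gene process labels so the
# per-category decay fits have subcategories (anammox, nitrogen fixation, ...)
# to work with.
default_categories <- function() {
  tibble::tribble(
    ~category,            ~share,
    "carbon_degradation", 0.22,
    "carbon_fixation",    0.10,
    "methane",            0.06,
    "nitrogen",           0.22,
    "phosphorus",         0.05,
    "sulfur",             0.07,
    "stress",             0.14,
    "metal_resistance",   0.10,
    "other",              0.04
  )
}

gene_pool <- function() {
  tibble::tribble(
    ~category,            ~gene,      ~subcategory,
    "carbon_degradation", "amyA",     "starch_degradation",
    "carbon_degradation", "xylA",     "hemicellulose_degradation",
    "carbon_degradation", "cellobiase", "cellulose_degradation",
    "carbon_degradation", "chitinase",  "chitin_degradation",
    "carbon_degradation", "pulA",     "pullulan_degradation",
    "carbon_degradation", "lip",      "lignin_degradation",
    "carbon_fixation",    "rubisco",  "calvin_cycle",
    "carbon_fixation",    "aclB",     "reductive_tca",
    "carbon_fixation",    "CODH",     "acetyl_coa_pathway",
    "carbon_fixation",    "pcc",      "hydroxypropionate_pathway",
    "methane",            "mcrA",     "methane_production",
    "methane",            "pmoA",     "methane_oxidation",
    "methane",            "mmoX",     "methane_oxidation",
    "nitrogen",           "amoA",     "ammonia_oxidation",
    "nitrogen",           "hzo",      "anammox",
    "nitrogen",           "nifH",     "nitrogen_fixation",
    "nitrogen",           "nirK",     "denitrification",
    "nitrogen",           "nirS",     "denitrification",
    "nitrogen",           "nosZ",     "denitrification",
    "nitrogen",           "norB",     "denitrification",
    "nitrogen",           "napA",     "dissimilatory_n_reduction",
    "nitrogen",           "gdh",      "ammonification",
    "nitrogen",           "ureC",     "ammonification",
    "phosphorus",         "ppx",      "polyphosphate_degradation",
    "phosphorus",         "ppk",      "polyphosphate_synthesis",
    "phosphorus",         "phoD",     "phosphorus_mineralization",
    "sulfur",             "dsrA",     "sulfite_reduction",
    "sulfur",             "aprA",     "sulfate_reduction",
    "sulfur",             "sox",      "sulfur_oxidation",
    "stress",             "cspA",     "cold_shock",
    "stress",             "cspB",     "cold_shock",
    "stress",             "arcA",     "oxygen_limitation",
    "stress",             "arcB",     "oxygen_limitation",
    "stress",             "katN",     "oxidative_stress",
    "metal_resistance",   "mer",      "mercury_resistance",
    "metal_resistance",   "merG",     "mercury_resistance",
    "metal_resistance",   "copA",     "copper_resistance",
    "metal_resistance",   "czcA",     "cadmium_zinc_cobalt",
    "other",              "gyrB",     "housekeeping"
  )
}

# ---- occupancy calibration ---------------------------------------------------

# Retention probability of a truly present spot in one replicate after the
# "detected in >= 2 of R replicates" filter, given per-replicate detection
# probability d.
retained_prob <- function(d, R) d * (1 - (1 - d)^(R - 1))

# Expected within-elevation (replicate-pair) Sorensen similarity after
# preprocessing: the filter rescues mutually detected pairs, so this exceeds
# any between-elevation similarity.
within_similarity <- function(d, R) d / (1 - (1 - d)^(R - 1))

# Per-replicate detection probability implied by dropout and the SNR filter.
base_detect_prob <- function(design) {
  snr_pass <- 1 - plnorm(design$snr_threshold,
                         design$snr_shape[["meanlog"]], design$snr_shape[["sdlog"]])
  (1 - design$replicate_dropout) * snr_pass
}

# Decompose a convex, decreasing similarity profile G with G(0) = 1 into a
# mixture of triangular niche kernels ("hinge" basis (1 - D/c)+ plus an
# everywhere-present atom).  Exact: mixture weights are the slope changes of
# the piecewise-linear interpolant.
hinge_decompose <- function(D, G) {
  J <- length(D)
  s <- diff(c(1, G)) / diff(c(0, D))      # segment slopes
  if (any(diff(s) < -1e-9)) {
    abort("infeasible occupancy calibration: target similarity profile is not convex-compatible",
          class = "geochipr_error_infeasible")
  }
  if (any(s > 1e-12)) {
    abort("infeasible occupancy calibration: target similarities must be non-increasing in distance",
          class = "geochipr_error_infeasible")
  }
  knots <- numeric(0); beta <- numeric(0)
  for (j in seq_len(J - 1)) {
    b <- D[j] * (s[j + 1] - s[j])
    if (b > 1e-12) { knots <- c(knots, D[j]); beta <- c(beta, b) }
  }
  s_tail <- s[J]
  if (abs(s_tail) < 1e-13) {
    beta_inf <- G[J]
  } else {
    c_last <- D[J] + G[J] / (-s_tail)
    knots <- c(knots, c_last); beta <- c(beta, c_last * (-s_tail))
    beta_inf <- 0
  }
  total <- sum(beta) + beta_inf
  if (abs(total - 1) > 1e-8) {
    abort("internal error: hinge decomposition does not reproduce G(0) = 1",
          class = "geochipr_error_internal")
  }
  list(knots = knots, beta = beta, beta_inf = beta_inf,
       G = function(x) {
         vapply(x, function(xx) {
           sum(beta * pmax(0, 1 - xx / knots)) + beta_inf
         }, numeric(1))
       })
}

# Per-elevation detection probabilities implementing the richness gradient:
# solve the retained-replicate probability for each elevation's target
# expected richness.
richness_adjusted_detect <- function(design, d, rho, one_minus_sr) {
  elev <- design$elevations
  R <- design$n_replicates
  if (design$richness_slope == 0) return(rep(d, length(elev)))
  targets <- rho + design$richness_slope * (elev - mean(elev)) /
    (design$n_probes * design$occupancy_base * one_minus_sr)
  if (any(targets <= 0 | targets > 1)) {
    abort("infeasible richness_slope for this design",
          class = "geochipr_error_infeasible")
  }
  vapply(targets, function(tt) {
    uniroot(function(x) retained_prob(x, R) - tt, c(1e-6, 1), tol = 1e-12)$root
  }, numeric(1))
}

# Full occupancy calibration: chooses the niche-width mixture, the
# elevation-level thinning and the regional-pool probability so that the
# expected post-preprocessing Sorensen similarities hit the target power-law
# decay line exactly.
calibrate_occupancy <- function(design) {
  elev <- design$elevations
  R <- design$n_replicates
  d <- base_detect_prob(design)
  rho <- retained_prob(d, R)
  s_w <- within_similarity(d, R)
  one_minus_sr <- 1 - design$singleton_rate

  Dist <- sort(unique(as.numeric(dist(elev))))
  Dist <- Dist[Dist > 0]
  z <- design$true_z

  # saturated regional pool: every probe present at every elevation; only
  # meaningful without decay
  if (design$occupancy_base >= 0.9995) {
    if (z > 0) {
      abort("infeasible parameter combination: a saturated pool (occupancy_base = 1) admits no similarity decay; set true_z = 0",
            class = "geochipr_error_infeasible")
    }
    G_flat <- function(x) rep(1, length(x))
    d_e <- richness_adjusted_detect(design, d, rho, one_minus_sr)
    return(list(anchor = "saturated", d = d, d_e = d_e, rho = rho,
                rho_e = retained_prob(d_e, R),
                s_within = within_similarity(d_e, R),
                s_line = function(D) one_minus_sr * rho * G_flat(D),
                ell = 1, g = 1, q = 1, L_k = numeric(0),
                widths = numeric(0), pi_fin = numeric(0), pi_inf = 1,
                G = G_flat, Dist = Dist, sigma = rep(1, length(Dist))))
  }

  line_from <- function(S_anchor, D_anchor) {
    function(D) S_anchor * (D / D_anchor)^(-2 * z)
  }
  anchor <- design$anchor
  s_line <- line_from(s_w, design$d_zero)
  sigma_max <- 0.995
  sigma <- s_line(Dist) / (one_minus_sr * rho)
  if (anchor %in% c("auto", "within") && max(sigma) > sigma_max) {
    if (anchor == "within") {
      abort(sprintf(paste0(
        "infeasible parameter combination: anchoring the decay line at the ",
        "within-elevation similarity requires expected elevation-level ",
        "similarity %.3f > %.3f; increase true_z or decrease ",
        "replicate_dropout/singleton_rate"), max(sigma), sigma_max),
        class = "geochipr_error_infeasible")
    }
    anchor <- "ref"
  } else if (anchor == "auto") {
    anchor <- "within"
  }
  if (anchor == "ref") {
    s_line <- line_from(design$sorensen_ref, min(Dist))
    sigma <- s_line(Dist) / (one_minus_sr * rho)
    if (max(sigma) > sigma_max) {
      abort(sprintf(paste0(
        "infeasible parameter combination: required elevation-level similarity ",
        "%.3f exceeds %.3f; lower sorensen_ref or singleton_rate/replicate_dropout"),
        max(sigma), sigma_max), class = "geochipr_error_infeasible")
    }
  }

  # Elevation-level thinning: chosen so the niche profile G = sigma / ell is
  # convex together with the point (0, 1); kappa > 1 keeps a slope margin.
  kappa <- 1.3
  if (length(Dist) >= 2 && sigma[1] - sigma[2] > 1e-12) {
    ell <- sigma[1] + kappa * Dist[1] / (Dist[2] - Dist[1]) * (sigma[1] - sigma[2])
    ell <- min(ell, 0.9995)
  } else {
    ell <- sigma[1]   # flat profile: G identically 1
  }
  G_target <- sigma / ell
  if (max(G_target) > 1 + 1e-12) {
    abort("infeasible occupancy calibration: elevation-level thinning cannot reach target similarity",
          class = "geochipr_error_infeasible")
  }
  G_target <- pmin(G_target, 1)

  dec <- hinge_decompose(Dist, G_target)
  widths <- dec$knots / 2
  span <- max(elev) - min(elev)
  # per-width-class centre range: just wide enough that every elevation has
  # the same marginal cover probability 2w / (span + 2w)
  L_k <- span + 2 * widths
  q <- 1 / (dec$beta_inf + sum(dec$beta * L_k / (2 * widths)))
  if (length(widths) == 0) q <- 1 / dec$beta_inf
  g <- design$occupancy_base / (ell * q)
  if (g > 1) {
    abort(sprintf(paste0(
      "infeasible parameter combination: occupancy_base = %.3f exceeds the ",
      "maximum %.3f attainable under this decay calibration"),
      design$occupancy_base, ell * q), class = "geochipr_error_infeasible")
  }

  pi_fin <- if (length(widths)) q * dec$beta * L_k / (2 * widths) else numeric(0)
  pi_inf <- q * dec$beta_inf

  d_e <- richness_adjusted_detect(design, d, rho, one_minus_sr)

  list(anchor = anchor, d = d, d_e = d_e, rho = rho, rho_e = retained_prob(d_e, R),
       s_within = within_similarity(d_e, R), s_line = s_line,
       ell = ell, g = g, q = q, L_k = L_k,
       widths = widths, pi_fin = pi_fin, pi_inf = pi_inf,
       G = dec$G, Dist = Dist, sigma = sigma)
}
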