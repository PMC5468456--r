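#' Sorensen similarity of two presence sets
#'
#' `2 |A n B| / (|A| + |B|)` on presence/absence.
#'
#' @param a,b Logical presence vectors over the same probe universe, or
#'   character vectors of present probe identifiers.
#' @return Similarity in `[0, 1]`.
#' @export
sorensen <- function(a, b) {
  if (is.character(a) || is.character(b)) {
    na <- length(unique(a)); nb <- length(unique(b))
    ni <- length(intersect(a, b))
  } else {
    stopifnot(length(a) == length(b))
    na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  }
  if (na + nb == 0) {
    abort("Sorensen similarity undefined: both sets empty",
          class = "geochipr_error_degenerate")
  }
  2 * ni / (na + nb)
}

#' Build the pairwise similarity-versus-distance table
#'
#' For every unordered sample pair (or elevation pair), the Sorensen
#' similarity of post-preprocessing presence sets and the elevation
#' difference in metres.  Zero distances (same-elevation pairs) are
#' substituted by `d_zero` so the log-log decay fit is defined, and flagged.
#'
#' @param abund A `geochip_abund` object.
#' @param category,subcategory Optional annotation filter restricting the
#'   probe universe before presence sets are formed.
#' @param level `"sample"` (default): all sample pairs.  `"elevation"`:
#'   pooled per-elevation presence (detected in >= 1 retained replicate).
#' @param d_zero Substituted distance for zero elevation difference (m).
#' @return An `edr_pairs` tibble: `unit_a`, `unit_b`, `distance`,
#'   `raw_distance`, `substituted`, `sorensen`.
#' @export
pair_table <- function(abund, category = NULL, subcategory = NULL,
                       level = c("sample", "elevation"), d_zero = 0.01) {
  level <- arg_match(level)
  stopifnot(inherits(abund, "geochip_abund"))
  det <- restrict_probes(abund, category, subcategory)
  sheet <- abund$samples
  if (is.null(sheet)) abort("abundance object carries no sample sheet",
                            class = "geochipr_error_format")

  if (level == "sample") {
    units <- colnames(det)
    elev <- sheet$elevation[match(units, sheet$sample_id)]
    pres <- det
  } else {
    elevs <- sort(unique(sheet$elevation))
    pres <- vapply(elevs, function(e) {
      cols <- sheet$sample_id[sheet$elevation == e]
      rowSums(det[, cols, drop = FALSE]) >= 1
    }, logical(nrow(det)))
    colnames(pres) <- as.character(elevs)
    units <- colnames(pres)
    elev <- elevs
  }
  if (sum(pres) == 0) {
    abort("no detected probes in the selected universe",
          class = "geochipr_error_empty")
  }
  n <- length(units)
  if (n < 2) abort("need >= 2 units", class = "geochipr_error_config")
  idx <- t(utils::combn(n, 2))
  sor <- vapply(seq_len(nrow(idx)), function(k) {
    sorensen(pres[, idx[k, 1]], pres[, idx[k, 2]])
  }, numeric(1))
  raw_d <- abs(elev[idx[, 1]] - elev[idx[, 2]])
  out <- tibble(
    unit_a = units[idx[, 1]], unit_b = units[idx[, 2]],
    raw_distance = raw_d,
    substituted = raw_d == 0,
    distance = if_else(raw_d == 0, d_zero, raw_d),
    sorensen = sor
  )
  attr(out, "d_zero") <- d_zero
  attr(out, "level") <- level
  class(out) <- c("edr_pairs", class(out))
  out
}

restrict_probes <- function(abund, category = NULL, subcategory = NULL) {
  det <- abund$detected
  if (is.null(category) && is.null(subcategory)) return(det)
  ann <- abund$annotation
  keep <- rep(TRUE, nrow(ann))
  if (!is.null(category)) keep <- keep & ann$category %in% category
  if (!is.null(subcategory)) keep <- keep & ann$subcategory %in% subcategory
  if (!any(keep)) {
    abort("no probes in the requested category", class = "geochipr_error_empty")
  }
  det[ann$probe_id[keep], , drop = FALSE]
}

#' Fit the elevation-decay relationship
#'
#' Ordinary least squares of `log(S)` on `log(D)` over the pair table; the
#' decay model is `log(S) = constant - 2 z log(D)`, so the reported exponent
#' is `z = -slope / 2`.  Pairs with zero similarity cannot enter the log fit
#' and are dropped and counted.  The slope, `z` and the correlation `r` are
#' invariant to the logarithm base; the constant is reported in the chosen
#' base.
#'
#' @param pairs An [pair_table()] result (any tibble with `distance` and
#'   `sorensen` works).
#' @param log_base `"10"` (default) or `"e"`.
#' @return An `edr_fit` object.
#' @export
fit_edr <- function(pairs, log_base = c("10", "e")) {
  log_base <- arg_match(log_base)
  lg <- if (log_base == "10") log10 else log
  pos <- pairs$sorensen > 0
  n_zero <- sum(!pos)
  use <- pairs[pos, , drop = FALSE]
  if (nrow(use) < 3) {
    abort("need >= 3 pairs with positive similarity", class = "geochipr_error_config")
  }
  x <- lg(use$distance); y <- lg(use$sorensen)
  if (length(unique(x)) < 2) {
    abort("degenerate regression: all pair distances identical",
          class = "geochipr_error_degenerate")
  }
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  r <- if (sd(y) == 0) 0 else unname(cor(x, y))
  p_slope <- suppressWarnings(summary(fit)$coefficients[2, 4])
  structure(list(
    z = -slope / 2,
    slope = slope,
    constant = intercept,
    r = r,
    p_slope = p_slope,
    n_pairs = nrow(use),
    n_zero_dropped = n_zero,
    log_base = log_base,
    d_zero = attr(pairs, "d_zero") %||% NA_real_,
    pairs = use
  ), class = "edr_fit")
}

#' Bootstrap inference for the decay slope
#'
#' Resamples the pair rows with replacement (same size) `n_boot` times and
#' refits the log-log regression.  Two assessments are reported, mirroring
#' the two uses of the bootstrap: (a) the bootstrap slope distribution
#' against zero (percentile confidence interval and a two-sided add-one
#' p-value), and (b) a one-sample t-test of the bootstrap slopes against the
#' observed slope.  Degenerate replicates (all resampled distances identical)
#' are redrawn, with a hard cap and a logged count.
#'
#' @param fit An [fit_edr()] result.
#' @param n_boot Number of bootstrap replicates (default 999).
#' @param seed Integer seed; the slope vector is reproducible given it.
#' @param conf_level Confidence level of the percentile interval.
#' @return The `edr_fit` with bootstrap fields added: `boot_slopes`,
#'   `boot_z`, `ci_slope`, `p_zero`, `reject_zero`, `t_vs_observed`,
#'   `p_vs_observed`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_edr <- function(fit, n_boot = 999, seed = 1L, conf_level = 0.95) {
  stopifnot(inherits(fit, "edr_fit"))
  lg <- if (fit$log_base == "10") log10 else log
  x <- lg(fit$pairs$distance); y <- lg(fit$pairs$sorensen)
  n <- length(x)
  set.seed(as.integer(seed))
  slopes <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (try in seq_len(100L)) {
      ii <- sample.int(n, n, replace = TRUE)
      xb <- x[ii]
      if (length(unique(xb)) >= 2) break
      n_redrawn <- n_redrawn + 1L
      if (try == 100L) {
        abort("bootstrap redraw cap reached: resampled distances keep collapsing",
              class = "geochipr_error_degenerate")
      }
    }
    yb <- y[ii]
    xc <- xb - mean(xb)
    slopes[b] <- sum(xc * yb) / sum(xc^2)
  }
  alpha <- 1 - conf_level
  ci <- unname(quantile(slopes, c(alpha / 2, 1 - alpha / 2), type = 7))
  frac_le <- (sum(slopes <= 0) + 1) / (n_boot + 1)
  frac_ge <- (sum(slopes >= 0) + 1) / (n_boot + 1)
  p_zero <- min(1, 2 * min(frac_le, frac_ge))
  if (sd(slopes) < 1e-12 * max(1, abs(fit$slope))) {
    # noiseless input: every resample reproduces the observed slope
    t_stat <- 0; p_obs <- 1
  } else {
    tt <- t.test(slopes, mu = fit$slope)
    t_stat <- unname(tt$statistic); p_obs <- tt$p.value
  }
  fit$boot_slopes <- slopes
  fit$boot_z <- -slopes / 2
  fit$ci_slope <- ci
  fit$p_zero <- p_zero
  fit$reject_zero <- ci[1] > 0 || ci[2] < 0
  fit$t_vs_observed <- t_stat
  fit$p_vs_observed <- p_obs
  fit$n_boot <- n_boot
  fit$n_redrawn <- n_redrawn
  fit$boot_seed <- as.integer(seed)
  fit
}

#' Fit the elevation-decay relationship from an abundance object
#'
#' Convenience wrapper: [pair_table()] + [fit_edr()] + optional
#' [bootstrap_edr()].
#'
#' @inheritParams pair_table
#' @inheritParams fit_edr
#' @param n_boot Bootstrap replicates; `0` skips the bootstrap.
#' @param seed Bootstrap seed.
#' @return An `edr_fit`.
#' @export
edr <- function(abund, category = NULL, subcategory = NULL,
                level = "sample", d_zero = 0.01, log_base = "10",
                n_boot = 999, seed = 1L) {
  pairs <- pair_table(abund, category = category, subcategory = subcategory,
                      level = level, d_zero = d_zero)
  fit <- fit_edr(pairs, log_base = log_base)
  if (n_boot > 0) fit <- bootstrap_edr(fit, n_boot = n_boot, seed = seed)
  fit
}

#' Per-category decay exponents with BH correction
#'
#' One decay fit per functional category (or subcategory/process), with
#' Benjamini-Hochberg adjustment of the p-values across the family.
#' Per-category failures (e.g. empty categories) are reported as flagged
#' rows, not errors.
#'
#' @param abund A `geochip_abund` object.
#' @param by `"category"` or `"subcategory"`.
#' @param groups Which groups to fit; default all present in the annotation.
#' @inheritParams edr
#' @return A tibble sorted by `z`: one row per group with `z`, `r`,
#'   `p_slope`, `p_zero`, `p_vs_observed`, BH-adjusted columns and an
#'   `error` flag column.
#' @export
category_edr_family <- function(abund, by = c("category", "subcategory"),
                                groups = NULL, level = "sample",
                                d_zero = 0.01, log_base = "10",
                                n_boot = 999, seed = 1L) {
  by <- arg_match(by)
  if (is.null(groups)) groups <- sort(unique(abund$annotation[[by]]))
  if (!length(groups)) abort("no categories to fit", class = "geochipr_error_empty")
  rows <- purrr::map(groups, function(g) {
    res <- tryCatch({
      args <- list(abund = abund, level = level, d_zero = d_zero,
                   log_base = log_base, n_boot = n_boot, seed = seed)
      args[[if (by == "category") "category" else "subcategory"]] <- g
      fit <- do.call(edr, args)
      tibble(group = g, z = fit$z, r = fit$r, n_pairs = fit$n_pairs,
             p_slope = fit$p_slope,
             p_zero = fit$p_zero %||% NA_real_,
             p_vs_observed = fit$p_vs_observed %||% NA_real_,
             error = NA_character_)
    }, error = function(e) {
      tibble(group = g, z = NA_real_, r = NA_real_, n_pairs = NA_integer_,
             p_slope = NA_real_, p_zero = NA_real_, p_vs_observed = NA_real_,
             error = conditionMessage(e))
    })
    res
  })
  out <- bind_rows(rows) %>%
    mutate(p_slope_adj = p.adjust(.data$p_slope, method = "BH"),
           p_zero_adj = p.adjust(.data$p_zero, method = "BH"),
           p_vs_observed_adj = p.adjust(.data$p_vs_observed, method = "BH")) %>%
    arrange(dplyr::desc(.data$z))
  out
}

#' Sensitivity of the decay exponent to the zero-distance substitution
#'
#' Same-elevation pairs have zero elevation difference and enter the log-log
#' fit only through the substituted distance `d_zero`; this diagnostic refits
#' the decay exponent over a grid of substitution values so the dependence is
#' visible in reports.
#'
#' @param abund A `geochip_abund` object (or an `edr_pairs` table).
#' @param d_zero_grid Substitution values (m) to scan.
#' @param ... Passed to [pair_table()] when `abund` is an abundance object.
#' @return A tibble `d_zero`, `z`, `r`.
#' @export
edr_sensitivity <- function(abund, d_zero_grid = c(0.01, 0.1, 1, 10, 100), ...) {
  get_pairs <- function(dz) {
    if (inherits(abund, "edr_pairs")) {
      p <- abund
      p$distance <- if_else(p$substituted, dz, p$raw_distance)
      attr(p, "d_zero") <- dz
      p
    } else {
      pair_table(abund, d_zero = dz, ...)
    }
  }
  purrr::map_dfr(d_zero_grid, function(dz) {
    fit <- fit_edr(get_pairs(dz))
    tibble(d_zero = dz, z = fit$z, r = fit$r)
  })
}

#' @export
print.edr_fit <- function(x, ...) {
  cat("<edr_fit>  log(S) = constant - 2 z log(D)\n")
  cat(sprintf("  z = %.4f   r = %.3f   n_pairs = %d (zero-similarity dropped: %d)\n",
              x$z, x$r, x$n_pairs, x$n_zero_dropped))
  if (!is.null(x$boot_slopes)) {
    cat(sprintf("  bootstrap (n = %d): slope CI [%.4g, %.4g], p(slope = 0) = %.4g\n",
                x$n_boot, x$ci_slope[1], x$ci_slope[2], x$p_zero))
    cat(sprintf("  one-sample t vs observed slope: t = %.3g, p = %.3g\n",
                x$t_vs_observed, x$p_vs_observed))
  }
  invisible(x)
}

#' @method tidy edr_fit
#' @export
tidy.edr_fit <- function(x, ...) {
  tibble(term = c("constant", "slope"),
         estimate = c(x$constant, x$slope))
}

#' @method glance edr_fit
#' @export
glance.edr_fit <- function(x, ...) {
  tibble(z = x$z, constant = x$constant, r = x$r, p_slope = x$p_slope,
         n_pairs = x$n_pairs, n_zero_dropped = x$n_zero_dropped,
         p_zero = x$p_zero %||% NA_real_,
         t_vs_observed = x$t_vs_observed %||% NA_real_,
         p_vs_observed = x$p_vs_observed %||% NA_real_,
         n_boot = x$n_boot %||% NA_integer_)
}

#' @method autoplot edr_fit
#' @export
autoplot.edr_fit <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$sorensen)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = "Elevation difference D (m, log scale)",
                  y = "Sorensen similarity (log scale)",
                  subtitle = sprintf("z = %.4f, r = %.2f", object$z, object$r)) +
    ggplot2::theme_minimal()
}
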