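#' Shannon diversity (nats)
#'
#' `H = -sum(p_i ln p_i)` over detected entries, with `p_i` the abundance
#' proportions.  Computed on (pre-log) normalized intensities, so it is
#' invariant to the shared normalization constant.
#'
#' @param x Nonnegative abundance vector.
#' @return Shannon index in nats.
#' @export
shannon <- function(x) {
  p <- check_abund_vector(x)
  -sum(p * log(p))
}

#' Simpson diversity
#'
#' @param x Nonnegative abundance vector.
#' @param variant `"gini"` (default, `1 - sum(p^2)`), `"inverse"`
#'   (`1 / sum(p^2)`) or `"dominance"` (`sum(p^2)`).
#' @return Simpson index under the chosen variant.
#' @export
simpson <- function(x, variant = c("gini", "inverse", "dominance")) {
  variant <- arg_match(variant)
  p <- check_abund_vector(x)
  D <- sum(p^2)
  switch(variant, gini = 1 - D, inverse = 1 / D, dominance = D)
}

#' Evenness
#'
#' Pielou evenness `J = H / ln(richness)` (default) or Simpson evenness
#' `(1 / sum(p^2)) / richness`.
#'
#' @param x Nonnegative abundance vector with at least two detected entries.
#' @param type `"pielou"` or `"simpson"`.
#' @return Evenness in `[0, 1]`.
#' @export
evenness <- function(x, type = c("pielou", "simpson")) {
  type <- arg_match(type)
  richness <- sum(x > 0, na.rm = TRUE)
  if (richness < 2) {
    abort("evenness is undefined for fewer than 2 detected entries",
          class = "geochipr_error_degenerate")
  }
  switch(type,
         pielou = shannon(x) / log(richness),
         simpson = simpson(x, "inverse") / richness)
}

check_abund_vector <- function(x) {
  x <- x[!is.na(x)]
  if (any(x < 0)) abort("abundances must be nonnegative", class = "geochipr_error_domain")
  s <- sum(x)
  if (s <= 0) {
    abort("degenerate sample: all abundances zero", class = "geochipr_error_degenerate")
  }
  p <- x[x > 0] / s
  p
}

#' Per-sample diversity profile along the gradient
#'
#' Richness (detected probes), Shannon, Simpson and evenness per sample,
#' computed on the pre-log normalized abundances.
#'
#' @param abund A `geochip_abund` object.
#' @return A `diversity_profile` tibble: one row per sample with the indices
#'   plus elevation and replicate.
#' @export
diversity_profile <- function(abund) {
  stopifnot(inherits(abund, "geochip_abund"))
  m <- abund$norm
  prof <- tibble(
    sample_id = colnames(m),
    richness = colSums(abund$detected),
    shannon = apply(m, 2, shannon),
    simpson = apply(m, 2, simpson),
    pielou = apply(m, 2, evenness, type = "pielou"),
    simpson_evenness = apply(m, 2, evenness, type = "simpson")
  )
  if (!is.null(abund$samples)) {
    prof <- left_join(prof,
                      select(abund$samples, "sample_id", "elevation", "replicate"),
                      by = "sample_id") %>%
      select("sample_id", "elevation", "replicate", dplyr::everything())
  }
  class(prof) <- c("diversity_profile", class(prof))
  prof
}

#' Trend of a diversity index along elevation
#'
#' Correlation of a per-sample index with elevation across samples, with a
#' two-sided p-value.
#'
#' @param profile A [diversity_profile()] result (or any tibble with
#'   `elevation` and the index column).
#' @param index Column name of the index (default `"shannon"`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `index`, `method`, `estimate`, `p.value`, `n`.
#' @export
trend_vs_elevation <- function(profile, index = "shannon",
                               method = c("pearson", "spearman")) {
  method <- arg_match(method)
  if (!index %in% names(profile)) {
    abort(paste("no column", index, "in profile"), class = "geochipr_error_format")
  }
  y <- profile[[index]]; e <- profile$elevation
  ok <- complete.cases(y, e)
  if (length(unique(e[ok])) < 3) {
    abort("need >= 3 distinct elevations for a trend", class = "geochipr_error_config")
  }
  if (sd(y[ok]) == 0) {
    abort("index is constant across samples; correlation undefined",
          class = "geochipr_error_degenerate")
  }
  ct <- suppressWarnings(cor.test(e[ok], y[ok], method = method))
  tibble(index = index, method = method,
         estimate = unname(ct$estimate), p.value = ct$p.value, n = sum(ok))
}

#' @method autoplot diversity_profile
#' @export
autoplot.diversity_profile <- function(object, index = "shannon", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$elevation, y = .data[[index]])) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "steelblue") +
    ggplot2::labs(x = "Elevation (m asl)", y = index) +
    ggplot2::theme_minimal()
}
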