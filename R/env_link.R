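#' Community distance matrix
#'
#' Bray-Curtis on normalized (pre-log) abundances by default; alternatives
#' are Euclidean on ln abundances and Sorensen (binary Bray-Curtis) on the
#' detection matrix.
#'
#' @param abund A `geochip_abund` object.
#' @param method `"bray"`, `"euclidean_ln"` or `"sorensen"`.
#' @return A `dist` over samples.
#' @export
community_distance <- function(abund, method = c("bray", "euclidean_ln", "sorensen")) {
  method <- arg_match(method)
  switch(method,
         bray = vegan::vegdist(t(abund$norm), method = "bray"),
         euclidean_ln = dist(t(abund$values)),
         sorensen = vegan::vegdist(t(abund$detected * 1), method = "bray", binary = TRUE))
}

#' Euclidean environmental distance on standardized columns
#'
#' @param sheet Sample sheet.
#' @param vars Column names to use.
#' @param sample_ids Restrict/order to these samples.
#' @return A `dist` over the samples with complete data for `vars`.
#' @export
env_distance <- function(sheet, vars, sample_ids = NULL) {
  if (!all(vars %in% names(sheet))) {
    abort(paste("unknown variables:", paste(setdiff(vars, names(sheet)), collapse = ", ")),
          class = "geochipr_error_format")
  }
  df <- sheet[, c("sample_id", vars)]
  if (!is.null(sample_ids)) df <- df[match(sample_ids, df$sample_id), ]
  keep <- complete.cases(df[, vars])
  x <- scale(as.matrix(df[keep, vars]))
  d <- dist(x)
  attr(d, "Labels") <- df$sample_id[keep]
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the distance vectors with a one-tailed permutation
#' p-value, `(count >= observed + 1) / (n_perm + 1)`.
#'
#' @param d_comm,d_env `dist` objects in matching sample order.
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed (permutation-deterministic).
#' @param method Correlation method on the distance vectors.
#' @return One-row tibble `statistic`, `p.value`, `n`, `n_perm`.
#' @export
mantel_test <- function(d_comm, d_env, n_perm = 999, seed = 1L,
                        method = "pearson") {
  if (attr(d_comm, "Size") != attr(d_env, "Size")) {
    abort("distance matrices have different sizes", class = "geochipr_error_format")
  }
  if (attr(d_comm, "Size") < 4) {
    abort("need >= 4 samples for a Mantel test", class = "geochipr_error_config")
  }
  set.seed(as.integer(seed))
  m <- vegan::mantel(d_comm, d_env, permutations = n_perm, method = method)
  tibble(statistic = unname(m$statistic), p.value = m$signif,
         n = attr(d_comm, "Size"), n_perm = n_perm)
}

#' Simple Mantel tests of community structure against single variables
#'
#' One test per environmental variable (plus elevation itself), each on the
#' samples with complete data for that variable; the community distance is
#' recomputed on the same subset so the matrices stay aligned.
#'
#' @param abund A `geochip_abund` object.
#' @param vars Variables to screen; default every numeric sample-sheet column
#'   except identifiers.
#' @param method Community distance metric, see [community_distance()].
#' @param n_perm,seed Permutation settings.
#' @param cor_method Correlation method on distances (`"pearson"` default).
#' @return Tibble `variable`, `statistic`, `p.value`, `n`, `stars`.
#' @export
mantel_env <- function(abund, vars = NULL, method = "bray",
                       n_perm = 999, seed = 1L, cor_method = "pearson") {
  sheet <- abund$samples
  if (is.null(vars)) {
    num <- names(sheet)[vapply(sheet, is.numeric, logical(1))]
    vars <- setdiff(num, c("replicate"))
  }
  d_full <- community_distance(abund, method = method)
  dm <- as.matrix(d_full)
  purrr::map_dfr(vars, function(v) {
    keep <- sheet$sample_id[!is.na(sheet[[v]])]
    keep <- intersect(colnames(dm), keep)
    if (length(keep) < 4) {
      return(tibble(variable = v, statistic = NA_real_, p.value = NA_real_,
                    n = length(keep), stars = "untested"))
    }
    dc <- as.dist(dm[keep, keep])
    de <- env_distance(sheet, v, sample_ids = keep)
    res <- mantel_test(dc, de, n_perm = n_perm, seed = seed, method = cor_method)
    tibble(variable = v, statistic = res$statistic, p.value = res$p.value,
           n = res$n, stars = p_stars(res$p.value))
  })
}

p_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Permutational multivariate ANOVA (PERMANOVA) on a distance matrix
#'
#' Pseudo-F from the among/within sum-of-squares decomposition of the
#' distance matrix with a permutation p-value over random relabelings
#' (adonis-style, one factor).
#'
#' @param d A `dist` over samples.
#' @param grouping Factor of group labels in the same order.
#' @param n_perm,seed Permutation settings.
#' @return One-row tibble `pseudo_F`, `R2`, `df`, `p.value`.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = 1L) {
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2) {
    abort("need >= 2 groups", class = "geochipr_error_config")
  }
  if (any(table(grouping) < 2)) {
    abort("every group needs >= 2 samples", class = "geochipr_error_config")
  }
  set.seed(as.integer(seed))
  df <- data.frame(g = grouping)
  a <- vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  tibble(pseudo_F = a$F[1], R2 = a$R2[1], df = a$Df[1], p.value = a$`Pr(>F)`[1])
}

#' PERMANOVA of community structure by elevation
#'
#' @param abund A `geochip_abund` object.
#' @param method Community distance metric.
#' @inheritParams permanova
#' @return One-row tibble as in [permanova()].
#' @export
permanova_elevation <- function(abund, method = "bray", n_perm = 999, seed = 1L) {
  d <- community_distance(abund, method = method)
  elev <- abund$samples$elevation[match(colnames(abund$norm), abund$samples$sample_id)]
  permanova(d, elev, n_perm = n_perm, seed = seed)
}

#' Relative abundance of functional categories or gene families
#'
#' Sum of normalized probe signals in each group divided by the sample's
#' total signal.
#'
#' @param abund A `geochip_abund` object.
#' @param by Annotation column to group probes by (`"category"`,
#'   `"subcategory"` or `"gene"`).
#' @return Long tibble `sample_id`, `group`, `rel_abundance`.
#' @export
category_abundance <- function(abund, by = "category") {
  ann <- abund$annotation
  if (!by %in% names(ann)) abort(paste("no annotation column", by),
                                 class = "geochipr_error_format")
  g <- ann[[by]][match(rownames(abund$norm), ann$probe_id)]
  totals <- colSums(abund$norm)
  agg <- rowsum(abund$norm, group = g)
  tibble(
    group = rep(rownames(agg), times = ncol(agg)),
    sample_id = rep(colnames(agg), each = nrow(agg)),
    rel_abundance = as.vector(sweep(agg, 2, totals, "/"))
  )
}

#' Pearson-correlation screen of group abundances against environment, with FDR
#'
#' One Pearson correlation per (group, variable) pair on pairwise-complete
#' observations, BH-adjusted across the whole screen (one family per run).
#' Pairs with fewer than 4 complete observations are flagged untested rather
#' than silently dropped.
#'
#' @param abundances Long tibble from [category_abundance()].
#' @param sheet Sample sheet.
#' @param vars Environmental variables to screen; default all numeric except
#'   identifiers and elevation-design columns.
#' @return Tibble `group`, `variable`, `n`, `estimate`, `p.value`, `p_adj`,
#'   `tested`, `stars`.
#' @export
pearson_fdr_screen <- function(abundances, sheet, vars = NULL) {
  if (is.null(vars)) {
    num <- names(sheet)[vapply(sheet, is.numeric, logical(1))]
    vars <- setdiff(num, c("replicate", "elevation"))
  }
  wide <- tidyr::pivot_wider(abundances, names_from = "group",
                             values_from = "rel_abundance")
  merged <- left_join(wide, sheet, by = "sample_id")
  groups <- unique(abundances$group)
  out <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(vars, function(v) {
      x <- merged[[g]]; y <- merged[[v]]
      ok <- complete.cases(x, y)
      if (sum(ok) < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        return(tibble(group = g, variable = v, n = sum(ok),
                      estimate = NA_real_, p.value = NA_real_, tested = FALSE))
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      tibble(group = g, variable = v, n = sum(ok),
             estimate = unname(ct$estimate), p.value = ct$p.value, tested = TRUE)
    })
  })
  out %>%
    mutate(p_adj = p.adjust(.data$p.value, method = "BH"),
           stars = p_stars(.data$p_adj))
}

#' Variance-inflation-factor screening of environmental variables
#'
#' Iteratively drops the variable with the highest VIF (`1 / (1 - R^2)` of
#' that variable regressed on the remaining candidates) until all VIFs are
#' below `threshold`.  Perfectly collinear variables surface as infinite VIF
#' and are dropped first.
#'
#' @param sheet Sample sheet (or any data frame).
#' @param vars Candidate variable names.
#' @param threshold Retention threshold (default 20).
#' @return A `vif_screen` object: `retained` (names), `vifs` (final values),
#'   `dropped` (tibble of drop order and VIF at drop time).
#' @export
vif_screen <- function(sheet, vars, threshold = 20) {
  if (length(vars) < 2) abort("need >= 2 candidate variables",
                              class = "geochipr_error_config")
  df <- as.data.frame(sheet[, vars])
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) <= length(vars)) {
    abort("need more complete samples than candidate variables",
          class = "geochipr_error_config")
  }
  vif_of <- function(cols) {
    vapply(cols, function(v) {
      others <- setdiff(cols, v)
      r2 <- suppressWarnings(summary(lm(stats::reformulate(others, v), data = df)))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  current <- vars
  dropped <- tibble(variable = character(), vif = numeric(), order = integer())
  step <- 0L
  while (length(current) >= 2) {
    v <- vif_of(current)
    if (all(v < threshold)) break
    step <- step + 1L
    worst <- names(v)[which.max(v)]
    dropped <- bind_rows(dropped, tibble(variable = worst, vif = unname(v[worst]),
                                         order = step))
    current <- setdiff(current, worst)
  }
  final <- if (length(current) >= 2) vif_of(current) else setNames(1, current)
  structure(list(retained = current, vifs = final, dropped = dropped,
                 threshold = threshold), class = "vif_screen")
}

#' @export
print.vif_screen <- function(x, ...) {
  cat("<vif_screen> threshold", x$threshold, "\n")
  cat("  retained:", paste(sprintf("%s (%.2f)", names(x$vifs), x$vifs),
                           collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped :", paste(sprintf("%s (VIF %.3g)", x$dropped$variable,
                                     x$dropped$vif), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Constrained correspondence analysis of the community matrix
#'
#' CCA of the ln-abundance community matrix constrained by environmental
#' variables, returning the constrained-inertia fraction and a permutation
#' significance test.
#'
#' @param abund A `geochip_abund` object (ln abundances are ordinated).
#' @param vars Constraint variable names (usually [vif_screen()] survivors).
#' @param n_perm,seed Permutation settings for the significance test (0 skips).
#' @return A `cca_fit`: `explained` (constrained-inertia fraction), `p.value`,
#'   `model` (the vegan object), `n`, `vars`.
#' @export
constrained_ordination <- function(abund, vars, n_perm = 199, seed = 1L) {
  Y <- t(abund$values)
  sheet <- abund$samples
  if (length(vars) > nrow(Y) - 1) {
    abort("more constraints than samples - 1", class = "geochipr_error_rank")
  }
  miss <- setdiff(vars, names(sheet))
  if (length(miss)) {
    abort(paste("unknown constraint variables:", paste(miss, collapse = ", ")),
          class = "geochipr_error_format")
  }
  df <- as.data.frame(sheet[match(rownames(Y), sheet$sample_id), vars, drop = FALSE])
  keep <- complete.cases(df)
  Y <- Y[keep, colSums(Y[keep, , drop = FALSE]) > 0, drop = FALSE]
  df <- df[keep, , drop = FALSE]
  if (length(vars) > nrow(Y) - 1) {
    abort("more constraints than samples - 1", class = "geochipr_error_rank")
  }
  mm <- as.matrix(df)
  if (qr(scale(mm, scale = FALSE))$rank < ncol(mm)) {
    abort("constraint matrix is rank deficient (duplicate or collinear columns)",
          class = "geochipr_error_rank")
  }
  model <- vegan::cca(Y ~ ., data = df)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    p <- vegan::anova.cca(model, permutations = n_perm)$`Pr(>F)`[1]
  }
  structure(list(explained = model$CCA$tot.chi / model$tot.chi,
                 p.value = p, model = model, n = nrow(Y), vars = vars),
            class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("<cca_fit> %d samples, %d constraints: %.1f%% inertia explained",
              x$n, length(x$vars), 100 * x$explained))
  if (!is.na(x$p.value)) cat(sprintf(" (perm p = %.3g)", x$p.value))
  cat("\n")
  invisible(x)
}

#' Variation partitioning across three variable groups
#'
#' Partitions the community variation explained by three disjoint groups of
#' environmental variables into the seven pure/shared components by
#' inclusion-exclusion over constrained ordinations of every nonempty group
#' union; the components sum to the full-model explained fraction by
#' construction.
#'
#' @param abund A `geochip_abund` object.
#' @param groups Named list of exactly three disjoint character vectors of
#'   variable names.
#' @return A `variation_partition` object: `components` tibble (the seven
#'   fractions plus residual), `total_explained`, per-subset fractions.
#' @export
variation_partition <- function(abund, groups) {
  if (length(groups) != 3) abort("need exactly three variable groups",
                                 class = "geochipr_error_config")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- c("A", "B", "C")
  }
  if (any(lengths(groups) == 0)) abort("groups must be nonempty",
                                       class = "geochipr_error_config")
  if (length(unlist(groups)) != length(unique(unlist(groups)))) {
    abort("groups must be disjoint", class = "geochipr_error_config")
  }
  gn <- names(groups)
  subsets <- list(
    A = groups[[1]], B = groups[[2]], C = groups[[3]],
    AB = c(groups[[1]], groups[[2]]), AC = c(groups[[1]], groups[[3]]),
    BC = c(groups[[2]], groups[[3]]),
    ABC = unlist(groups)
  )
  f <- vapply(subsets, function(v) {
    constrained_ordination(abund, v, n_perm = 0)$explained
  }, numeric(1))
  pure_a <- f[["ABC"]] - f[["BC"]]
  pure_b <- f[["ABC"]] - f[["AC"]]
  pure_c <- f[["ABC"]] - f[["AB"]]
  abc <- f[["A"]] + f[["B"]] + f[["C"]] -
    f[["AB"]] - f[["AC"]] - f[["BC"]] + f[["ABC"]]
  ab <- f[["A"]] + f[["B"]] - f[["AB"]] - abc
  ac <- f[["A"]] + f[["C"]] - f[["AC"]] - abc
  bc <- f[["B"]] + f[["C"]] - f[["BC"]] - abc
  comp <- tibble(
    component = c(paste0("pure_", gn), paste0("shared_", c(paste(gn[1], gn[2], sep = "_"),
                                                           paste(gn[1], gn[3], sep = "_"),
                                                           paste(gn[2], gn[3], sep = "_"))),
                  "shared_all", "residual"),
    fraction = c(pure_a, pure_b, pure_c, ab, ac, bc, abc, 1 - f[["ABC"]])
  )
  structure(list(components = comp, total_explained = f[["ABC"]],
                 subset_fractions = f, groups = groups),
            class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat(sprintf("<variation_partition> total explained: %.2f%%\n",
              100 * x$total_explained))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  %-18s %7.2f%%\n", x$components$component[i],
                100 * x$components$fraction[i]))
  }
  invisible(x)
}
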