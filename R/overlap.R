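#' Per-elevation presence sets
#'
#' A probe is present at an elevation iff it is detected in at least one
#' retained replicate there (after preprocessing).
#'
#' @param abund A `geochip_abund` object.
#' @return Logical matrix, probes x elevations.
#' @export
elevation_presence <- function(abund) {
  stopifnot(inherits(abund, "geochip_abund"))
  sheet <- abund$samples
  if (is.null(sheet)) abort("abundance object carries no sample sheet",
                            class = "geochipr_error_format")
  elevs <- sort(unique(sheet$elevation))
  pres <- vapply(elevs, function(e) {
    cols <- sheet$sample_id[sheet$elevation == e]
    rowSums(abund$detected[, cols, drop = FALSE]) >= 1
  }, logical(nrow(abund$detected)))
  colnames(pres) <- as.character(elevs)
  rownames(pres) <- rownames(abund$detected)
  pres
}

#' Ubiquitous / unique gene accounting over elevations
#'
#' Classifies every detected probe by its elevation occupancy: ubiquitous
#' (detected at all elevations), unique (detected at exactly one), or
#' intermediate.  Pairwise shared-gene counts are reported with three
#' denominators, since "percentage of shared genes" admits several readings:
#' the pair union (default, Jaccard-style), the smaller set of the pair, and
#' all detected genes.
#'
#' @param presence Logical probes x elevations matrix (from
#'   [elevation_presence()]), or a `geochip_abund` object.
#' @return An `overlap_report` object.
#' @export
classify_overlap <- function(presence) {
  if (inherits(presence, "geochip_abund")) presence <- elevation_presence(presence)
  if (ncol(presence) < 2) abort("need >= 2 elevations", class = "geochipr_error_config")
  n_occ <- rowSums(presence)
  union_n <- sum(n_occ >= 1)
  if (union_n == 0) abort("no probe detected anywhere", class = "geochipr_error_degenerate")
  nE <- ncol(presence)
  per_elev <- tibble(
    elevation = as.numeric(colnames(presence)),
    detected = colSums(presence),
    unique = colSums(presence & n_occ == 1)
  ) %>%
    mutate(unique_fraction_of_site = .data$unique / .data$detected)

  ubiquitous <- sum(n_occ == nE)
  unique_total <- sum(n_occ == 1)

  shared <- crossprod(presence)            # |A n B|
  sizes <- colSums(presence)
  pair_union <- outer(sizes, sizes, "+") - shared
  pct_pair_union <- shared / pair_union
  pct_min_set <- shared / outer(sizes, sizes, pmin)
  pct_all_detected <- shared / union_n
  diag_names <- colnames(presence)

  structure(list(
    n_elevations = nE,
    union_detected = union_n,
    per_elevation = per_elev,
    ubiquitous = ubiquitous,
    ubiquitous_fraction = ubiquitous / union_n,
    unique_total = unique_total,
    unique_fraction = unique_total / union_n,
    intermediate = union_n - ubiquitous - unique_total,
    shared_counts = shared,
    shared_pct_pair_union = pct_pair_union,
    shared_pct_min_set = pct_min_set,
    shared_pct_all_detected = pct_all_detected,
    shared_denominator_default = "pair_union"
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  cat(sprintf("  detected genes (union)  : %d\n", x$union_detected))
  cat(sprintf("  ubiquitous              : %d (%.2f%%)\n",
              x$ubiquitous, 100 * x$ubiquitous_fraction))
  cat(sprintf("  unique to one elevation : %d (%.2f%%)\n",
              x$unique_total, 100 * x$unique_fraction))
  cat(sprintf("  intermediate            : %d\n", x$intermediate))
  cat("  shared %% (pair-union denominator, default):\n")
  print(round(100 * x$shared_pct_pair_union, 2))
  invisible(x)
}

#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  nE <- x$n_elevations
  elevs <- as.numeric(rownames(x$shared_counts))
  idx <- t(utils::combn(nE, 2))
  tibble(
    elev_a = elevs[idx[, 1]], elev_b = elevs[idx[, 2]],
    distance = abs(elevs[idx[, 2]] - elevs[idx[, 1]]),
    shared = x$shared_counts[idx],
    pct_pair_union = x$shared_pct_pair_union[idx],
    pct_min_set = x$shared_pct_min_set[idx],
    pct_all_detected = x$shared_pct_all_detected[idx]
  )
}

#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble(union_detected = x$union_detected,
         ubiquitous = x$ubiquitous,
         ubiquitous_fraction = x$ubiquitous_fraction,
         unique_total = x$unique_total,
         unique_fraction = x$unique_fraction,
         intermediate = x$intermediate)
}

#' Correlation of shared-gene counts with elevation distance
#'
#' Pearson correlation between pairwise shared detected-probe counts and
#' pairwise elevation differences.  The default pairs samples (more points);
#' `level = "elevation"` pairs pooled elevations.
#'
#' @param abund A `geochip_abund` object.
#' @param level `"sample"` or `"elevation"`.
#' @return One-row tibble `estimate`, `p.value`, `n_pairs`, `level`.
#' @export
shared_vs_distance <- function(abund, level = c("sample", "elevation")) {
  level <- arg_match(level)
  stopifnot(inherits(abund, "geochip_abund"))
  sheet <- abund$samples
  if (level == "sample") {
    pres <- abund$detected
    elev <- sheet$elevation[match(colnames(pres), sheet$sample_id)]
  } else {
    pres <- elevation_presence(abund)
    elev <- as.numeric(colnames(pres))
  }
  n <- ncol(pres)
  idx <- t(utils::combn(n, 2))
  if (nrow(idx) < 3) abort("need >= 3 pairs", class = "geochipr_error_config")
  shared <- crossprod(pres)[idx]
  d <- abs(elev[idx[, 1]] - elev[idx[, 2]])
  if (sd(shared) == 0) {
    abort("shared counts are constant; correlation undefined",
          class = "geochipr_error_degenerate")
  }
  ct <- cor.test(d, shared, method = "pearson")
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         n_pairs = nrow(idx), level = level)
}
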