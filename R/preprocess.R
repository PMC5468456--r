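#' @keywords internal
#' Stage bookkeeping: the preprocessing chain is ordered (SNR filter ->
#' replicate filter -> normalization -> log transform) and each step refuses
#' to run out of order.  Filters accept their own output so they are
#' idempotent.
stage_of <- function(x) attr(x, "geochip_stage") %||% "raw"

require_stage <- function(x, allowed, step) {
  if (!stage_of(x) %in% allowed) {
    abort(sprintf("%s must run after %s (input is at stage '%s')",
                  step, paste(allowed, collapse = "/"), stage_of(x)),
          class = "geochipr_error_order")
  }
  invisible(x)
}

prov_of <- function(x) attr(x, "geochip_prov") %||% list()

add_prov <- function(x, record) {
  prov <- prov_of(x)
  prov[[length(prov) + 1]] <- record
  attr(x, "geochip_prov") <- prov
  x
}

#' Remove array spots with low signal-to-noise ratio
#'
#' Marks spots with SNR strictly below `threshold` as undetected, per spot and
#' per sample (a probe stays detected in samples where its SNR passes).
#'
#' @param table Long probe table (`probe_id`, `sample_id`, `signal`, `snr`).
#' @param threshold SNR detection threshold; spots with `snr < threshold` are
#'   removed.
#' @return The table with a logical `detected` column and provenance attached.
#' @export
filter_snr <- function(table, threshold = 2) {
  if (!"snr" %in% names(table)) {
    abort("probe table has no 'snr' column", class = "geochipr_error_format")
  }
  require_stage(table, c("raw", "snr"), "filter_snr")
  prov <- prov_of(table)
  had <- if ("detected" %in% names(table)) table$detected else rep(TRUE, nrow(table))
  out <- mutate(table, detected = had & .data$snr >= threshold)
  attr(out, "geochip_stage") <- "snr"
  attr(out, "geochip_prov") <- c(prov, list(list(
    step = "filter_snr", threshold = threshold,
    removed = sum(had) - sum(out$detected))))
  out
}

#' Remove spots detected in only one replicate of an elevation group
#'
#' Within each elevation's replicate group, a probe detected in exactly one
#' replicate is set undetected in that replicate; probes detected in two or
#' more replicates of the group are untouched.  Groups are independent, so a
#' probe may survive at one elevation and be removed at another.
#'
#' @param table Probe table that has passed [filter_snr()].
#' @param sheet Sample sheet with `sample_id`, `elevation`, `replicate`.
#' @return The filtered table.
#' @export
filter_replicate_singletons <- function(table, sheet) {
  require_stage(table, c("snr", "replicate"), "filter_replicate_singletons")
  check_sheet(sheet)
  grp_sizes <- dplyr::count(distinct(sheet, .data$sample_id, .data$elevation),
                            .data$elevation)
  if (any(grp_sizes$n < 2)) {
    abort("every elevation needs >= 2 replicates for the replicate filter",
          class = "geochipr_error_config")
  }
  missing <- setdiff(unique(table$sample_id), sheet$sample_id)
  if (length(missing)) {
    abort(paste("samples absent from sheet:", paste(missing, collapse = ", ")),
          class = "geochipr_error_format")
  }
  prov <- prov_of(table)
  joined <- table %>%
    left_join(select(sheet, "sample_id", "elevation"), by = "sample_id") %>%
    group_by(.data$probe_id, .data$elevation) %>%
    mutate(.keep_spot = .data$detected & sum(.data$detected) >= 2L) %>%
    ungroup()
  removed_by_elev <- joined %>%
    filter(.data$detected & !.data$.keep_spot) %>%
    dplyr::count(.data$elevation, name = "removed")
  out <- joined %>%
    mutate(detected = .data$.keep_spot) %>%
    select(-"elevation", -".keep_spot")
  removed <- sum(table$detected) - sum(out$detected)
  attr(out, "geochip_stage") <- "replicate"
  attr(out, "geochip_prov") <- c(prov, list(list(step = "filter_replicate_singletons",
                                                 removed = removed,
                                                 removed_by_elevation = removed_by_elev)))
  attr(out, "geochip_samples") <- sheet
  out
}

#' Normalize spot intensities by per-sample total signal
#'
#' Divides every detected spot's intensity by the total detected signal of its
#' sample and multiplies by one shared constant, so the per-sample totals are
#' identical afterwards.  The default constant is the mean of the per-sample
#' totals, which keeps values near the raw scale.
#'
#' @param table Probe table that has passed both filters.
#' @param constant_rule `"mean_total"` (default) or `"fixed"`.
#' @param constant The constant when `constant_rule = "fixed"`.
#' @return The table with `signal` replaced by normalized intensity
#'   (undetected spots are exactly 0).
#' @export
normalize_total_signal <- function(table, constant_rule = c("mean_total", "fixed"),
                                   constant = NULL) {
  constant_rule <- arg_match(constant_rule)
  require_stage(table, "replicate", "normalize_total_signal")
  prov <- prov_of(table); sheet <- attr(table, "geochip_samples")
  totals <- table %>%
    group_by(.data$sample_id) %>%
    summarise(total = sum(.data$signal[.data$detected]), .groups = "drop")
  if (any(totals$total <= 0)) {
    bad <- totals$sample_id[totals$total <= 0]
    abort(paste("degenerate sample(s) with zero total detected signal:",
                paste(bad, collapse = ", ")),
          class = "geochipr_error_degenerate")
  }
  const <- switch(constant_rule,
                  mean_total = mean(totals$total),
                  fixed = {
                    if (is.null(constant)) {
                      abort("constant_rule = 'fixed' needs a constant",
                            class = "geochipr_error_config")
                    }
                    constant
                  })
  out <- table %>%
    left_join(totals, by = "sample_id") %>%
    mutate(signal = if_else(.data$detected, .data$signal / .data$total * const, 0),
           total = NULL)
  attr(out, "geochip_stage") <- "normalized"
  attr(out, "geochip_prov") <- c(prov, list(list(step = "normalize_total_signal",
                                                 rule = constant_rule,
                                                 constant = const)))
  attr(out, "geochip_samples") <- sheet
  attr(out, "geochip_constant") <- const
  out
}

#' Natural-log transform and assembly of the abundance matrix
#'
#' Applies the natural logarithm to normalized detected intensities and
#' assembles the `geochip_abund` container used by all downstream stages:
#' an ln-abundance matrix, the parallel pre-log normalized matrix, the
#' boolean detection matrix, probe annotation and the full preprocessing
#' provenance.
#'
#' @param table Normalized probe table.
#' @param offset `"plus1"` (default) applies `ln(x + 1)` uniformly;
#'   `"none"` applies plain `ln(x)` and errors on values <= 0.
#' @return A `geochip_abund` object.
#' @export
log_transform <- function(table, offset = c("plus1", "none")) {
  offset <- arg_match(offset)
  require_stage(table, "normalized", "log_transform")
  prov <- prov_of(table)
  sheet <- attr(table, "geochip_samples")

  wide <- function(col) {
    m <- table %>%
      select("probe_id", "sample_id", all_of(col)) %>%
      tidyr::pivot_wider(names_from = "sample_id", values_from = all_of(col))
    mat <- as.matrix(wide_drop_id(m))
    rownames(mat) <- m$probe_id
    mat
  }
  norm <- wide("signal")
  det <- wide("detected") > 0
  if (!is.null(sheet)) {
    keep <- intersect(sheet$sample_id, colnames(norm))
    norm <- norm[, keep, drop = FALSE]; det <- det[, keep, drop = FALSE]
  }
  norm[!det] <- 0
  if (offset == "none") {
    if (any(norm[det] <= 0)) {
      abort("nonpositive normalized value reached ln() with offset = 'none'",
            class = "geochipr_error_domain")
    }
    vals <- ifelse(det, suppressWarnings(log(norm)), 0)
  } else {
    vals <- ifelse(det, log1p(norm), 0)
  }

  annot_cols <- intersect(c("probe_id", "gene", "category", "subcategory", "organism"),
                          names(table))
  annot <- distinct(select(table, all_of(annot_cols)))

  structure(list(
    values = vals,
    norm = norm,
    detected = det,
    annotation = annot,
    samples = sheet,
    log_offset = offset,
    norm_constant = attr(table, "geochip_constant"),
    provenance = c(prov, list(list(step = "log_transform", offset = offset)))
  ), class = "geochip_abund")
}

wide_drop_id <- function(m) m[, setdiff(names(m), "probe_id"), drop = FALSE]

#' Run the full preprocessing chain
#'
#' The public pipeline entry point; runs the four steps in their fixed order:
#' SNR filter, replicate-singleton filter, total-signal normalization,
#' natural-log transform.
#'
#' @param signals Raw long probe table (e.g. from [generate_signal_table()]
#'   or [read_probe_table()]).
#' @param samples Sample sheet.
#' @param snr_min SNR detection threshold.
#' @inheritParams normalize_total_signal
#' @inheritParams log_transform
#' @return A `geochip_abund` object.
#' @export
preprocess_geochip <- function(signals, samples, snr_min = 2,
                               constant_rule = "mean_total", constant = NULL,
                               offset = "plus1") {
  signals %>%
    filter_snr(threshold = snr_min) %>%
    filter_replicate_singletons(samples) %>%
    normalize_total_signal(constant_rule = constant_rule, constant = constant) %>%
    log_transform(offset = offset)
}

check_sheet <- function(sheet) {
  need <- c("sample_id", "elevation", "replicate")
  if (!all(need %in% names(sheet))) {
    abort(paste("sample sheet needs columns:", paste(need, collapse = ", ")),
          class = "geochipr_error_format")
  }
  if (!is.numeric(sheet$elevation)) {
    abort("elevation must be numeric (m asl)", class = "geochipr_error_format")
  }
  invisible(sheet)
}

#' @export
print.geochip_abund <- function(x, ...) {
  cat("<geochip_abund>:", nrow(x$values), "probes x", ncol(x$values), "samples\n")
  cat("  detected spots :", sum(x$detected), "\n")
  cat("  normalization  :", format(x$norm_constant), "(shared constant)\n")
  cat("  log offset     :", x$log_offset, "\n")
  for (p in x$provenance) {
    if (!is.null(p$removed)) cat("  ", p$step, ": removed", p$removed, "spots\n")
  }
  invisible(x)
}

#' Tidy a preprocessed abundance object into a long tibble
#'
#' @param x A `geochip_abund` object.
#' @param ... Unused.
#' @return One row per probe x sample with ln abundance, pre-log normalized
#'   abundance and detection state.
#' @method tidy geochip_abund
#' @export
tidy.geochip_abund <- function(x, ...) {
  tibble(
    probe_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    ln_abundance = as.vector(x$values),
    abundance = as.vector(x$norm),
    detected = as.vector(x$detected)
  )
}
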