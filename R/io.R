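#' Write a probe table as tab-delimited text
#'
#' Wide layout: one row per probe with annotation columns followed by paired
#' `<sample>_signal` / `<sample>_snr` columns.
#'
#' @param table Long probe table.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_probe_table <- function(table, path) {
  annot_cols <- intersect(c("probe_id", "gene", "category", "subcategory", "organism"),
                          names(table))
  wide <- table %>%
    select(all_of(annot_cols), "sample_id", "signal", "snr") %>%
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = c("signal", "snr"),
                       names_glue = "{sample_id}_{.value}")
  # order: signal/snr pairs per sample
  samples <- unique(table$sample_id)
  ord <- c(annot_cols, as.vector(rbind(paste0(samples, "_signal"),
                                       paste0(samples, "_snr"))))
  readr::write_tsv(wide[, ord], path)
  invisible(path)
}

#' Read a tab-delimited probe table
#'
#' Expects the layout written by [write_probe_table()]: annotation columns
#' (`probe_id` mandatory) plus paired `<sample>_signal` / `<sample>_snr`
#' columns.
#'
#' @param path Input file.
#' @return A long probe table at stage `"raw"`.
#' @export
read_probe_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"probe_id" %in% names(wide)) {
    abort("probe table needs a probe_id column", class = "geochipr_error_format")
  }
  sig_cols <- grep("_signal$", names(wide), value = TRUE)
  snr_cols <- grep("_snr$", names(wide), value = TRUE)
  samples <- sub("_signal$", "", sig_cols)
  if (!setequal(samples, sub("_snr$", "", snr_cols))) {
    abort("signal and snr columns do not pair up", class = "geochipr_error_format")
  }
  if (!length(samples)) {
    abort("no <sample>_signal columns found", class = "geochipr_error_format")
  }
  annot_cols <- setdiff(names(wide), c(sig_cols, snr_cols))
  long <- wide %>%
    tidyr::pivot_longer(cols = all_of(c(sig_cols, snr_cols)),
                        names_to = c("sample_id", ".value"),
                        names_pattern = "(.*)_(signal|snr)$")
  out <- as_tibble(long[, c(annot_cols, "sample_id", "signal", "snr")])
  attr(out, "geochip_stage") <- "raw"
  out
}

#' Read a sample sheet
#'
#' @param path CSV file with at least `sample_id`, `elevation`, `replicate`.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_sheet(sheet)
  sheet
}

#' Write a preprocessed abundance matrix with a provenance sidecar
#'
#' @param abund A `geochip_abund` object.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_abundance <- function(abund, dir) {
  stopifnot(inherits(abund, "geochip_abund"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "abundance_ln.tsv"),
             detected = file.path(dir, "detected.tsv"),
             provenance = file.path(dir, "provenance.json"))
  readr::write_tsv(as_tibble(abund$values, rownames = "probe_id"), paths[["matrix"]])
  readr::write_tsv(as_tibble(abund$detected * 1L, rownames = "probe_id"),
                   paths[["detected"]])
  jsonlite::write_json(list(
    norm_constant = abund$norm_constant,
    log_offset = abund$log_offset,
    steps = abund$provenance
  ), paths[["provenance"]], auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(paths)
}

#' Load a GEO series-matrix export of GeoChip signals
#'
#' Maps a series-matrix style text export (metadata lines starting with `!`,
#' a tab-delimited block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` with an `ID_REF` probe column and one column
#' per sample) onto the long probe-table layout the preprocessing chain
#' reads.  Deposited GeoChip series matrices typically contain already
#' SNR-filtered intensities without SNR columns; in that case spots with a
#' reported signal are given an SNR above any plausible threshold (`Inf`) and
#' empty cells a SNR of 0, so the SNR filter reproduces the deposited
#' detection pattern.
#'
#' @param path Series-matrix text file.
#' @param annotation Optional tibble (or path to a TSV) with `probe_id` plus
#'   any of `gene`, `category`, `subcategory`, `organism`.
#' @return A long probe table at stage `"raw"`.
#' @export
read_geo_series_matrix <- function(path, annotation = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1) {
    abort("no series_matrix_table block found", class = "geochipr_error_format")
  }
  block <- lines[(beg + 1):(end - 1)]
  tab <- readr::read_tsv(I(block), show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA", "null"))
  names(tab)[1] <- "probe_id"
  tab$probe_id <- gsub('^"|"$', "", as.character(tab$probe_id))
  long <- tab %>%
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "signal") %>%
    mutate(signal = suppressWarnings(as.numeric(.data$signal)),
           snr = if_else(!is.na(.data$signal) & .data$signal > 0, Inf, 0),
           signal = dplyr::coalesce(.data$signal, 0))
  if (!is.null(annotation)) {
    if (is.character(annotation)) {
      annotation <- readr::read_tsv(annotation, show_col_types = FALSE,
                                    progress = FALSE)
    }
    long <- left_join(long, annotation, by = "probe_id")
  }
  out <- as_tibble(long[, c(intersect(c("probe_id", "gene", "category",
                                        "subcategory", "organism"), names(long)),
                            "sample_id", "signal", "snr")])
  attr(out, "geochip_stage") <- "raw"
  out
}

#' Validate raw inputs before any computation
#'
#' Schema and consistency checks on a probe table and sample sheet: missing
#' columns, sample-identifier mismatches, duplicate probe rows, negative
#' signals, missing SNR.  Returns findings rather than erroring, so a run
#' configuration can decide how to proceed.
#'
#' @param signals Long probe table or path to one.
#' @param samples Sample sheet or path to one.
#' @return A tibble of findings (`check`, `severity`, `detail`); zero rows
#'   means a clean input.
#' @export
validate_inputs <- function(signals, samples) {
  if (is.character(signals)) signals <- read_probe_table(signals)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  finding <- function(check, severity, detail) {
    tibble(check = check, severity = severity, detail = detail)
  }
  out <- list(tibble(check = character(), severity = character(),
                     detail = character()))
  need <- c("probe_id", "sample_id", "signal", "snr")
  miss <- setdiff(need, names(signals))
  if (length(miss)) {
    out <- c(out, list(finding("columns", "error",
                               paste("probe table missing:", paste(miss, collapse = ", ")))))
    return(bind_rows(out))
  }
  sheet_miss <- setdiff(c("sample_id", "elevation", "replicate"), names(samples))
  if (length(sheet_miss)) {
    out <- c(out, list(finding("columns", "error",
                               paste("sample sheet missing:", paste(sheet_miss, collapse = ", ")))))
    return(bind_rows(out))
  }
  not_in_table <- setdiff(samples$sample_id, signals$sample_id)
  if (length(not_in_table)) {
    out <- c(out, list(finding("sample_match", "error",
                               paste("in sheet but not in probe table:",
                                     paste(not_in_table, collapse = ", ")))))
  }
  not_in_sheet <- setdiff(signals$sample_id, samples$sample_id)
  if (length(not_in_sheet)) {
    out <- c(out, list(finding("sample_match", "error",
                               paste("in probe table but not in sheet:",
                                     paste(not_in_sheet, collapse = ", ")))))
  }
  dup <- signals %>%
    dplyr::count(.data$probe_id, .data$sample_id) %>%
    filter(n > 1)
  if (nrow(dup)) {
    out <- c(out, list(finding("duplicate_probe", "error",
                               paste("duplicated probe rows:",
                                     paste(unique(dup$probe_id), collapse = ", ")))))
  }
  if (any(signals$signal < 0, na.rm = TRUE)) {
    out <- c(out, list(finding("negative_signal", "error",
                               sprintf("%d negative signal values",
                                       sum(signals$signal < 0, na.rm = TRUE)))))
  }
  if (any(is.na(signals$snr))) {
    out <- c(out, list(finding("missing_snr", "warning",
                               sprintf("%d spots without SNR", sum(is.na(signals$snr))))))
  }
  if (any(duplicated(samples$sample_id))) {
    out <- c(out, list(finding("duplicate_sample", "error", "duplicated sample_id in sheet")))
  }
  bind_rows(out)
}
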