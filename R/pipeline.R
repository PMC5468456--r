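#' Default run configuration
#'
#' Every stochastic step carries an explicit seed, and the whole
#' configuration is serialized into the output directory for provenance.
#' The three variation-partitioning groups are a repository convention
#' (climate/pH, soil chemistry, vegetation), not a claim about any
#' particular dataset; override them per run.
#'
#' @return A nested list of defaults; override entries via [run_pipeline()].
#' @export
default_config <- function() {
  list(
    synthetic = list(enabled = TRUE, true_z = 0.01, n_probes = 5000,
                     rng_seed = 1L),
    input = list(signals = NULL, samples = NULL),
    out_dir = NULL,
    stages = c("preprocess", "diversity", "edr", "overlap", "env_link", "network"),
    preprocess = list(snr_min = 2, constant_rule = "mean_total", offset = "plus1"),
    diversity = list(trend_index = "shannon"),
    edr = list(n_boot = 999, seed = 7L, d_zero = 0.01, log_base = "10",
               by_category = TRUE, category_n_boot = 99),
    env_link = list(n_perm = 999, seed = 11L, method = "bray",
                    vif_threshold = 20,
                    vpa_groups = list(
                      climate_ph = c("T", "pH"),
                      soil = c("moisture", "NO3", "NH4", "TN_10_20"),
                      vegetation = c("veg_biomass", "veg_species", "veg_diversity"))),
    network = list(category = "carbon_fixation", min_prevalence = 0.5,
                   top_n = 150, scan = c(0.5, 0.95, 0.01), min_nodes = 30,
                   env_vars = NULL)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Configuration file.
#' @return The configuration merged over [default_config()].
#' @export
read_run_config <- function(path) {
  user <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_config(), user)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in their fixed order
#' (simulate/load -> preprocess -> diversity -> EDR -> overlap -> env_link
#' -> network) under one configuration.  Stages that fail are recorded with
#' their error; stages depending on a failed stage are skipped with a logged
#' reason; independent stages continue.
#'
#' @param config A configuration list (merged over [default_config()]) or a
#'   path to a YAML/JSON configuration.
#' @return A `run_report` object; if `config$out_dir` is set, stage outputs
#'   (TSV/JSON/GraphML) and the serialized configuration are written there.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- merge_config(default_config(), config)
  report <- list(config = config, stages = list(), warnings = character())
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  note <- function(stage, value) report$stages[[stage]] <<- value
  failed <- character()
  run_stage <- function(stage, deps, expr) {
    if (!stage %in% c(config$stages, "load")) return(invisible(NULL))
    bad <- intersect(deps, failed)
    if (length(bad)) {
      note(stage, list(skipped = TRUE,
                       reason = paste("dependency failed:", paste(bad, collapse = ", "))))
      failed <<- c(failed, stage)
      return(invisible(NULL))
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, list(error = conditionMessage(res)))
      failed <<- c(failed, stage)
      return(invisible(NULL))
    }
    res
  }

  # ---- input -----------------------------------------------------------------
  sim <- NULL
  if (isTRUE(config$synthetic$enabled)) {
    design <- synthetic_design(
      n_probes = config$synthetic$n_probes,
      true_z = config$synthetic$true_z,
      rng_seed = config$synthetic$rng_seed
    )
    sim <- simulate_geochip(design)
    signals <- sim$signals; samples <- sim$samples
    note("input", list(kind = "synthetic", true_z = design$true_z,
                       n_probes = design$n_probes, seed = design$rng_seed))
  } else {
    signals <- read_probe_table(config$input$signals)
    samples <- read_sample_sheet(config$input$samples)
    note("input", list(kind = "files", signals = config$input$signals,
                       samples = config$input$samples))
  }
  findings <- validate_inputs(signals, samples)
  note("validation", findings)
  if (any(findings$severity == "error")) {
    report$stages$validation_failed <- TRUE
    class(report) <- "run_report"
    return(report)
  }

  # ---- preprocess ------------------------------------------------------------
  abund <- run_stage("preprocess", character(), {
    a <- preprocess_geochip(signals, samples,
                            snr_min = config$preprocess$snr_min,
                            constant_rule = config$preprocess$constant_rule,
                            offset = config$preprocess$offset)
    note("preprocess", list(
      n_probes = nrow(a$values), n_samples = ncol(a$values),
      detected = sum(a$detected), norm_constant = a$norm_constant,
      provenance = a$provenance))
    if (!is.null(out_dir)) write_abundance(a, file.path(out_dir, "preprocess"))
    a
  })

  # ---- diversity -------------------------------------------------------------
  run_stage("diversity", "preprocess", {
    prof <- diversity_profile(abund)
    trend <- trend_vs_elevation(prof, index = config$diversity$trend_index)
    note("diversity", list(profile = prof, trend = trend))
    if (!is.null(out_dir)) readr::write_tsv(prof, file.path(out_dir, "diversity.tsv"))
    prof
  })

  # ---- EDR -------------------------------------------------------------------
  run_stage("edr", "preprocess", {
    fit <- edr(abund, d_zero = config$edr$d_zero, log_base = config$edr$log_base,
               n_boot = config$edr$n_boot, seed = config$edr$seed)
    sens <- edr_sensitivity(abund, d_zero_grid = c(config$edr$d_zero, 0.1, 1, 10, 100))
    fam <- NULL
    if (isTRUE(config$edr$by_category)) {
      fam <- category_edr_family(abund, by = "category",
                                 d_zero = config$edr$d_zero,
                                 n_boot = config$edr$category_n_boot,
                                 seed = config$edr$seed)
    }
    note("edr", list(fit = glance(fit), sensitivity = sens, by_category = fam))
    if (!is.null(out_dir)) {
      jsonlite::write_json(list(fit = glance(fit), sensitivity = sens,
                                by_category = fam),
                           file.path(out_dir, "edr.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    fit
  })

  # ---- overlap ---------------------------------------------------------------
  run_stage("overlap", "preprocess", {
    rep_ <- classify_overlap(abund)
    svd_ <- shared_vs_distance(abund)
    note("overlap", list(summary = glance(rep_), pairs = tidy(rep_),
                         shared_vs_distance = svd_))
    if (!is.null(out_dir)) {
      readr::write_tsv(tidy(rep_), file.path(out_dir, "overlap_pairs.tsv"))
      jsonlite::write_json(list(summary = glance(rep_), shared_vs_distance = svd_),
                           file.path(out_dir, "overlap.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    rep_
  })

  # ---- environment linkage ---------------------------------------------------
  run_stage("env_link", "preprocess", {
    cfg <- config$env_link
    mant <- mantel_env(abund, method = cfg$method, n_perm = cfg$n_perm,
                       seed = cfg$seed)
    perm <- permanova_elevation(abund, method = cfg$method,
                                n_perm = cfg$n_perm, seed = cfg$seed)
    cat_ab <- category_abundance(abund)
    screen <- pearson_fdr_screen(cat_ab, abund$samples)
    cand <- unlist(cfg$vpa_groups, use.names = FALSE)
    vif <- vif_screen(abund$samples, cand, threshold = cfg$vif_threshold)
    cca <- constrained_ordination(abund, vif$retained, n_perm = min(cfg$n_perm, 199),
                                  seed = cfg$seed)
    groups <- purrr::map(cfg$vpa_groups, ~ intersect(.x, vif$retained))
    vpa <- NULL
    if (all(lengths(groups) > 0)) {
      vpa <- variation_partition(abund, groups)
    } else {
      report$warnings <<- c(report$warnings,
                            "VPA skipped: a variable group lost all members in VIF screening")
    }
    note("env_link", list(mantel = mant, permanova = perm, screen = screen,
                          vif_retained = vif$retained, vif_dropped = vif$dropped,
                          cca_explained = cca$explained, cca_p = cca$p.value,
                          vpa = if (!is.null(vpa)) vpa$components,
                          vpa_total = if (!is.null(vpa)) vpa$total_explained))
    if (!is.null(out_dir)) {
      readr::write_tsv(mant, file.path(out_dir, "mantel.tsv"))
      readr::write_tsv(screen, file.path(out_dir, "pearson_screen.tsv"))
      jsonlite::write_json(
        list(permanova = perm, vif_retained = vif$retained,
             cca_explained = cca$explained,
             vpa = if (!is.null(vpa)) vpa$components),
        file.path(out_dir, "env_link.json"), auto_unbox = TRUE, digits = NA)
    }
    mant
  })

  # ---- network ---------------------------------------------------------------
  run_stage("network", "preprocess", {
    cfg <- config$network
    scan <- if (length(cfg$scan) == 3) seq(cfg$scan[1], cfg$scan[2], by = cfg$scan[3])
            else cfg$scan
    net <- co_occurrence_network(abund, category = cfg$category,
                                 min_prevalence = cfg$min_prevalence,
                                 top_n = cfg$top_n, env_vars = cfg$env_vars,
                                 scan = scan, min_nodes = cfg$min_nodes)
    note("network", list(threshold = net$threshold, topology = net$topology))
    if (!is.null(out_dir)) {
      write_network(net, file.path(out_dir, "network"))
      jsonlite::write_json(list(threshold = net$threshold, topology = net$topology),
                           file.path(out_dir, "network", "topology.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    net
  })

  if (!is.null(out_dir)) {
    yaml::write_yaml(config, file.path(out_dir, "config_used.yaml"))
  }
  report$failed <- failed
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    status <- if (is.data.frame(st)) "ok"
              else if (is.list(st) && !is.null(st[["error"]])) paste("ERROR:", st[["error"]])
              else if (is.list(st) && isTRUE(st[["skipped"]])) paste("skipped:", st[["reason"]])
              else "ok"
    cat(sprintf("  %-12s %s\n", nm, status))
  }
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
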