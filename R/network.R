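#' Select probes for network construction
#'
#' Association networks are built on a subset of the array (category filter
#' plus prevalence/abundance floor) because the full probe set is far larger
#' than the sample count.
#'
#' @param abund A `geochip_abund` object.
#' @param category,subcategory Optional annotation filter.
#' @param min_prevalence Minimum fraction of samples in which a probe must be
#'   detected.
#' @param top_n Keep at most the `top_n` most abundant qualifying probes.
#' @return Character vector of probe ids.
#' @export
select_network_nodes <- function(abund, category = NULL, subcategory = NULL,
                                 min_prevalence = 0.5, top_n = NULL) {
  det <- restrict_probes(abund, category, subcategory)
  prev <- rowMeans(det)
  ids <- rownames(det)[prev >= min_prevalence]
  if (!length(ids)) abort("no probes pass the prevalence floor",
                          class = "geochipr_error_empty")
  if (!is.null(top_n) && length(ids) > top_n) {
    ab <- rowSums(abund$norm[ids, , drop = FALSE])
    ids <- ids[order(ab, decreasing = TRUE)][seq_len(top_n)]
  }
  ids
}

#' Absolute Spearman similarity matrix over network nodes
#'
#' Node-by-node |Spearman rho| on per-sample abundances, with environmental
#' variables optionally appended as nodes (pairwise-complete observations,
#' mid-ranked ties).  Constant nodes have undefined correlations and are
#' dropped with a warning.
#'
#' @param abund A `geochip_abund` object.
#' @param probe_ids Probe nodes (e.g. from [select_network_nodes()]).
#' @param env_vars Sample-sheet columns to append as environment nodes.
#' @return A `gene_similarity` object: the symmetric similarity matrix with a
#'   `roles` attribute (`"gene"` / `"env"`).
#' @export
spearman_similarity <- function(abund, probe_ids = NULL, env_vars = NULL) {
  if (is.null(probe_ids)) probe_ids <- rownames(abund$norm)
  X <- t(abund$norm[probe_ids, , drop = FALSE])
  roles <- rep("gene", ncol(X))
  if (!is.null(env_vars)) {
    sheet <- abund$samples
    E <- as.matrix(sheet[match(rownames(X), sheet$sample_id), env_vars, drop = FALSE])
    colnames(E) <- env_vars
    X <- cbind(X, E)
    roles <- c(roles, rep("env", length(env_vars)))
  }
  n_obs <- colSums(!is.na(X))
  if (any(n_obs < 4)) {
    abort("every node needs >= 4 non-missing observations",
          class = "geochipr_error_config")
  }
  const <- apply(X, 2, function(v) sd(v, na.rm = TRUE) == 0)
  if (any(const)) {
    warn(sprintf("dropping %d constant node(s): similarity undefined", sum(const)))
    X <- X[, !const, drop = FALSE]
    roles <- roles[!const]
  }
  S <- abs(suppressWarnings(cor(X, method = "spearman",
                                use = "pairwise.complete.obs")))
  diag(S) <- 1
  structure(S, roles = roles, class = c("gene_similarity", class(S)))
}

# ---- random-matrix-theory threshold selection -------------------------------

# Unfold a sorted eigenvalue spectrum by a smoothing-spline fit of the
# cumulative spectral density, so spacings are on a uniform mean-1 scale
# regardless of the global density shape.  The largest eigenvalues (global
# modes of a thresholded similarity matrix; Perron eigenvalues of its
# components) distort any smooth density fit, so a top fraction is trimmed
# before unfolding.
unfold_spectrum <- function(ev, df = 10, trim = 0.1) {
  ev <- sort(ev)
  n0 <- length(ev)
  if (n0 < 20) abort("too few eigenvalues to unfold", class = "geochipr_error_degenerate")
  if (diff(range(ev)) < 1e-10) {
    abort("degenerate spectrum: eigenvalues (near-)identical",
          class = "geochipr_error_degenerate")
  }
  if (trim > 0) ev <- ev[seq_len(floor(n0 * (1 - trim)))]
  n <- length(ev)
  F_emp <- (seq_len(n) - 0.5) / n
  fit <- tryCatch(smooth.spline(ev, F_emp, df = min(df, floor(n / 4))),
                  error = function(e) {
                    abort("spectrum unfolding failed (near-degenerate spectrum)",
                          class = "geochipr_error_degenerate")
                  })
  e_unf <- n * sort(predict(fit, ev)$y)
  s <- diff(e_unf)
  s <- s[s > 0]
  if (length(s) < 15) abort("too few usable spacings", class = "geochipr_error_degenerate")
  s / mean(s)
}

# Chi-squared goodness of fit of mean-1 spacings against the Poisson
# (exp(-s)) or GOE/Wigner (pi s/2 exp(-pi s^2/4)) form, on equal-probability
# bins of the null.
nnsd_gof <- function(s, form = c("poisson", "goe"), n_bins = NULL) {
  form <- arg_match(form)
  n <- length(s)
  if (is.null(n_bins)) n_bins <- max(5, min(12, floor(n / 8)))
  probs <- seq(0, 1, length.out = n_bins + 1)
  qnull <- switch(form,
                  poisson = function(p) -log(1 - p),
                  goe = function(p) sqrt(-4 * log(1 - p) / pi))
  edges <- qnull(probs)
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  obs <- table(cut(s, edges))
  expd <- rep(n / n_bins, n_bins)
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  df <- n_bins - 2   # one df for the mean normalization
  tibble(statistic = stat, df = df,
         p.value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Scan candidate thresholds for the RMT transition
#'
#' For each candidate threshold the sub-threshold similarities are zeroed,
#' connected nodes kept, the eigenvalue spectrum unfolded, and the
#' nearest-neighbour spacing distribution (NNSD) tested against the Poisson
#' and the GOE/Wigner forms.
#'
#' @param sim A [spearman_similarity()] matrix.
#' @param scan Ascending threshold grid in (0, 1).
#' @param min_nodes Minimum connected nodes for spacing statistics.
#' @return Tibble `threshold`, `n_nodes`, `n_edges`, `p_poisson`, `p_goe`.
#' @export
rmt_scan <- function(sim, scan = seq(0.5, 0.95, by = 0.01), min_nodes = 30) {
  stopifnot(is.matrix(sim))
  purrr::map_dfr(scan, function(t) {
    A <- sim * (sim >= t)
    diag(A) <- 0
    keep <- rowSums(A > 0) > 0
    res <- tibble(threshold = t, n_nodes = sum(keep),
                  n_edges = sum(A[keep, keep, drop = FALSE] > 0) / 2,
                  p_poisson = NA_real_, p_goe = NA_real_)
    if (sum(keep) < min_nodes) return(res)
    M <- A[keep, keep, drop = FALSE]
    diag(M) <- 1
    s <- tryCatch(unfold_spectrum(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
                  error = function(e) NULL)
    if (is.null(s)) return(res)
    res$p_poisson <- nnsd_gof(s, "poisson")$p.value
    res$p_goe <- nnsd_gof(s, "goe")$p.value
    res
  })
}

#' Choose the network threshold by the RMT transition criterion
#'
#' The chosen threshold is the smallest scanned value at which the NNSD of
#' the thresholded similarity matrix stops differing from the Poisson form
#' (chi-squared goodness of fit not rejecting Poisson at `alpha`) while
#' still rejecting the GOE/Wigner form.
#'
#' @inheritParams rmt_scan
#' @param alpha Test level for both goodness-of-fit decisions.
#' @param require_goe_rejection Also require the GOE form to be rejected at
#'   the chosen threshold.
#' @param persistence The Poisson criterion must hold at this many
#'   consecutive grid points (guards against isolated goodness-of-fit
#'   flukes; default 2).
#' @return The chosen threshold (numeric scalar) with the scan trace attached
#'   as attribute `"scan"`.  Errors (class `geochipr_error_no_transition`)
#'   with the trace in the condition if no scanned threshold qualifies.
#' @export
rmt_threshold <- function(sim, scan = seq(0.5, 0.95, by = 0.01), alpha = 0.05,
                          min_nodes = 30, require_goe_rejection = TRUE,
                          persistence = 2) {
  trace <- rmt_scan(sim, scan = scan, min_nodes = min_nodes)
  ok <- !is.na(trace$p_poisson) & trace$p_poisson > alpha
  if (require_goe_rejection) ok <- ok & !is.na(trace$p_goe) & trace$p_goe < alpha
  run_ok <- ok
  if (persistence > 1) {
    for (k in seq_len(persistence - 1)) {
      run_ok <- run_ok & c(ok[-seq_len(k)], rep(TRUE, k))
    }
  }
  if (!any(run_ok)) {
    abort("no RMT transition found on the scanned grid",
          class = "geochipr_error_no_transition", scan = trace)
  }
  chosen <- min(trace$threshold[run_ok])
  attr(chosen, "scan") <- trace
  chosen
}

#' Build the association network at a threshold
#'
#' @param sim A [spearman_similarity()] matrix.
#' @param threshold Similarity cutoff; node pairs at or above it are linked.
#' @param keep_isolated Keep nodes without any edge (default drops them).
#' @return A `gene_network`: igraph graph (vertex attribute `role`, edge
#'   attribute `similarity`), plus the threshold.
#' @export
build_network <- function(sim, threshold, keep_isolated = FALSE) {
  A <- (sim >= threshold) * sim
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$role <- attr(sim, "roles") %||% rep("gene", nrow(A))
  igraph::E(g)$similarity <- igraph::E(g)$weight
  if (!keep_isolated) g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  structure(list(graph = g, threshold = threshold), class = "gene_network")
}

#' Topology diagnostics of an association network
#'
#' The four indices reported for molecular ecological networks: the power-law
#' fit of the degree distribution (OLS of log frequency on log degree;
#' exponent and R^2), the average shortest-path distance on the largest
#' connected component, the modularity of the greedy agglomerative partition,
#' and the average local clustering coefficient.
#'
#' @param net A `gene_network` (or igraph graph).
#' @return One-row tibble of the metrics plus component coverage.
#' @export
topology_stats <- function(net) {
  g <- if (inherits(net, "gene_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n < 3 || igraph::ecount(g) < 2) {
    abort("need >= 3 nodes and >= 2 edges", class = "geochipr_error_config")
  }
  deg <- igraph::degree(g)
  pl <- fit_power_law_ols(deg[deg > 0], log_bin = n > 200)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, comp$membership == big)
  apd <- igraph::mean_distance(sub, directed = FALSE)
  fg <- igraph::cluster_fast_greedy(igraph::simplify(g))
  tibble(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    power_law_exponent = pl$exponent,
    power_law_r2 = pl$r2,
    avg_path_distance = apd,
    component_coverage = max(comp$csize) / n,
    modularity = igraph::modularity(fg),
    n_modules = length(unique(igraph::membership(fg))),
    avg_clustering = igraph::transitivity(g, type = "localaverage", isolates = "zero")
  )
}

# OLS power-law fit of a degree sample: log10(frequency) on log10(degree),
# with logarithmic degree bins for large graphs.
fit_power_law_ols <- function(deg, log_bin = FALSE) {
  if (log_bin) {
    edges <- unique(round(2^seq(0, ceiling(log2(max(deg))) + 1, by = 0.5)))
    bin <- cut(deg, c(edges - 0.5, Inf), labels = FALSE)
    tab <- tapply(deg, bin, length)
    width <- diff(c(edges, 2 * max(edges)))[as.integer(names(tab))]
    k <- tapply(deg, bin, mean)
    freq <- as.numeric(tab) / width
  } else {
    tab <- table(deg)
    k <- as.numeric(names(tab))
    freq <- as.numeric(tab)
  }
  ok <- freq > 0 & k > 0
  if (sum(ok) < 3) return(list(exponent = NA_real_, r2 = NA_real_))
  x <- log10(k[ok]); y <- log10(freq[ok])
  fit <- lm(y ~ x)
  list(exponent = -unname(coef(fit)[2]), r2 = summary(fit)$r.squared)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> threshold %.2f: %d nodes, %d edges\n",
              x$threshold, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Build a co-occurrence network end to end
#'
#' Node selection, Spearman similarity, RMT threshold choice, network
#' construction and topology in one call.
#'
#' @inheritParams select_network_nodes
#' @inheritParams spearman_similarity
#' @inheritParams rmt_threshold
#' @return A `gene_network` with `topology` and `scan` entries added.
#' @export
co_occurrence_network <- function(abund, category = NULL, subcategory = NULL,
                                  min_prevalence = 0.5, top_n = 300,
                                  env_vars = NULL,
                                  scan = seq(0.5, 0.95, by = 0.01),
                                  alpha = 0.05, min_nodes = 30) {
  ids <- select_network_nodes(abund, category = category, subcategory = subcategory,
                              min_prevalence = min_prevalence, top_n = top_n)
  sim <- spearman_similarity(abund, ids, env_vars = env_vars)
  thr <- rmt_threshold(sim, scan = scan, alpha = alpha, min_nodes = min_nodes)
  net <- build_network(sim, thr)
  net$topology <- topology_stats(net)
  net$scan <- attr(thr, "scan")
  net
}

#' Write a network as an edge list and GraphML
#'
#' @param net A `gene_network`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  el <- igraph::as_data_frame(net$graph, what = "edges")
  paths <- c(edges = file.path(dir, "network_edges.tsv"),
             graphml = file.path(dir, "network.graphml"))
  readr::write_tsv(as_tibble(el), paths[["edges"]])
  igraph::write_graph(net$graph, paths[["graphml"]], format = "graphml")
  invisible(paths)
}
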