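# Shared fixture builders; everything is generated in code at test time.

# A small long-format probe table from explicit signal/snr matrices.
make_probe_table <- function(signal, snr, sample_ids = colnames(signal),
                             probe_ids = rownames(signal)) {
  if (is.null(probe_ids)) probe_ids <- sprintf("p%02d", seq_len(nrow(signal)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(ncol(signal)))
  out <- tibble::tibble(
    probe_id = rep(probe_ids, times = ncol(signal)),
    gene = "genX", category = "catA", subcategory = "subA", organism = "orgA",
    sample_id = rep(sample_ids, each = nrow(signal)),
    signal = as.vector(signal),
    snr = as.vector(snr)
  )
  attr(out, "geochip_stage") <- "raw"
  out
}

make_sheet <- function(elevations, n_replicates) {
  grid <- expand.grid(replicate = seq_len(n_replicates), elevation = elevations)
  tibble::tibble(
    sample_id = sprintf("E%d_R%d", grid$elevation, grid$replicate),
    elevation = grid$elevation,
    replicate = grid$replicate
  )
}

# A minimal geochip_abund built directly from matrices (no preprocessing),
# for modules that only consume the container.
make_abund <- function(norm, detected = norm > 0, sheet = NULL,
                       annotation = NULL, values = log1p(norm)) {
  if (is.null(rownames(norm))) rownames(norm) <- sprintf("p%03d", seq_len(nrow(norm)))
  if (is.null(colnames(norm))) colnames(norm) <- sprintf("s%03d", seq_len(ncol(norm)))
  dimnames(values) <- dimnames(detected) <- dimnames(norm)
  if (is.null(annotation)) {
    annotation <- tibble::tibble(probe_id = rownames(norm), gene = "genX",
                                 category = "catA", subcategory = "subA",
                                 organism = "orgA")
  }
  structure(list(values = values, norm = norm, detected = detected,
                 annotation = annotation, samples = sheet,
                 log_offset = "plus1", norm_constant = 1,
                 provenance = list()),
            class = "geochip_abund")
}

# Brute-force detection oracle: (snr >= threshold) AND (>= 2 detected
# replicates in the elevation group), written as plain loops.
detect_bruteforce <- function(table, sheet, threshold = 2) {
  probes <- unique(table$probe_id)
  samples <- sheet$sample_id
  det <- matrix(FALSE, length(probes), length(samples),
                dimnames = list(probes, samples))
  pass <- matrix(FALSE, length(probes), length(samples),
                 dimnames = list(probes, samples))
  for (i in seq_len(nrow(table))) {
    pass[table$probe_id[i], table$sample_id[i]] <- table$snr[i] >= threshold
  }
  for (p in probes) {
    for (e in unique(sheet$elevation)) {
      grp <- sheet$sample_id[sheet$elevation == e]
      k <- sum(pass[p, grp])
      for (s in grp) det[p, s] <- pass[p, s] && k >= 2
    }
  }
  det
}

# Modular similarity matrix: many small blocks of high similarity over a
# low-similarity background; the RMT transition should sit strictly between
# the two bands.
make_modular_similarity <- function(seed, n_blocks = 30, size_range = 3:8,
                                    noise = c(0.1, 0.4), block = c(0.75, 0.98)) {
  set.seed(seed)
  sizes <- sample(size_range, n_blocks, replace = TRUE)
  blk <- rep(seq_along(sizes), sizes)
  n <- length(blk)
  S <- matrix(runif(n * n, noise[1], noise[2]), n, n)
  win <- outer(blk, blk, "==")
  S[win] <- runif(sum(win), block[1], block[2])
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  diag(S) <- 1
  dimnames(S) <- list(paste0("n", 1:n), paste0("n", 1:n))
  S
}

# Null pair table: the 12-sample transect pair design with log-similarities
# carrying iid noise and no distance dependence.
make_null_pairs <- function(seed, sd_log10 = 0.015) {
  elev <- rep(c(3200, 3400, 3600, 3800), each = 3)
  idx <- t(utils::combn(12, 2))
  D <- abs(elev[idx[, 1]] - elev[idx[, 2]])
  set.seed(seed)
  tibble::tibble(
    raw_distance = D,
    substituted = D == 0,
    distance = ifelse(D == 0, 0.01, D),
    sorensen = 10^(log10(0.8) + stats::rnorm(length(D), 0, sd_log10))
  )
}

# Explicit normal-equations OLS oracle for the log-log decay fit.
edr_normal_equations <- function(D, S) {
  x <- log10(D); y <- log10(S)
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept, z = -slope / 2)
}

# All 24 permutations of 1:4 (for exact Mantel enumeration).
gtools_permutations_4 <- function() {
  out <- matrix(0L, 0, 4)
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    out <- rbind(out, c(a, b, cc, setdiff(1:4, c(a, b, cc))))
  }
  out
}

# Step-up BH oracle, written from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in rev(seq_len(m))) {
    i <- ord[k]
    prev <- min(prev, p[i] * m / k)
    adj[i] <- prev
  }
  adj
}
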