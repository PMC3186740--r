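#' Mixture weights for the tissue-breadth distribution
#'
#' The synthetic ground truth draws each gene's expression breadth from a
#' three-component mixture: universally expressed genes (expressed in every
#' tissue of the panel), tissue-specific genes (expressed in exactly one
#' tissue), and intermediate genes (expressed in between 2 and N-1 tissues,
#' breadth uniform over that range).
#'
#' @param universal,specific,intermediate Non-negative mixture weights; must
#'   sum to 1 within 1e-9.
#' @return A `breadth_params` list.
#' @export
breadth_params <- function(universal = 0.4, specific = 0.2, intermediate = 0.4) {
  w <- c(universal = universal, specific = specific, intermediate = intermediate)
  if (any(!is.finite(w)) || any(w < 0))
    stop_tc("breadth mixture weights must be finite and non-negative")
  if (abs(sum(w) - 1) > 1e-9)
    stop_tc("breadth mixture weights must sum to 1 (got %.12g)", sum(w))
  structure(as.list(w), class = "breadth_params")
}

#' Generate a binary gene x tissue expression ground truth
#'
#' Each gene is assigned a breadth class from the mixture in `breadth`
#' (see [breadth_params()]) and then a set of expressing tissues:
#' universal genes get all tissues, tissue-specific genes one uniformly
#' chosen tissue, intermediate genes a uniformly chosen breadth in
#' \[2, N-1\] and a uniform subset of that size.
#'
#' @param n_genes Number of genes (>= 1). Gene identifiers are g000001, ...
#' @param tissues Character vector of >= 2 unique tissue names.
#' @param breadth A [breadth_params()] object.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An object of class `ground_truth`: list with `truth` (0/1 integer
#'   matrix, genes x tissues), `genes`, `tissues`, `class` (per-gene planted
#'   class) and `breadth` (the mixture used).
#' @examples
#' gt <- generate_ground_truth(100, c("heart", "liver", "testis"),
#'                             breadth_params(0.5, 0.5, 0), seed = 1)
#' table(rowSums(gt$truth))
#' @export
generate_ground_truth <- function(n_genes, tissues, breadth = breadth_params(),
                                  seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", 1)
  if (!is.character(tissues) || length(tissues) < 2L || anyDuplicated(tissues))
    stop_tc("'tissues' must be >= 2 unique tissue names")
  if (!inherits(breadth, "breadth_params")) breadth <- do.call(breadth_params, as.list(breadth))
  n_tissues <- length(tissues)
  if (breadth$intermediate > 0 && n_tissues < 4L)
    stop_tc("intermediate breadth (2..N-1) needs >= 4 tissues when its weight is positive; got %d",
            n_tissues)
  n_genes <- as.integer(n_genes)
  genes <- sprintf("g%06d", seq_len(n_genes))

  with_seed(seed, {
    cls <- sample(c("universal", "specific", "intermediate"), n_genes,
                  replace = TRUE,
                  prob = c(breadth$universal, breadth$specific, breadth$intermediate))
    truth <- matrix(0L, n_genes, n_tissues, dimnames = list(genes, tissues))
    truth[cls == "universal", ] <- 1L
    idx_spec <- which(cls == "specific")
    if (length(idx_spec)) {
      cols <- sample.int(n_tissues, length(idx_spec), replace = TRUE)
      truth[cbind(idx_spec, cols)] <- 1L
    }
    for (i in which(cls == "intermediate")) {
      k <- sample(2:(n_tissues - 1L), 1L)
      truth[i, sample.int(n_tissues, k)] <- 1L
    }
  })

  structure(list(truth = truth, genes = genes, tissues = tissues,
                 class = stats::setNames(cls, genes), breadth = breadth),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d genes x %d tissues\n",
              nrow(x$truth), ncol(x$truth)))
  print(table(planted_class = x$class))
  invisible(x)
}

# Draw probeset counts per gene from the platform's weight vector.
draw_probeset_counts <- function(n_genes, weights) {
  sample.int(length(weights), n_genes, replace = TRUE, prob = weights)
}

#' Simulate probeset-level P/M/A call tables
#'
#' Emulates MAS5.0-style microarray output: each gene receives one or more
#' probesets (count drawn from the platform's `probesets_per_gene` weights),
#' and each probeset x tissue x replicate slot is detected with probability
#' `sensitivity` when the gene is truly expressed in that tissue and with
#' probability `false_positive_rate` otherwise. Detected slots are emitted
#' as "P", except that a fraction `m_fraction` of them are downgraded to
#' marginal ("M") calls; undetected slots are "A". Downstream call
#' derivation treats M as present, so the downgrade exercises that rule
#' without changing detection rates.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param platform A [platform_model()] with kind `"pma_calls"`.
#' @param seed Integer seed.
#' @return List with `calls` (data.frame: probeset_id, tissue, replicate,
#'   call in P/M/A) and `mapping` (data.frame: probeset_id, gene_id).
#' @export
simulate_pma_calls <- function(truth, platform, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  check_kind(platform, "pma_calls")
  with_seed(seed, {
    n_ps_per_gene <- draw_probeset_counts(length(truth$genes),
                                          platform$probesets_per_gene)
    gene_of <- rep(truth$genes, n_ps_per_gene)
    probesets <- sprintf("ps%07d", seq_along(gene_of))
    mapping <- data.frame(probeset_id = probesets, gene_id = gene_of,
                          stringsAsFactors = FALSE)

    n_rep <- platform$n_replicates
    grid <- expand.grid(probeset_id = probesets, tissue = truth$tissues,
                        replicate = seq_len(n_rep),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    expressed <- truth$truth[cbind(match(gene_of[match(grid$probeset_id, probesets)],
                                         truth$genes),
                                   match(grid$tissue, truth$tissues))] == 1L
    p_detect <- ifelse(expressed, platform$sensitivity, platform$false_positive_rate)
    detected <- stats::runif(nrow(grid)) < p_detect
    call <- ifelse(detected, "P", "A")
    if (platform$m_fraction > 0) {
      down <- detected & stats::runif(nrow(grid)) < platform$m_fraction
      call[down] <- "M"
    }
    grid$call <- call
  })
  list(calls = grid, mapping = mapping)
}

# P(median of n replicate p-values < threshold) when each replicate is
# independently "detected" (p ~ U(0, t)) with probability q, else U(t, 1):
# for odd n this is P(Binom(n, q) >= (n+1)/2). Solve for q given a target
# post-median rate; exact for odd n, used as-is for even n (the mixed
# central-pair case has small probability mass and is documented).
median_rate <- function(q, n) {
  k <- floor(n / 2) + 1L
  stats::pbinom(k - 1L, n, q, lower.tail = FALSE)
}

calibrate_replicate_rate <- function(target, n) {
  if (target <= 0) return(0)
  if (target >= 1) return(1)
  stats::uniroot(function(q) median_rate(q, n) - target,
                 interval = c(0, 1), tol = 1e-12)$root
}

#' Simulate gene-level detection p-values
#'
#' Emulates DABG (detection above background) output for exon arrays: per
#' gene x tissue x replicate, a p-value below the call threshold (default
#' 0.05, uniform on \[0, t)) with a per-replicate probability calibrated so
#' that the rate of present calls after taking the replicate median equals
#' the platform's planted `sensitivity` (for truly expressed genes) or
#' `false_positive_rate` (otherwise); undetected replicates draw p uniform
#' on \[t, 1\]. The calibration is exact for odd replicate counts (the
#' default is 3).
#'
#' @param truth A [generate_ground_truth()] object.
#' @param platform A [platform_model()] with kind `"detection_pvalues"`.
#' @param seed Integer seed.
#' @param threshold The downstream call threshold the calibration targets
#'   (default 0.05).
#' @return data.frame with columns gene_id, tissue, replicate, pvalue.
#' @export
simulate_detection_pvalues <- function(truth, platform, seed = 1L,
                                       threshold = 0.05) {
  stopifnot(inherits(truth, "ground_truth"))
  check_kind(platform, "detection_pvalues")
  assert_scalar_number(threshold, "threshold", 1e-12, 1 - 1e-12)
  n_rep <- platform$n_replicates
  q_s <- calibrate_replicate_rate(platform$sensitivity, n_rep)
  q_f <- calibrate_replicate_rate(platform$false_positive_rate, n_rep)
  with_seed(seed, {
    grid <- expand.grid(gene_id = truth$genes, tissue = truth$tissues,
                        replicate = seq_len(n_rep),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    expressed <- truth$truth[cbind(match(grid$gene_id, truth$genes),
                                   match(grid$tissue, truth$tissues))] == 1L
    q <- ifelse(expressed, q_s, q_f)
    detected <- stats::runif(nrow(grid)) < q
    u <- stats::runif(nrow(grid))
    grid$pvalue <- ifelse(detected, u * threshold, threshold + u * (1 - threshold))
  })
  grid
}

# Lognormal location such that P(RPKM >= threshold) = rate, given sdlog.
# Boundary rates use half-normal constructions so 0/1 are exact.
rpkm_draw <- function(n, rate, sdlog, threshold) {
  if (n == 0L) return(numeric(0))
  if (rate <= 0) return(threshold * exp(-(abs(stats::rnorm(n)) + 1e-9) * sdlog))
  if (rate >= 1) return(threshold * exp(abs(stats::rnorm(n)) * sdlog))
  meanlog <- log(threshold) + sdlog * stats::qnorm(rate)
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Simulate an RPKM expression matrix
#'
#' Emulates RNA-seq expression estimates: expressed gene x sample cells draw
#' RPKM from a lognormal whose log-scale location is set so that
#' P(RPKM >= threshold) equals the platform `sensitivity`; unexpressed cells
#' use the `false_positive_rate` the same way. Tissues may contribute more
#' than one sample; sample columns are named `tissue.index` so downstream
#' per-tissue averaging (as done for cerebellum-style multi-sample tissues)
#' needs no sidecar annotation.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param platform A [platform_model()] with kind `"rpkm"`.
#' @param samples_per_tissue Named integer vector (tissue -> sample count),
#'   or a single count recycled to all tissues. Default 1.
#' @param seed Integer seed.
#' @param threshold The downstream RPKM call threshold the locations are
#'   calibrated against (default 1).
#' @return Numeric matrix, genes x samples, column names `tissue.index`.
#' @export
simulate_rpkm <- function(truth, platform, samples_per_tissue = 1L, seed = 1L,
                          threshold = 1.0) {
  stopifnot(inherits(truth, "ground_truth"))
  check_kind(platform, "rpkm")
  assert_scalar_number(threshold, "threshold", lo = 1e-12)
  if (length(samples_per_tissue) == 1L && is.null(names(samples_per_tissue)))
    samples_per_tissue <- stats::setNames(rep(as.integer(samples_per_tissue),
                                              length(truth$tissues)), truth$tissues)
  if (!all(truth$tissues %in% names(samples_per_tissue)))
    stop_tc("samples_per_tissue must name every tissue")
  samples_per_tissue <- samples_per_tissue[truth$tissues]
  if (any(samples_per_tissue < 1)) stop_tc("each tissue needs >= 1 sample")

  cols <- unlist(lapply(truth$tissues, function(t)
    paste(t, seq_len(samples_per_tissue[[t]]), sep = ".")))
  col_tissue <- rep(truth$tissues, samples_per_tissue)
  n_genes <- length(truth$genes)
  with_seed(seed, {
    mat <- matrix(0, n_genes, length(cols), dimnames = list(truth$genes, cols))
    for (j in seq_along(cols)) {
      expressed <- truth$truth[, col_tissue[j]] == 1L
      mat[expressed, j] <- rpkm_draw(sum(expressed), platform$sensitivity,
                                     platform$rpkm_sdlog, threshold)
      mat[!expressed, j] <- rpkm_draw(sum(!expressed), platform$false_positive_rate,
                                      platform$rpkm_sdlog, threshold)
    }
  })
  mat
}

#' Generate a random protein-interaction network
#'
#' Draws `n_edges` distinct unordered gene pairs uniformly without
#' replacement (a simple undirected graph: no self-loops, no duplicate
#' edges).
#'
#' @param genes Character vector of gene identifiers.
#' @param n_edges Number of edges; must not exceed choose(n_genes, 2).
#' @param seed Integer seed.
#' @return An [interaction_network()] object.
#' @export
generate_network <- function(genes, n_edges, seed = 1L) {
  n <- length(genes)
  assert_scalar_number(n_edges, "n_edges", 0)
  n_pairs <- n * (n - 1) / 2
  if (n_edges > n_pairs)
    stop_tc("n_edges = %d exceeds the %d possible pairs of %d genes",
            n_edges, n_pairs, n)
  if (n_edges == 0)
    return(interaction_network(data.frame(gene_a = character(0),
                                          gene_b = character(0))))
  with_seed(seed, {
    idx <- sample(n_pairs, n_edges)          # unranked pair indices
    # unrank: pairs grouped by first element i, block sizes (n-1), (n-2), ...
    ends <- cumsum((n - 1):1)
    i <- findInterval(idx - 1, ends) + 1L
    j <- i + (idx - c(0, ends)[i])
  })
  interaction_network(data.frame(gene_a = genes[i], gene_b = genes[j],
                                 stringsAsFactors = FALSE))
}

#' Generate random protein complexes
#'
#' Each complex is a set of distinct member genes with size drawn from
#' `size_probs` (weights over sizes 3, 4, 5, ...). Optionally a fraction of
#' complexes duplicate an earlier complex's member set under a new name, to
#' exercise downstream deduplication.
#'
#' @param genes Character vector of gene identifiers.
#' @param n_complexes Number of complexes to generate.
#' @param size_probs Numeric weights; element i is the weight of size i + 2
#'   (sizes start at 3, the minimum meaningful complex size).
#' @param duplicate_rate Probability that a complex (after the first) copies
#'   a previously generated member set.
#' @param seed Integer seed.
#' @return A [complex_set()] object (duplicates retained; see
#'   [filter_complexes()] for deduplication).
#' @export
generate_complexes <- function(genes, n_complexes, size_probs = c(0.5, 0.3, 0.2),
                               duplicate_rate = 0, seed = 1L) {
  assert_scalar_number(n_complexes, "n_complexes", 0)
  assert_scalar_number(duplicate_rate, "duplicate_rate", 0, 1)
  if (!is.numeric(size_probs) || any(size_probs < 0) || sum(size_probs) <= 0)
    stop_tc("'size_probs' must be non-negative weights over sizes 3, 4, ...")
  sizes <- seq_along(size_probs) + 2L
  if (max(sizes[size_probs > 0]) > length(genes))
    stop_tc("largest complex size exceeds the number of genes")
  members <- vector("list", n_complexes)
  if (n_complexes > 0) with_seed(seed, {
    for (k in seq_len(n_complexes)) {
      if (k > 1 && stats::runif(1) < duplicate_rate) {
        members[[k]] <- members[[sample.int(k - 1L, 1L)]]
      } else {
        sz <- sizes[sample.int(length(sizes), 1L, prob = size_probs)]
        members[[k]] <- sort(sample(genes, sz))
      }
    }
  })
  names(members) <- sprintf("cx%05d", seq_len(n_complexes))
  complex_set(members)
}

#' Simulate a complete three-platform study from one seed
#'
#' Convenience wrapper tying the generators together: one ground truth, one
#' observation set per supplied platform, a random interaction network and a
#' random complex set. All randomness derives from the single `seed` via a
#' fixed per-stage stream-splitting scheme, so each stage is independently
#' reproducible.
#'
#' @param n_genes,tissues,breadth Passed to [generate_ground_truth()].
#' @param platforms List of [platform_model()] objects.
#' @param n_edges,n_complexes Sizes of the random network and complex set.
#' @param samples_per_tissue Passed to [simulate_rpkm()] for RPKM platforms.
#' @param duplicate_rate Passed to [generate_complexes()].
#' @param seed Single integer master seed.
#' @return List with `truth`, `observations` (named per platform; each the
#'   simulator output for that platform's kind), `network`, `complexes`.
#' @export
simulate_study <- function(n_genes = 1000, tissues = c("heart", "liver", "testis",
                                                       "muscle", "cerebellum"),
                           breadth = breadth_params(),
                           platforms = default_platforms(),
                           n_edges = 2000, n_complexes = 300,
                           samples_per_tissue = 1L, duplicate_rate = 0,
                           seed = 1L) {
  truth <- generate_ground_truth(n_genes, tissues, breadth,
                                 seed = split_seed(seed, "truth"))
  obs <- lapply(platforms, function(p) {
    s <- split_seed(seed, paste0("platform:", p$name))
    switch(p$kind,
           pma_calls = simulate_pma_calls(truth, p, seed = s),
           detection_pvalues = simulate_detection_pvalues(truth, p, seed = s),
           rpkm = simulate_rpkm(truth, p, samples_per_tissue, seed = s))
  })
  names(obs) <- vapply(platforms, `[[`, "", "name")
  list(truth = truth,
       observations = obs,
       network = generate_network(truth$genes, n_edges,
                                  seed = split_seed(seed, "network")),
       complexes = generate_complexes(truth$genes, n_complexes,
                                      duplicate_rate = duplicate_rate,
                                      seed = split_seed(seed, "complexes")))
}

#' Default three-platform panel
#'
#' One platform per observation kind, with detection characteristics chosen
#' to mirror the qualitative ordering seen across technologies: a
#' low-sensitivity two-replicate P/M/A microarray, a mid-sensitivity
#' three-replicate exon-array p-value platform, and a high-sensitivity
#' single-sample RPKM platform.
#'
#' @return List of three [platform_model()] objects.
#' @export
default_platforms <- function() {
  list(
    platform_model("gene_atlas", "pma_calls",
                   sensitivity = 0.5, false_positive_rate = 0.02),
    platform_model("exon_array", "detection_pvalues",
                   sensitivity = 0.85, false_positive_rate = 0.05),
    platform_model("rna_seq", "rpkm",
                   sensitivity = 0.95, false_positive_rate = 0.03)
  )
}
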