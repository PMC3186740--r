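#' Tissue breadth per gene
#'
#' A gene's breadth is the number of tissues with a present call. Breadth
#' induces four classes that partition the gene universe: `absent`
#' (breadth 0), `tissue_specific` (exactly one tissue of the analyzed
#' panel; the tissue is recorded), `intermediate` (2..N-1) and `universal`
#' (all N tissues of the panel). The panel is whatever tissues the call
#' matrix holds — specificity is always relative to the analyzed panel.
#'
#' @param m A [call_matrix()].
#' @return Object of class `breadth_table`: data.frame with columns
#'   gene_id, breadth, class, tissue (the unique tissue for
#'   tissue-specific genes, NA otherwise); attributes `platform` and
#'   `n_tissues`.
#' @export
gene_breadth <- function(m) {
  stopifnot(inherits(m, "call_matrix"))
  if (nrow(m) == 0L) stop_tc("empty call matrix")
  n_tissues <- ncol(m)
  b <- rowSums(m)
  cls <- ifelse(b == 0L, "absent",
         ifelse(b == 1L, "tissue_specific",
         ifelse(b == n_tissues, "universal", "intermediate")))
  spec_tissue <- rep(NA_character_, nrow(m))
  idx <- which(b == 1L)
  if (length(idx))
    spec_tissue[idx] <- colnames(m)[max.col(m[idx, , drop = FALSE])]
  out <- data.frame(gene_id = rownames(m), breadth = as.integer(b),
                    class = cls, tissue = spec_tissue,
                    stringsAsFactors = FALSE)
  structure(out, platform = call_platform(m), n_tissues = n_tissues,
            class = c("breadth_table", "data.frame"))
}

#' Breadth distribution across platforms
#'
#' Tabulates, per platform, how many genes are called expressed in
#' 0, 1, ..., N tissues, with fractions of the shared universe — the
#' side-by-side view used to compare how broadly each technology sees
#' genes expressed.
#'
#' @param tables List of [gene_breadth()] tables over the same gene
#'   universe.
#' @param n_genes_shared Size of the shared universe; defaults to the
#'   number of rows of the first table, and every table must match it.
#' @return data.frame with columns platform, breadth (0..N), count,
#'   fraction; per platform the counts sum to `n_genes_shared` and the
#'   fractions to 1.
#' @export
breadth_distribution <- function(tables, n_genes_shared = NULL) {
  if (inherits(tables, "breadth_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  genes <- sort(tables[[1]]$gene_id)
  n_genes_shared <- n_genes_shared %||% length(genes)
  n_tissues <- attr(tables[[1]], "n_tissues")
  out <- lapply(tables, function(tb) {
    if (!inherits(tb, "breadth_table")) stop_tc("inputs must be breadth_table objects")
    if (!identical(sort(tb$gene_id), genes) || nrow(tb) != n_genes_shared)
      stop_tc("breadth tables must cover the same shared gene universe")
    if (!identical(attr(tb, "n_tissues"), n_tissues))
      stop_tc("breadth tables must share the tissue panel size")
    counts <- tabulate(tb$breadth + 1L, nbins = n_tissues + 1L)
    data.frame(platform = attr(tb, "platform"), breadth = 0:n_tissues,
               count = counts, fraction = counts / n_genes_shared,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Breadth-class misassignment caused by limited sensitivity
#'
#' On synthetic data with known ground truth, quantifies the bias a
#' low-sensitivity platform introduces: truly universal genes that missed
#' calls demote to intermediate, tissue-specific or absent classes. For a
#' truly universal gene over N tissues observed at per-tissue sensitivity
#' s (false positives negligible), the chance of being reported
#' tissue-specific is N * s * (1-s)^(N-1).
#'
#' @param truth A [generate_ground_truth()] object.
#' @param tables List of [gene_breadth()] tables (one per platform) over
#'   genes contained in the truth.
#' @return data.frame with one row per platform and observed class:
#'   platform, class, count, rate (fraction of truly universal genes
#'   assigned that class).
#' @export
specificity_vs_sensitivity_report <- function(truth, tables) {
  stopifnot(inherits(truth, "ground_truth"))
  if (inherits(tables, "breadth_table")) tables <- list(tables)
  n_tissues <- length(truth$tissues)
  truly_universal <- truth$genes[rowSums(truth$truth) == n_tissues]
  classes <- c("universal", "intermediate", "tissue_specific", "absent")
  out <- lapply(tables, function(tb) {
    if (!all(tb$gene_id %in% truth$genes))
      stop_tc("breadth table contains genes unknown to the ground truth")
    d <- tb[tb$gene_id %in% truly_universal, , drop = FALSE]
    if (nrow(d) == 0L)
      stop_tc("no truly universal genes in breadth table for platform '%s'",
              attr(tb, "platform"))
    counts <- vapply(classes, function(cl) sum(d$class == cl), 0L)
    data.frame(platform = attr(tb, "platform"), class = classes,
               count = counts, rate = counts / nrow(d),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
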