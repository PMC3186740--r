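#' Detection-call thresholds
#'
#' @param dabg_p Detection p-value threshold for the median-of-replicates
#'   rule; present iff median p is strictly below it. The strict inequality
#'   at the boundary follows the usual detection-p convention and is
#'   configurable via `dabg_strict`.
#' @param rpkm RPKM threshold; present iff the per-tissue mean RPKM is
#'   greater than or equal to it (inclusive).
#' @param dabg_strict Logical; `TRUE` (default) uses `median p < dabg_p`,
#'   `FALSE` uses `<=`.
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(dabg_p = 0.05, rpkm = 1.0, dabg_strict = TRUE) {
  assert_scalar_number(dabg_p, "dabg_p", 1e-12, 1 - 1e-12)
  assert_scalar_number(rpkm, "rpkm", lo = 1e-12)
  structure(list(dabg_p = dabg_p, rpkm = rpkm, dabg_strict = isTRUE(dabg_strict)),
            class = "call_thresholds")
}

#' Gene-level calls from probeset P/M/A tables
#'
#' Aggregates probeset-level Present/Marginal/Absent calls to binary
#' gene x tissue calls: marginal (M) calls are treated as present; a
#' probeset is present in a tissue if at least one replicate is P or M; a
#' gene is present if at least one of its mapped probesets is present.
#' Probesets absent from the mapping are dropped (with a logged count), and
#' genes with no measured probeset are excluded from the output rather than
#' called absent — "not on the array" is not the same as "absent".
#'
#' @param probeset_calls data.frame with columns probeset_id, tissue,
#'   replicate, call (values P/M/A).
#' @param mapping data.frame with columns probeset_id, gene_id; may be
#'   many-to-many (a probeset mapped to several genes contributes its calls
#'   to each of them).
#' @param platform Platform name stamped on the result.
#' @return A [call_matrix()].
#' @export
pma_gene_calls <- function(probeset_calls, mapping, platform = "pma") {
  req <- c("probeset_id", "tissue", "replicate", "call")
  if (!is.data.frame(probeset_calls) || !all(req %in% names(probeset_calls)))
    stop_tc("probeset_calls needs columns %s", paste(req, collapse = ", "))
  if (!is.data.frame(mapping) || !all(c("probeset_id", "gene_id") %in% names(mapping)))
    stop_tc("mapping needs columns probeset_id, gene_id")
  if (nrow(mapping) == 0L) stop_tc("empty probeset-to-gene mapping")
  bad <- setdiff(unique(probeset_calls$call), c("P", "M", "A"))
  if (length(bad)) stop_tc("unknown call symbol(s): %s", paste(bad, collapse = ", "))

  tissues <- sort(unique(as.character(probeset_calls$tissue)))
  if (length(tissues) == 0L) stop_tc("no tissues in probeset call table")

  measured_ps <- unique(as.character(probeset_calls$probeset_id))
  unmapped <- setdiff(measured_ps, mapping$probeset_id)
  if (length(unmapped))
    tc_log("dropping %d unmapped probeset(s) of %d measured",
           length(unmapped), length(measured_ps))

  # probeset present per tissue: any replicate P or M
  present <- probeset_calls$call %in% c("P", "M")
  ps_tissue <- unique(data.frame(
    probeset_id = as.character(probeset_calls$probeset_id)[present],
    tissue = as.character(probeset_calls$tissue)[present],
    stringsAsFactors = FALSE))

  # genes = those with >= 1 measured, mapped probeset
  map <- mapping[as.character(mapping$probeset_id) %in% measured_ps, , drop = FALSE]
  genes <- sort(unique(as.character(map$gene_id)))
  if (length(genes) == 0L) stop_tc("no measured probeset maps to any gene")

  calls <- matrix(0L, length(genes), length(tissues),
                  dimnames = list(genes, tissues))
  if (nrow(ps_tissue)) {
    hit <- merge(ps_tissue, map, by = "probeset_id")
    if (nrow(hit))
      calls[cbind(match(as.character(hit$gene_id), genes),
                  match(hit$tissue, tissues))] <- 1L
  }
  call_matrix(calls, platform)
}

#' Gene-level calls from replicate detection p-values
#'
#' Per (gene, tissue), the replicate p-values are summarised by their
#' median (for an even replicate count, the mean of the two central
#' values); the gene is called present iff the median is below the
#' threshold (strict `<` by default, see [call_thresholds()]).
#'
#' @param pvalues data.frame with columns gene_id, tissue, replicate,
#'   pvalue (all p-values in \[0, 1\]).
#' @param thresholds A [call_thresholds()] object.
#' @param platform Platform name stamped on the result.
#' @return A [call_matrix()].
#' @export
dabg_gene_calls <- function(pvalues, thresholds = call_thresholds(),
                            platform = "dabg") {
  req <- c("gene_id", "tissue", "replicate", "pvalue")
  if (!is.data.frame(pvalues) || !all(req %in% names(pvalues)))
    stop_tc("pvalues needs columns %s", paste(req, collapse = ", "))
  p <- pvalues$pvalue
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_tc("detection p-values must lie in [0, 1]")
  genes <- sort(unique(as.character(pvalues$gene_id)))
  tissues <- sort(unique(as.character(pvalues$tissue)))
  med <- tapply(p, list(gene_id = factor(pvalues$gene_id, genes),
                        tissue = factor(pvalues$tissue, tissues)),
                stats::median)
  if (anyNA(med)) stop_tc("every (gene, tissue) needs >= 1 replicate p-value")
  present <- if (thresholds$dabg_strict) med < thresholds$dabg_p else med <= thresholds$dabg_p
  calls <- matrix(as.integer(present), length(genes), length(tissues),
                  dimnames = list(genes, tissues))
  call_matrix(calls, platform)
}

#' Gene-level calls from an RPKM expression matrix
#'
#' Per (gene, tissue), the expression value is the arithmetic mean of that
#' tissue's sample columns (values are averaged before thresholding, the
#' rule used for multi-sample tissues such as cerebellum); the gene is
#' present iff the mean RPKM is >= the threshold (inclusive).
#'
#' @param expr Numeric gene x sample matrix with column names
#'   `tissue.sampleIndex` (the part before the last "." is the tissue) and
#'   non-negative values.
#' @param thresholds A [call_thresholds()] object.
#' @param platform Platform name stamped on the result.
#' @return A [call_matrix()].
#' @export
rpkm_gene_calls <- function(expr, thresholds = call_thresholds(),
                            platform = "rpkm") {
  if (!is.matrix(expr) || is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_tc("'expr' must be a matrix with gene row names and tissue.sample column names")
  if (anyNA(expr)) stop_tc("expression matrix has missing cells")
  if (any(expr < 0)) stop_tc("negative RPKM value(s)")
  col_tissue <- sub("\\.[^.]*$", "", colnames(expr))
  tissues <- sort(unique(col_tissue))
  genes <- rownames(expr)
  means <- sapply(tissues, function(t)
    rowMeans(expr[, col_tissue == t, drop = FALSE]))
  means <- matrix(means, nrow = length(genes), dimnames = list(genes, tissues))
  calls <- matrix(as.integer(means >= thresholds$rpkm), length(genes),
                  length(tissues), dimnames = list(genes, tissues))
  calls <- calls[sort(genes), , drop = FALSE]
  call_matrix(calls, platform)
}

#' Restrict call matrices to their shared gene universe
#'
#' Cross-platform statistics are only meaningful on genes measurable on all
#' platforms, so every matrix is cut down to the sorted intersection of the
#' gene sets; dropped-gene counts are logged per input. Tissue sets must be
#' identical unless `intersect_tissues = TRUE`, in which case the tissue
#' intersection is taken as well.
#'
#' @param matrices List of >= 2 [call_matrix()] objects.
#' @param intersect_tissues Logical; allow differing tissue panels and
#'   restrict to the common tissues.
#' @return List of call matrices with identical (sorted) gene rows.
#' @export
restrict_to_shared <- function(matrices, intersect_tissues = FALSE) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop_tc("need >= 2 call matrices")
  lapply(matrices, function(m) if (!inherits(m, "call_matrix"))
    stop_tc("all inputs must be call_matrix objects"))
  tissue_sets <- lapply(matrices, colnames)
  common_tissues <- Reduce(intersect, tissue_sets)
  if (!intersect_tissues &&
      !all(vapply(tissue_sets, function(t) setequal(t, tissue_sets[[1]]), TRUE)))
    stop_tc("tissue sets differ; pass intersect_tissues = TRUE to intersect them")
  if (length(common_tissues) == 0L) stop_tc("no common tissues")
  shared <- sort(Reduce(intersect, lapply(matrices, rownames)))
  if (length(shared) == 0L) stop_tc("empty shared gene universe")
  lapply(matrices, function(m) {
    dropped <- nrow(m) - length(shared)
    if (dropped > 0)
      tc_log("platform '%s': dropping %d of %d genes outside the shared universe",
             call_platform(m), dropped, nrow(m))
    m[shared, sort(common_tissues), drop = FALSE]
  })
}
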