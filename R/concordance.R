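#' Confusion counts between two platforms' calls in one tissue
#'
#' Counts, over the shared gene universe, the genes called expressed in
#' both datasets (TP), expressed in neither (TN), expressed only in the
#' first (FP), and expressed only in the second (FN). The FP/FN orientation
#' is fixed by argument order; the Matthews correlation derived from the
#' counts is invariant to it.
#'
#' @param a,b [call_matrix()] objects over an identical gene universe
#'   (use [restrict_to_shared()] first).
#' @param tissue Tissue name present in both matrices.
#' @return Object of class `confusion_counts`: list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(a, b, tissue) {
  stopifnot(inherits(a, "call_matrix"), inherits(b, "call_matrix"))
  if (!identical(rownames(a), rownames(b)))
    stop_tc("gene universes differ; apply restrict_to_shared() first")
  if (!(tissue %in% colnames(a)) || !(tissue %in% colnames(b)))
    stop_tc("tissue '%s' missing from one of the matrices", tissue)
  x <- a[, tissue] == 1L
  y <- b[, tissue] == 1L
  structure(list(TP = sum(x & y), TN = sum(!x & !y),
                 FP = sum(x & !y), FN = sum(!x & y)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), the Pearson
#' correlation of the two underlying 0/1 classification vectors. When any
#' marginal factor is zero the coefficient is undefined; by the standard
#' convention 0 is returned, flagged with attribute `degenerate = TRUE`.
#'
#' @param x A [confusion_counts()] object, or a numeric vector/list with
#'   named entries TP, TN, FP, FN.
#' @return MCC in \[-1, 1\]; attribute `degenerate` marks the
#'   zero-denominator convention.
#' @examples
#' mcc(c(TP = 3, TN = 4, FP = 2, FN = 1))  # 10 / sqrt(600)
#' @export
mcc <- function(x) {
  x <- as.list(x)
  if (!all(c("TP", "TN", "FP", "FN") %in% names(x)))
    stop_tc("mcc() needs named counts TP, TN, FP, FN")
  tp <- as.numeric(x$TP); tn <- as.numeric(x$TN)
  fp <- as.numeric(x$FP); fn <- as.numeric(x$FN)
  counts <- c(tp, tn, fp, fn)
  if (anyNA(counts) || any(counts < 0)) stop_tc("confusion counts must be >= 0")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0)
    return(structure(0, degenerate = TRUE))
  structure((tp * tn - fp * fn) / sqrt(denom2), degenerate = FALSE)
}

#' Pairwise cross-platform concordance table
#'
#' For every unordered pair of platforms and every tissue, computes the
#' confusion counts and the Matthews correlation coefficient over the
#' shared gene universe, plus per-pair summaries (arithmetic mean over
#' tissues, and the min/max with the tissue attaining them).
#'
#' @param matrices List of >= 2 [call_matrix()] objects; restricted to the
#'   shared universe internally if needed.
#' @return Object of class `concordance_table`: list with `per_tissue`
#'   (data.frame: platform_a, platform_b, tissue, TP, TN, FP, FN, MCC,
#'   degenerate) and `summary` (data.frame: platform_a, platform_b,
#'   mean_mcc, min_mcc, min_tissue, max_mcc, max_tissue).
#' @export
pairwise_concordance <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop_tc("need >= 2 call matrices")
  gene_sets <- lapply(matrices, rownames)
  if (!all(vapply(gene_sets, identical, TRUE, gene_sets[[1]])))
    matrices <- restrict_to_shared(matrices)
  platforms <- vapply(matrices, call_platform, "")
  if (anyDuplicated(platforms)) stop_tc("platform names must be unique")
  tissues <- colnames(matrices[[1]])

  rows <- list()
  for (i in seq_len(length(matrices) - 1L)) for (j in (i + 1L):length(matrices)) {
    for (t in tissues) {
      cc <- confusion_counts(matrices[[i]], matrices[[j]], t)
      m <- mcc(cc)
      rows[[length(rows) + 1L]] <- data.frame(
        platform_a = platforms[i], platform_b = platforms[j], tissue = t,
        TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
        MCC = as.numeric(m), degenerate = isTRUE(attr(m, "degenerate")),
        stringsAsFactors = FALSE)
    }
  }
  per_tissue <- do.call(rbind, rows)

  pair_key <- paste(per_tissue$platform_a, per_tissue$platform_b, sep = " vs ")
  summ <- do.call(rbind, lapply(unique(pair_key), function(k) {
    d <- per_tissue[pair_key == k, , drop = FALSE]
    data.frame(platform_a = d$platform_a[1], platform_b = d$platform_b[1],
               mean_mcc = mean(d$MCC),
               min_mcc = min(d$MCC), min_tissue = d$tissue[which.min(d$MCC)],
               max_mcc = max(d$MCC), max_tissue = d$tissue[which.max(d$MCC)],
               stringsAsFactors = FALSE)
  }))
  structure(list(per_tissue = per_tissue, summary = summ),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, digits = 3, ...) {
  cat("<concordance_table>\n")
  s <- x$summary
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %s vs %s: mean MCC %.*f (min %.*f in %s, max %.*f in %s)\n",
                s$platform_a[k], s$platform_b[k], digits, s$mean_mcc[k],
                digits, s$min_mcc[k], s$min_tissue[k],
                digits, s$max_mcc[k], s$max_tissue[k]))
  invisible(x)
}
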