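#' Keep interactions measurable on every platform
#'
#' An interaction can only be analyzed across platforms if both partners
#' have expression estimates in every dataset, so edges with an endpoint
#' outside any matrix's gene universe are dropped (retention is logged).
#'
#' @param net An [interaction_network()].
#' @param matrices List of >= 1 [call_matrix()] objects.
#' @return Filtered [interaction_network()].
#' @export
filter_interactions <- function(net, matrices) {
  stopifnot(inherits(net, "interaction_network"))
  if (inherits(matrices, "call_matrix")) matrices <- list(matrices)
  if (length(matrices) < 1L) stop_tc("need >= 1 call matrix")
  keep <- rep(TRUE, nrow(net))
  for (m in matrices) {
    u <- rownames(m)
    keep <- keep & net$gene_a %in% u & net$gene_b %in% u
  }
  tc_log("retained %d of %d interactions with both partners measured everywhere",
         sum(keep), nrow(net))
  structure(net[keep, , drop = FALSE],
            class = c("interaction_network", "data.frame"))
}

#' Per-tissue interaction presence and per-edge breadth
#'
#' An interaction is present in a tissue iff both partner genes have
#' present calls there (the standard rule for projecting expression onto a
#' physical interaction network). Reports per-tissue present/absent edge
#' counts and each edge's breadth (number of tissues where present);
#' breadth 1 identifies tissue-specific interactions.
#'
#' @param net An [interaction_network()]; all endpoints must be in `m`'s
#'   universe (see [filter_interactions()]).
#' @param m A [call_matrix()].
#' @return List with `per_tissue` (data.frame: platform, tissue,
#'   present_count, absent_count) and `edges` (data.frame: gene_a, gene_b,
#'   breadth, plus one 0/1 column per tissue).
#' @export
interaction_presence <- function(net, m) {
  stopifnot(inherits(net, "interaction_network"), inherits(m, "call_matrix"))
  missing <- setdiff(unique(c(net$gene_a, net$gene_b)), rownames(m))
  if (length(missing))
    stop_tc("edge endpoint(s) missing from the call matrix: %s%s",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  present <- m[net$gene_a, , drop = FALSE] * m[net$gene_b, , drop = FALSE]
  colnames(present) <- colnames(m)
  per_tissue <- data.frame(platform = call_platform(m), tissue = colnames(m),
                           present_count = colSums(present),
                           absent_count = nrow(net) - colSums(present),
                           stringsAsFactors = FALSE, row.names = NULL)
  edges <- data.frame(gene_a = net$gene_a, gene_b = net$gene_b,
                      breadth = as.integer(rowSums(present)),
                      stringsAsFactors = FALSE)
  edges <- cbind(edges, as.data.frame(present, row.names = NULL))
  list(per_tissue = per_tissue, edges = edges)
}

#' Filter complexes to analyzable ones
#'
#' Retains complexes whose every member is in every platform's gene
#' universe and whose distinct-member count is at least `min_size`
#' (complexes need at least three different proteins to be meaningful),
#' and collapses exact duplicate member sets to the first-named complex
#' (duplicates logged).
#'
#' @param cs A [complex_set()].
#' @param matrices List of >= 1 [call_matrix()] objects.
#' @param min_size Minimum distinct-member count (default 3).
#' @return Filtered [complex_set()].
#' @export
filter_complexes <- function(cs, matrices, min_size = 3L) {
  stopifnot(inherits(cs, "complex_set"))
  if (inherits(matrices, "call_matrix")) matrices <- list(matrices)
  if (length(matrices) < 1L) stop_tc("need >= 1 call matrix")
  assert_scalar_number(min_size, "min_size", 1)
  if (length(cs) == 0L) return(cs)
  universes <- lapply(matrices, rownames)
  big_enough <- lengths(cs) >= min_size
  measured <- vapply(cs, function(members)
    all(vapply(universes, function(u) all(members %in% u), TRUE)), TRUE)
  keep <- big_enough & measured
  tc_log("complexes: %d too small, %d with unmeasured member(s) dropped",
         sum(!big_enough), sum(big_enough & !measured))
  kept <- cs[keep]
  # deduplicate by exact member-set equality (members stored sorted)
  key <- vapply(kept, paste, "", collapse = "\r")
  dup <- duplicated(key)
  if (any(dup)) tc_log("collapsed %d duplicate complex(es)", sum(dup))
  kept[!dup]
}

#' Classify complex expression per tissue
#'
#' For each complex and tissue, counts the members with present calls and
#' assigns one of three classes that partition all outcomes: `complete`
#' (all members expressed), `partial` (at least two members expressed but
#' not all), `absent` (at most one member expressed). The detection
#' percentage is 100 * n_expressed / n_members.
#'
#' @param cs A [complex_set()] whose members are all in `m`'s universe
#'   (see [filter_complexes()]).
#' @param m A [call_matrix()].
#' @return data.frame of class `complex_classification`: complex_name,
#'   tissue, platform, n_members, n_expressed, class,
#'   detection_percentage — one row per complex x tissue.
#' @export
classify_complexes <- function(cs, m) {
  stopifnot(inherits(cs, "complex_set"), inherits(m, "call_matrix"))
  missing <- setdiff(unique(unlist(cs)), rownames(m))
  if (length(missing))
    stop_tc("complex member(s) missing from the call matrix: %s%s",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  rows <- lapply(names(cs), function(nm) {
    members <- cs[[nm]]
    n_expr <- colSums(m[members, , drop = FALSE])
    data.frame(complex_name = nm, tissue = colnames(m),
               platform = call_platform(m),
               n_members = length(members),
               n_expressed = as.integer(n_expr),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(complex_name = character(0), tissue = character(0),
                      platform = character(0), n_members = integer(0),
                      n_expressed = integer(0), stringsAsFactors = FALSE)
  out$class <- ifelse(out$n_expressed == out$n_members, "complete",
               ifelse(out$n_expressed <= 1L, "absent", "partial"))
  out$detection_percentage <- 100 * out$n_expressed / pmax(out$n_members, 1L)
  structure(out, class = c("complex_classification", "data.frame"))
}

#' Cross-platform concordance of complex detection percentages
#'
#' Per tissue, correlates the two platforms' detection-percentage vectors
#' over the shared complexes (Pearson by default; Spearman available).
#' A tissue where either vector is constant has no defined correlation; it
#' is flagged degenerate and excluded from the mean/min/max summary.
#'
#' @param class_a,class_b [classify_complexes()] outputs over identical
#'   complexes and tissues.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `per_tissue` (data.frame: tissue, correlation,
#'   degenerate) and `summary` (data.frame: mean/min/max correlation with
#'   the tissues attaining min and max).
#' @export
complex_concordance <- function(class_a, class_b,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  for (d in list(class_a, class_b))
    if (!inherits(d, "complex_classification"))
      stop_tc("inputs must come from classify_complexes()")
  tissues <- sort(unique(class_a$tissue))
  if (!setequal(tissues, unique(class_b$tissue)))
    stop_tc("tissue sets differ between the two classifications")
  if (!setequal(unique(class_a$complex_name), unique(class_b$complex_name)))
    stop_tc("complex sets differ between the two classifications")

  per_tissue <- do.call(rbind, lapply(tissues, function(t) {
    a <- class_a[class_a$tissue == t, , drop = FALSE]
    b <- class_b[class_b$tissue == t, , drop = FALSE]
    b <- b[match(a$complex_name, b$complex_name), , drop = FALSE]
    x <- a$detection_percentage; y <- b$detection_percentage
    degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
    data.frame(tissue = t,
               correlation = if (degenerate) NA_real_ else
                 stats::cor(x, y, method = method),
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  ok <- per_tissue[!per_tissue$degenerate, , drop = FALSE]
  summary <- if (nrow(ok)) data.frame(
    mean_correlation = mean(ok$correlation),
    min_correlation = min(ok$correlation),
    min_tissue = ok$tissue[which.min(ok$correlation)],
    max_correlation = max(ok$correlation),
    max_tissue = ok$tissue[which.max(ok$correlation)],
    stringsAsFactors = FALSE)
  else data.frame(mean_correlation = NA_real_, min_correlation = NA_real_,
                  min_tissue = NA_character_, max_correlation = NA_real_,
                  max_tissue = NA_character_, stringsAsFactors = FALSE)
  list(per_tissue = per_tissue, summary = summary)
}
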