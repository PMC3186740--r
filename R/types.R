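#' Binary presence/absence call matrix
#'
#' The central container of the pipeline: a genes x tissues 0/1 integer
#' matrix (1 = present call) stamped with the platform it came from.
#'
#' @param calls Numeric/integer matrix with unique row (gene) and column
#'   (tissue) names and entries in \{0, 1\}.
#' @param platform Non-empty platform name.
#' @return Object of class `call_matrix` (a matrix with a `platform`
#'   attribute).
#' @export
call_matrix <- function(calls, platform) {
  if (!is.matrix(calls)) stop_tc("'calls' must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop_tc("call matrix needs gene row names and tissue column names")
  if (anyDuplicated(rownames(calls))) stop_tc("duplicate gene identifiers")
  if (anyDuplicated(colnames(calls))) stop_tc("duplicate tissue names")
  if (anyNA(calls)) stop_tc("call matrix has missing cells")
  if (!all(calls %in% c(0L, 1L))) stop_tc("call entries must be 0 or 1")
  if (!is.character(platform) || length(platform) != 1L || !nzchar(platform))
    stop_tc("'platform' must be a non-empty string")
  storage.mode(calls) <- "integer"
  structure(calls, platform = platform, class = c("call_matrix", "matrix", "array"))
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("<call_matrix> platform '%s': %d genes x %d tissues, %d present calls\n",
              attr(x, "platform"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

call_platform <- function(m) attr(m, "platform") %||% "unknown"

# Subsetting a call_matrix keeps class and platform when the result is
# still a matrix; vector results drop to plain integer as for any matrix.
#' @export
`[.call_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, platform = attr(x, "platform"),
                     class = c("call_matrix", "matrix", "array"))
  out
}

#' Undirected protein-interaction network
#'
#' Stores an edge list between gene identifiers with set semantics: edges
#' are unordered, self-loops are rejected, and duplicate edges (in either
#' orientation) are collapsed with a logged count.
#'
#' @param edges data.frame with character columns `gene_a`, `gene_b`.
#' @return Object of class `interaction_network`: a data.frame of canonical
#'   (gene_a < gene_b) unique edges.
#' @export
interaction_network <- function(edges) {
  if (!is.data.frame(edges) || !all(c("gene_a", "gene_b") %in% names(edges)))
    stop_tc("'edges' must be a data.frame with columns gene_a, gene_b")
  a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
  if (any(a == b)) stop_tc("self-loop edge(s): %s",
                           paste(unique(a[a == b]), collapse = ", "))
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) tc_log("collapsed %d duplicate edge(s)", sum(dup))
  out <- data.frame(gene_a = lo[!dup], gene_b = hi[!dup], stringsAsFactors = FALSE)
  structure(out, class = c("interaction_network", "data.frame"))
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d edges over %d genes\n",
              nrow(x), length(unique(c(x$gene_a, x$gene_b)))))
  invisible(x)
}

#' Named set of protein complexes
#'
#' @param complexes Named list; each element a character vector of distinct
#'   member gene identifiers (non-empty). Names must be unique.
#' @return Object of class `complex_set`.
#' @export
complex_set <- function(complexes) {
  if (!is.list(complexes)) stop_tc("'complexes' must be a named list")
  if (length(complexes)) {
    if (is.null(names(complexes)) || any(!nzchar(names(complexes))) ||
        anyDuplicated(names(complexes)))
      stop_tc("complex names must be unique and non-empty")
    sizes <- lengths(complexes)
    if (any(sizes == 0L)) stop_tc("empty member set in complex(es): %s",
                                  paste(names(complexes)[sizes == 0L], collapse = ", "))
    complexes <- lapply(complexes, function(m) sort(unique(as.character(m))))
  }
  structure(complexes, class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  cat(sprintf("<complex_set> %d complexes, member sizes %s\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "..") else "-"))
  invisible(x)
}

#' @export
`[.complex_set` <- function(x, i) complex_set(unclass(x)[i])
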