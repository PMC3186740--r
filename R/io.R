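# All tables are TSV: tab-separated, UTF-8, '.' decimal, one header row.
read_tsv_strict <- function(path, required, what = "table") {
  if (!file.exists(path)) stop_tc("file not found: %s", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!all(required %in% names(d)))
    stop_tc("%s '%s': header must contain columns %s", what, path,
            paste(required, collapse = ", "))
  d
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a detection-call table
#'
#' Three dialects are supported:
#' * `"probeset"` — long table `probeset_id, tissue, replicate, call` with
#'   call symbols P/M/A (MAS5.0-style probeset calls);
#' * `"pvalue"` — long table `gene_id, tissue, replicate, pvalue` with
#'   p-values in \[0, 1\] (DABG-style detection p-values);
#' * `"matrix"` — wide binary call matrix: first column `gene_id`, one 0/1
#'   column per tissue.
#' Invalid symbols, out-of-range p-values and duplicate
#' (id, tissue, replicate) rows are rejected with the offending line
#' identified; readers never coerce silently.
#'
#' @param path File path.
#' @param dialect One of `"probeset"`, `"pvalue"`, `"matrix"`.
#' @param platform For `dialect = "matrix"`: platform name to stamp on the
#'   returned [call_matrix()].
#' @return A data.frame (long dialects) or [call_matrix()].
#' @export
read_call_table <- function(path, dialect = c("probeset", "pvalue", "matrix"),
                            platform = "unknown") {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    d <- read_tsv_strict(path, "gene_id", "call matrix")
    if (anyDuplicated(d$gene_id))
      stop_tc("call matrix '%s': duplicate gene identifiers", path)
    mat <- as.matrix(d[, setdiff(names(d), "gene_id"), drop = FALSE])
    suppressWarnings(storage.mode(mat) <- "integer")
    rownames(mat) <- d$gene_id
    return(call_matrix(mat, platform))
  }
  if (dialect == "probeset") {
    d <- read_tsv_strict(path, c("probeset_id", "tissue", "replicate", "call"),
                         "probeset call table")
    bad <- which(!d$call %in% c("P", "M", "A"))
    if (length(bad))
      stop_tc("probeset call table '%s': invalid call symbol '%s' at data line %d",
              path, d$call[bad[1]], bad[1])
    key <- paste(d$probeset_id, d$tissue, d$replicate, sep = "\r")
  } else {
    d <- read_tsv_strict(path, c("gene_id", "tissue", "replicate", "pvalue"),
                         "p-value table")
    d$pvalue <- as.numeric(d$pvalue)
    bad <- which(is.na(d$pvalue) | d$pvalue < 0 | d$pvalue > 1)
    if (length(bad))
      stop_tc("p-value table '%s': p-value outside [0, 1] at data line %d",
              path, bad[1])
    key <- paste(d$gene_id, d$tissue, d$replicate, sep = "\r")
  }
  dup <- which(duplicated(key))
  if (length(dup))
    stop_tc("'%s': duplicate (id, tissue, replicate) row at data line %d",
            path, dup[1])
  d$replicate <- as.integer(d$replicate)
  d
}

#' Read an RPKM expression matrix
#'
#' Wide TSV: first column `gene_id`, remaining columns one sample each,
#' named `tissue.sampleIndex`. Values must be non-negative with no missing
#' cells (missingness is an error, never imputed).
#'
#' @param path File path.
#' @return Numeric gene x sample matrix.
#' @export
read_expression_matrix <- function(path) {
  d <- read_tsv_strict(path, "gene_id", "expression matrix")
  if (anyDuplicated(d$gene_id))
    stop_tc("expression matrix '%s': duplicate gene identifiers", path)
  samples <- setdiff(names(d), "gene_id")
  if (anyDuplicated(samples))
    stop_tc("expression matrix '%s': duplicate sample columns", path)
  mat <- as.matrix(d[, samples, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  if (anyNA(mat)) stop_tc("expression matrix '%s': missing or non-numeric cell", path)
  if (any(mat < 0)) stop_tc("expression matrix '%s': negative RPKM value", path)
  rownames(mat) <- d$gene_id
  mat
}

#' Read an interaction edge list
#'
#' TSV with columns `gene_a`, `gene_b`. Self-loops are an error; duplicate
#' edges (in either orientation) are collapsed with a logged warning.
#'
#' @param path File path.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path) {
  d <- read_tsv_strict(path, c("gene_a", "gene_b"), "edge list")
  interaction_network(d)
}

#' Read a GMT-style complex-membership file
#'
#' One complex per line: name, description, then member gene identifiers,
#' all tab-separated (so every line needs >= 3 fields). Duplicate complex
#' names are rejected.
#'
#' @param path File path.
#' @return A [complex_set()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_tc("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(complex_set(stats::setNames(list(), character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_tc("GMT file '%s': line %d has fewer than 3 tab-separated fields",
            path, short[1])
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop_tc("GMT file '%s': duplicated complex name '%s'", path,
            nms[duplicated(nms)][1])
  complex_set(stats::setNames(lapply(fields, function(f) f[-(1:2)]), nms))
}

#' Read a probeset-to-gene mapping table
#'
#' TSV with columns `probeset_id`, `gene_id`. The mapping may be
#' many-to-many: one probeset may map to several genes and vice versa;
#' exact duplicate rows are collapsed.
#'
#' @param path File path.
#' @return data.frame with columns probeset_id, gene_id.
#' @export
read_mapping <- function(path) {
  d <- read_tsv_strict(path, c("probeset_id", "gene_id"), "mapping table")
  unique(d[, c("probeset_id", "gene_id")])
}

#' Write a binary call matrix as TSV
#' @param m A [call_matrix()].
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_call_matrix <- function(m, path) {
  stopifnot(inherits(m, "call_matrix"))
  d <- data.frame(gene_id = rownames(m), as.data.frame(unclass(m)[,, drop = FALSE]),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(d, path)
}

#' Write an expression matrix as TSV
#' @param mat Numeric gene x sample matrix.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  d <- data.frame(gene_id = rownames(mat), as.data.frame(mat),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(d, path)
}

#' Write an edge list as TSV
#' @param net An [interaction_network()].
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(net, path) write_tsv(as.data.frame(net), path)

#' Write a complex set in GMT format
#' @param cs A [complex_set()].
#' @param path Destination path.
#' @param descriptions Optional character vector of per-complex
#'   descriptions (default "na").
#' @return The path, invisibly.
#' @export
write_gmt <- function(cs, path, descriptions = NULL) {
  stopifnot(inherits(cs, "complex_set"))
  descriptions <- descriptions %||% rep("na", length(cs))
  lines <- vapply(seq_along(cs), function(i)
    paste(c(names(cs)[i], descriptions[i], cs[[i]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML file holding the call thresholds, platform declarations and input
#' paths. Recognized top-level keys: `thresholds` (dabg_p, rpkm,
#' dabg_strict), `platforms` (list of platform_model fields), `paths`
#' (free-form), `seed`.
#'
#' @param path YAML file path.
#' @return List with `thresholds` ([call_thresholds()]), `platforms`
#'   (list of [platform_model()]), `paths`, `seed`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_tc("file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  th <- do.call(call_thresholds, c(list(),
    cfg$thresholds[intersect(names(cfg$thresholds),
                             c("dabg_p", "rpkm", "dabg_strict"))]))
  platforms <- lapply(cfg$platforms, function(p) do.call(platform_model, p))
  list(thresholds = th, platforms = platforms,
       paths = cfg$paths, seed = cfg$seed)
}

#' Write result tables plus run metadata
#'
#' Each named element of `tables` (a data.frame) is written as
#' `<name>.tsv` in `out_dir`; a `run_metadata.yaml` records the seed, the
#' configuration, the package version and the R version for provenance.
#'
#' @param tables Named list of data.frames (may be empty data.frames,
#'   which produce headers-only files).
#' @param out_dir Output directory (created if missing).
#' @param seed The seed the run used, recorded in the metadata.
#' @param config Optional configuration list echoed into the metadata.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, seed = NULL, config = NULL) {
  if (!is.list(tables) || (length(tables) && is.null(names(tables))))
    stop_tc("'tables' must be a named list of data.frames")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_tc("cannot create output directory '%s'", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(as.data.frame(tables[[nm]]), p)
    paths <- c(paths, p)
  }
  meta <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(list(
    package = "tissueconcord",
    version = as.character(utils::packageVersion("tissueconcord")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config,
    tables = names(tables)), meta)
  invisible(c(paths, meta))
}
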