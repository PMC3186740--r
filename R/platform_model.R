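#' Describe a measurement platform's detection behaviour
#'
#' A platform model abstracts one expression-measurement technology by its
#' per-observation detection characteristics: the probability `sensitivity`
#' that a truly expressed gene is detected, the probability
#' `false_positive_rate` that a truly unexpressed gene is detected, the
#' replicate structure, and the kind of raw observation the platform emits:
#'
#' * `"pma_calls"` — probeset-level Present/Marginal/Absent call tables with
#'   replicates, as produced by MAS5.0-style microarray processing. The
#'   sensitivity applies per probeset x replicate slot.
#' * `"detection_pvalues"` — gene-level detection p-values with replicates,
#'   as produced by the DABG (detection above background) method for exon
#'   arrays. The sensitivity is calibrated to the post-median call rate (see
#'   [simulate_detection_pvalues()]).
#' * `"rpkm"` — gene x sample RPKM expression estimates from RNA
#'   sequencing. The sensitivity is the probability that an expressed gene's
#'   RPKM clears the call threshold (see [simulate_rpkm()]).
#'
#' @param name Platform name (non-empty string); stamped onto call matrices.
#' @param kind One of `"pma_calls"`, `"detection_pvalues"`, `"rpkm"`.
#' @param sensitivity Detection probability for truly expressed genes,
#'   in (0, 1]. Must exceed `false_positive_rate` (an informative platform).
#' @param false_positive_rate Detection probability for truly unexpressed
#'   genes, in [0, 1).
#' @param n_replicates Replicates per tissue sample; defaults to 2 for
#'   P/M/A calls and 3 for detection p-values, 1 otherwise.
#' @param m_fraction P/M/A platforms only: fraction of Present calls emitted
#'   as Marginal instead. Marginal calls are treated as present downstream,
#'   so only their existence matters.
#' @param probesets_per_gene P/M/A platforms only: probability weights over
#'   probeset counts 1, 2, 3, ... per gene (named or unnamed numeric
#'   vector; position i = probability of i probesets).
#' @param rpkm_sdlog RPKM platforms only: log-scale spread (lognormal
#'   `sdlog`) shared by the expressed and unexpressed RPKM components. The
#'   log-scale locations are derived from `sensitivity`,
#'   `false_positive_rate` and the call threshold so that the planted rates
#'   are reproduced after thresholding.
#' @return An object of class `platform_model`.
#' @examples
#' platform_model("exon_array", "detection_pvalues",
#'                sensitivity = 0.85, false_positive_rate = 0.05)
#' @export
platform_model <- function(name, kind = c("pma_calls", "detection_pvalues", "rpkm"),
                           sensitivity, false_positive_rate,
                           n_replicates = NULL, m_fraction = 0.05,
                           probesets_per_gene = c(0.5, 0.3, 0.2),
                           rpkm_sdlog = 1.0) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_tc("platform 'name' must be a non-empty string")
  assert_scalar_number(sensitivity, "sensitivity", 0, 1)
  assert_scalar_number(false_positive_rate, "false_positive_rate", 0, 1)
  if (!(false_positive_rate < sensitivity))
    stop_tc("need false_positive_rate < sensitivity (informative platform); got fpr=%g, sens=%g",
            false_positive_rate, sensitivity)
  if (is.null(n_replicates))
    n_replicates <- switch(kind, pma_calls = 2L, detection_pvalues = 3L, 1L)
  assert_scalar_number(n_replicates, "n_replicates", 1)
  n_replicates <- as.integer(n_replicates)
  assert_scalar_number(m_fraction, "m_fraction", 0, 1)
  if (!is.numeric(probesets_per_gene) || length(probesets_per_gene) < 1L ||
      any(probesets_per_gene < 0) || sum(probesets_per_gene) <= 0)
    stop_tc("'probesets_per_gene' must be non-negative weights over counts 1,2,...")
  assert_scalar_number(rpkm_sdlog, "rpkm_sdlog", lo = 1e-12)

  structure(list(
    name = name, kind = kind,
    sensitivity = sensitivity, false_positive_rate = false_positive_rate,
    n_replicates = n_replicates, m_fraction = m_fraction,
    probesets_per_gene = probesets_per_gene / sum(probesets_per_gene),
    rpkm_sdlog = rpkm_sdlog
  ), class = "platform_model")
}

#' @export
print.platform_model <- function(x, ...) {
  cat(sprintf("<platform_model> %s (%s)\n", x$name, x$kind))
  cat(sprintf("  sensitivity %.3g, false-positive rate %.3g, %d replicate(s)\n",
              x$sensitivity, x$false_positive_rate, x$n_replicates))
  invisible(x)
}

check_kind <- function(platform, expected) {
  if (!inherits(platform, "platform_model"))
    stop_tc("'platform' must be a platform_model object")
  if (platform$kind != expected)
    stop_tc("platform '%s' has observation kind '%s'; this simulator needs '%s'",
            platform$name, platform$kind, expected)
  invisible(platform)
}
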