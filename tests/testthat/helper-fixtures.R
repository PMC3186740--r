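# Shared fixtures: tiny platforms and studies built in code at test time.
quiet_logging(TRUE)

TISSUES5 <- c("heart", "liver", "testis", "muscle", "cerebellum")

noiseless_platforms <- function() list(
  platform_model("pma_perfect", "pma_calls", sensitivity = 1,
                 false_positive_rate = 0, m_fraction = 0),
  platform_model("dabg_perfect", "detection_pvalues", sensitivity = 1,
                 false_positive_rate = 0),
  platform_model("rpkm_perfect", "rpkm", sensitivity = 1,
                 false_positive_rate = 0)
)

# Derive the three call matrices from a simulate_study() result.
derive_calls <- function(study, thresholds = call_thresholds()) {
  obs <- study$observations
  out <- list()
  for (nm in names(obs)) {
    kind <- if (is.list(obs[[nm]]) && !is.data.frame(obs[[nm]])) "pma"
            else if (is.matrix(obs[[nm]])) "rpkm" else "dabg"
    out[[nm]] <- switch(kind,
      pma = pma_gene_calls(obs[[nm]]$calls, obs[[nm]]$mapping, platform = nm),
      dabg = dabg_gene_calls(obs[[nm]], thresholds, platform = nm),
      rpkm = rpkm_gene_calls(obs[[nm]], thresholds, platform = nm))
  }
  out
}

# Hand-built call matrix from a named list tissue -> present gene subset.
tiny_call_matrix <- function(genes, tissues, present, platform = "toy") {
  m <- matrix(0L, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  for (t in names(present)) m[present[[t]], t] <- 1L
  call_matrix(m, platform)
}
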