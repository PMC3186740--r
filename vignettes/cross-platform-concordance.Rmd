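---
title: "Cross-platform concordance of tissue expression calls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform concordance of tissue expression calls: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueconcord)
quiet_logging(TRUE)
```

## The problem

Binary "is this gene expressed in this tissue?" calls are derived very
differently by different technologies: 3'-biased expression microarrays
emit Present/Marginal/Absent calls per probeset and replicate, exon
tiling arrays emit per-gene detection-above-background (DABG) p-values
per replicate, and RNA sequencing yields continuous RPKM estimates. Each
pipeline has its own sensitivity floor, so the *same* biological sample
yields different call sets, and summaries built on those calls — how many
genes are tissue-specific, which protein interactions exist in a tissue,
which protein complexes are completely expressed — inherit the bias.
This package makes the comparison itself the object of study: it derives
calls under each platform's rule, quantifies agreement, classifies tissue
breadth, propagates calls to interaction networks and complexes, and
provides a generative model with planted sensitivities so every claim the
pipeline makes can be tested against a known truth.

## Call derivation rules

All three rules produce a `call_matrix` (genes × tissues, 0/1) and are
deliberately minimal, mirroring standard practice for each technology:

* **P/M/A** (`pma_gene_calls`): marginal calls are treated as present —
  only presence evidence is propagated; a probeset is present in a tissue
  if at least one replicate says P or M; a gene is present if at least one
  of its probesets is. The probeset→gene mapping may be many-to-many; a
  probeset mapped to several genes contributes its calls to each, since
  aggregate mapping counts give no disambiguation rule. A gene whose
  probesets are all unmapped or unmeasured is *excluded* from the matrix,
  not called absent: "not on the array" is missingness, "absent" is a
  measurement, and conflating them would deflate cross-platform agreement
  artificially. Cross-platform statistics therefore run on the shared
  universe (`restrict_to_shared`).
* **DABG** (`dabg_gene_calls`): present iff the median replicate p-value
  is below the threshold (default 0.05, the conventional DABG cut). The
  boundary `p = 0.05` itself is treated as *absent* (strict `<`), the
  common convention for detection p-values; since reasonable people could
  read the threshold either way, the inequality is configurable
  (`call_thresholds(dabg_strict = FALSE)`). The median of an even number
  of replicates is the mean of the two central values.
* **RPKM** (`rpkm_gene_calls`): present iff the per-tissue mean RPKM is
  `>= 1` (inclusive, exactly as the rule is usually printed). When a
  tissue has several samples, values are averaged *before* thresholding —
  the rule used for multi-sample tissues such as cerebellum — rather than
  thresholding per sample and voting, which would change the call for
  genes expressed strongly in a minority of samples.

## Concordance

Agreement between two call matrices in one tissue is summarized by the
Matthews correlation coefficient of the confusion counts over the shared
genes (TP both present, TN both absent, FP/FN exactly one present):

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$$

MCC is exactly the Pearson correlation of the two 0/1 vectors, which is
what the test suite exploits as an independent oracle (brute-force
`cor()` on enumerated vectors). When any marginal factor is zero the
coefficient is undefined; the package returns 0 with a `degenerate`
attribute — the standard convention, chosen over `NA` so that summary
means remain computable, and flagged so the case is never silent. FP/FN
orientation is fixed by argument order and only affects the reported
columns, never the coefficient. Per-pair summaries report the arithmetic
mean over tissues plus min/max with their tissues.

## Tissue breadth

A gene's breadth is its number of present calls across the analyzed
panel; the classes *absent* (0), *tissue-specific* (exactly 1),
*intermediate* (2..N−1) and *universal* (N) partition the universe.
"Tissue-specific" is always relative to the panel under analysis — the
panel is a parameter, not a constant. `specificity_vs_sensitivity_report`
quantifies the headline bias on synthetic data: a truly universal gene
over N tissues observed at per-tissue sensitivity $s$ (negligible false
positives) is reported tissue-specific with probability
$N s (1-s)^{N-1}$ — for $N = 5$, $s = 0.5$ that is 15.6% of universal
genes misreported as tissue-specific, which is the mechanism by which
low-sensitivity platforms inflate tissue-specificity claims.

## Interactions and complexes

An interaction is present in a tissue iff both partners have present
calls there — the standard projection of expression onto a physical
network; the rule is a modeling choice of this package rather than a
quoted one, and it is the only rule consistent with treating calls as
presence evidence. Complexes are classified per tissue as *complete*
(all members expressed), *partial* (at least two members expressed, but
not all) or *absent* (at most one member expressed); the three classes
partition all outcomes for complexes of ≥ 3 members, and the detection
percentage $100\,n_\mathrm{expressed}/n_\mathrm{members}$ refines the
classes into a continuous score.

Filtering before classification: interactions keep only edges whose both
endpoints are measured on every platform; complexes need ≥ 3 *distinct*
members, all measured everywhere, and exact duplicate member sets
collapse to the first-named complex (the only operational reading of
duplicate removal). Complexes whose members are measured but absent
everywhere are *kept* — absence is information, not missingness.

Cross-platform agreement on complexes correlates the two platforms'
detection-percentage vectors per tissue. MCC is undefined for continuous
percentages, so Pearson is the default statistic (Spearman available via
`method = "spearman"`); a tissue where either vector is constant has no
defined correlation and is flagged degenerate and excluded from the
mean/min/max summary rather than imputed.

## The generative model

`simulate_study()` builds everything downstream stages consume:

* **Ground truth**: each gene draws a breadth class from a three-component
  mixture — universal, tissue-specific (one uniform tissue), intermediate
  (breadth uniform on \[2, N−1\], tissues a uniform subset). Real breadth
  spectra are only known empirically, so the weights are exposed as
  parameters; the default (0.4, 0.2, 0.4) puts substantial mass on both
  extremes, which is the regime where platform disagreement matters.
* **P/M/A platform**: each gene gets 1–3 probesets (weights 0.5/0.3/0.2,
  enough to exercise the at-least-one-probeset rule without modeling real
  array design); each probeset × tissue × replicate slot is detected with
  probability `sensitivity` (expressed) or `false_positive_rate` (not),
  and a configurable fraction of detected slots is emitted as M rather
  than P — M calls only need to exist, since they are treated as P.
  Sensitivity is defined *per slot*, so the gene-level detection rate
  after aggregation is $1-(1-s)^{kr}$ for $k$ probesets and $r$
  replicates — deliberately higher than $s$, exactly as replicate/probeset
  aggregation raises microarray sensitivity in practice.
* **DABG platform**: detected replicates draw p uniform below the call
  threshold, undetected ones uniform above it. The per-replicate
  detection probability is solved numerically from the binomial median
  formula so that the *post-median call rate* equals the planted
  sensitivity/FPR — the planted parameter means the same thing for every
  platform. Exact for odd replicate counts (default 3); for even counts
  the mixed central pair makes it approximate.
* **RPKM platform**: cells draw lognormal RPKM with the log-scale
  location set to `log(threshold) + sdlog * qnorm(rate)`, i.e. the planted
  rate *is* the lognormal tail probability above the call threshold.
  Rates 0 and 1 use half-normal constructions strictly below/above the
  threshold so the noiseless limit recovers truth exactly.
* **Network / complexes**: uniform simple graph (distinct unordered
  pairs, via combinatorial unranking) and uniform member sets of size
  ≥ 3, with optional duplicate-injection to exercise deduplication.

One master seed drives all stages through a fixed per-stage
stream-splitting hash, so any stage can be re-run independently and
byte-identically.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: errors are independent across genes,
tissues and platforms (no probe-sequence effects, no shared biological
confounding, no correlated replicate noise); expression is binary in
truth (no expression-level-dependent detection, where real microarray
sensitivity falls with decreasing abundance); mapping is synthetic. The
pipeline's *rules* are validated exactly; the generator's noise model is
an artifact choice, because no quantitative noise model for these
platforms is established.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `dabg_p` | 0.05 | p-value | conventional DABG presence threshold; strict `<` |
| `rpkm` | 1.0 | RPKM | conservative presence threshold, inclusive `>=` |
| `sensitivity` | per platform | probability | planted per-observation detection rate |
| `false_positive_rate` | per platform | probability | must be `< sensitivity` (informative platform) |
| `n_replicates` | 2 (P/M/A), 3 (DABG) | count | replicate structures typical for each assay |
| breadth weights | (0.4, 0.2, 0.4) | mixture | mass on both extremes of the breadth spectrum |
| `min_size` | 3 | members | smallest meaningful complex |

The default panel (`default_platforms()`) orders sensitivities
microarray < exon array < RNA-seq (0.5 / 0.85 / 0.95 with FPRs
0.02 / 0.05 / 0.03), reproducing the qualitative technology ordering that
motivates the analysis.

## Numerical and degenerate-input choices

* Zero-denominator MCC → 0 with `degenerate = TRUE` (never silent).
* Constant detection-percentage vectors → correlation `NA`, flagged,
  excluded from summaries.
* DABG calibration solves the binomial median equation by `uniroot` at
  tolerance 1e-12; boundary rates 0/1 short-circuit exactly.
* Readers reject rather than coerce: call symbols outside P/M/A,
  p-values outside \[0, 1\], negative RPKM, duplicate keys, self-loops
  and short GMT lines all raise located errors; duplicate edges and
  duplicate complexes collapse with a logged count.
* Empty inputs are legal where they are meaningful (empty networks,
  empty result tables → headers-only files) and errors where they are
  not (empty mapping, empty gene universe).

## Problem sizes

The test suite validates planted-rate recovery at 10^4–10^5 cells
(binomial 99% intervals), closed-form MCC recovery at 10^5 genes within
±0.02, and the sensitivity-bias ordering (0.95 vs 0.5, FPR 0.01) on 100
seeds of 5000 genes × 5 tissues with 2000 edges and 300 complexes. The
acceptance script runs the full study once at 5000 genes with the default
panel and six cerebellum samples. These sizes give Monte-Carlo error well
inside the asserted tolerances while keeping a full run in the order of a
minute or two.

## Known limitations

* Calls are binary; no continuous specificity index (tau, TSI) is
  provided, since the exact-one-tissue definition is the object of study.
* The closed-form concordance oracle assumes independent errors between
  platforms; real platforms share biological samples and correlate.
* Identifier handling is opaque-string only; mapping identifiers across
  databases is out of scope by design.
* The P/M/A gene-level rate depends on the probeset-count distribution;
  comparisons that require identical gene-level planted rates across
  platforms should use the DABG or RPKM generators, whose calibration
  makes the planted rate exact at the gene level.
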