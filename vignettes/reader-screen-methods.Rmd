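---
title: "Methods: calling reader proteins of modified RNA from pulldown proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling reader proteins of modified RNA from pulldown proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modreader)
```

## The screen and its statistical model

An RNA-bait pulldown screen compares protein recovery across six
conditions: four biotinylated baits each carrying one cytosine-5
modification (m⁵C, hm⁵C, hm⁵Cm, f⁵C), one unmodified bait (`C`), and a
beads-only control, each in three biological replicates. Label-free
quantification yields one iBAQ intensity per protein per sample, with
zero recording non-detection.

The analysis model is deliberately simple — it is a ranking-and-screening
procedure, not an inferential one:

* **Total-intensity normalization.** Each sample's intensities are
  divided by that sample's total over all retained proteins. This removes
  differences in input material and instrument response between
  pulldowns; the resulting values are compositional fractions. The
  assumption is that the *total* captured protein is comparable in
  meaning across conditions — reasonable here because the bulk of every
  pulldown is nonspecific background shared across baits.
* **Median over replicates.** The per-condition summary is the median of
  the (three) normalized replicate values, zeros included. The median at
  n = 3 tolerates one aberrant or dropped-out replicate; with even
  replicate counts the midpoint of the central pair is used.
* **Pseudocount-stabilized fold changes.** A constant ε is added to every
  condition median before ratios are formed, making all fold changes
  finite and setting the fold change of a doubly-absent protein to
  exactly 1. In `derived` mode ε is one hundredth of the smallest
  *positive* median in the table. Zeros must be excluded from that
  minimum — otherwise the derived ε would be zero and stabilize nothing —
  and "smallest value" is read over the condition medians, the quantities
  ε is added to. A `fixed` mode accepts any externally chosen ε (for
  example 1e-9) for reproducing previous analyses.
* **Dual-control thresholding.** A protein is a candidate reader of
  modification *M* when its fold change over the beads-only control is at
  least `t_beads` (default 2.0) *and* its fold change over the unmodified
  bait is at least `t_unmod` (default 1.5). The two controls play
  different roles: beads-only removes matrix-sticky proteins, the
  unmodified bait removes sequence- rather than modification-specific RNA
  binders.
* **Unique binders.** Candidates called for exactly one modification are
  the highest-confidence modification-specific readers; the full 15-region
  overlap structure of the four candidate sets is reported alongside.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `t_beads` | 2.0 | fold | enrichment over empty beads |
| `t_unmod` | 1.5 | fold | preference for the modified over unmodified bait |
| `strict` | `FALSE` (≥) | — | boundary convention; both readings of "at least x-fold" occur in practice, so the choice is explicit and echoed into `run_metadata.tsv` |
| `pseudocount` | `derived` | intensity fraction | ε = min positive median / 100; `fixed` reproduces an externally stated ε |
| QC policy | drop contaminant + reverse, keep only-by-site | — | standard MaxQuant hygiene; all three switches independent so row counts can be reconciled with any published filtering |
| enrichment background | detected proteins | — | the natural universe for "is this unique-binder set special among what the experiment could have seen"; a supplied gene list (e.g. all annotated genes) widens the universe and shrinks p-values |

Boundary semantics interact with the pseudocount: a protein absent from
bait and control has fold change exactly 1 and is never called; a protein
sitting exactly on both thresholds is called under `≥` but not `>`.

Ranking within a candidate list is by descending normalized median in
the bait condition (ties: descending fold change over `C`, then
identifier). Ranking by the bait condition — rather than an average over
conditions — orders candidates by how much material the bait actually
recovered, which is the quantity the screen measures.

## What the synthetic generator emulates — and what it does not

`simulate_pulldown()` draws a latent per-protein abundance from a
log-normal with `base_sdlog = 2` (natural-log scale), giving the 4–6
orders of magnitude of dynamic range typical of iBAQ tables. Each sample
value is `base × condition multiplier × exp(N(0, log_sigma²))`, then
dropout zeroes values at rate `dropout` (uniformly by default; an
`intensity` mode makes low-abundance values drop out preferentially via a
logistic in log-intensity, calibrated so the overall rate still equals
`dropout`). Bead-sticky proteins carry a constant multiplier in *every*
condition, so their fold change over beads is centred on 1 and the
pipeline correctly ignores them. Planted unique readers carry
`effect_size` only in their cognate bait; shared readers in all four
modified baits.

Default conditions are chosen once to match the screen being emulated:
6 conditions × 3 replicates; planted unique readers at the
per-modification scale the original screen reported (143, 62, 81, 33);
`effect_size = 4` (a clear but not extreme binding preference);
`log_sigma = 0.3`, i.e. ~30% replicate CV, typical for biological
replicates in label-free proteomics; `dropout = 0.1`.

The generator does **not** emulate: peptide-level identification and
protein inference, shared-peptide artefacts, match-between-runs,
condition-correlated batch effects, or compositional distortion from a
bait capturing a large fraction of total signal. Passing recovery tests
therefore shows the *procedure* behaves correctly under a realistic noise
model — not that any particular real screen has this error structure.

## Numerical choices and degenerate inputs

* Normalization refuses an all-zero sample (nothing to normalize) and
  names it; the denominator is computed over retained (post-QC) proteins
  only, since filtering precedes all analysis.
* Column-stochasticity holds to 1e-9 relative; all downstream quantities
  are invariant to rescaling any sample by a positive constant (this is a
  tested property, not an aspiration).
* `derived` ε errors on an all-zero median table rather than guessing.
* The hypergeometric test is exact (`P(X ≥ k)` by the distribution
  function, no normal approximation); BH adjustment is the standard
  step-up rule clipped at 1.
* The motif scanner validates sequences over the 20-letter alphabet plus
  `X`; `X` never satisfies a constrained pattern position but may sit
  under an `x` (any-residue) position. Overlapping matches are all
  reported; machine output is 0-based half-open.
* Identifier matching everywhere is exact-string after case
  normalization; no alias or orthology resolution is attempted — users
  supply annotation and FASTA files already mapped to the screen's gene
  names.

## Design choices that were genuinely open

* **Protein identity** is the proteinGroups row key; gene names are
  carried for reporting and joining but rows are never collapsed to
  genes, since the screen quantifies protein groups.
* **Zeros are measured values.** iBAQ tables encode non-detection as 0;
  removing them would bias medians upward for sporadically detected
  proteins, so zeros participate in medians as zeros.
* **The interface is R functions plus a thin script.** The pipeline is a
  file-in/file-out tool, so a small CLI wrapper ships in
  `inst/scripts/modreader.R`; all logic lives in exported, testable
  functions.
* **Phenotype enrichment is generic.** Any term → gene-set collection in
  GMT format is accepted; the module makes no attempt to reproduce a
  specific annotation service's corpus or slimming rules, which would pin
  the package to a network resource and a snapshot date.
* **RNP1/RNP2 patterns are data, not code.** The shipped defaults are the
  standard RRM literature consensus; a two-column pattern file overrides
  them completely.

## Known limitations

* Threshold-only calling has no false-discovery-rate control. With three
  replicates and ~30% replicate CV, the ratio of two medians is noisy
  (the log fold change has standard deviation ≈ 0.28), so roughly 0.5–1%
  of background proteins cross both default thresholds per modification —
  the package's own null-calibration benchmark (reader-free simulated
  screens, 20 seeds; also recomputed by `scripts/acceptance.R`) measures
  this directly. Consequently unique-binder lists from screens of ~2000
  proteins should be expected to contain a handful of noise-driven
  entries per modification, and precision of unique-binder recovery in
  the moderate-noise benchmark sits just below 0.9. Users wanting
  inferential control should treat the candidate lists as a screening
  stage and follow up orthogonally (as validation pulldowns do).
* Pseudocount-inflated ratios: a protein detected in a bait but zero in
  one control gets a very large fold change against that control. This is
  the intended behaviour of the ε rule, but it means "absent in control"
  and "strongly enriched" are not distinguished in the fold-change value
  itself; the candidate table retains the per-condition medians so such
  cases remain visible.
* Benchmark problem sizes: the test suite exercises the oracle-equivalence
  and invariance properties on small random tables (10–30 proteins, 18
  samples, hundreds of repetitions) and the recovery/null benchmarks on
  2000-background-protein screens over 20 seeds — sizes chosen to probe
  the statistics well while keeping the suite quick to run routinely.
* The enrichment test assumes genes are exchangeable under the null
  (standard for a hypergeometric over-representation test); correlated
  annotation structure is not modelled.
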