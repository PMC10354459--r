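# The quantitative core of the screen: per-sample total-intensity
# normalization, per-condition replicate medians, a data-derived
# pseudocount, fold changes against the beads-only and unmodified-C
# controls, dual-threshold candidate calling, and ranking.

#' Total-intensity normalization of iBAQ values
#'
#' Divides each sample's iBAQ values by that sample's total intensity over
#' the retained (post-QC-filter) proteins, giving a column-stochastic
#' matrix of unitless fractions. Zeros ("not detected") stay zero, and the
#' result is invariant to rescaling any sample by a positive constant.
#'
#' @param pg A [protein_groups()] object.
#' @param design A `sample_design`; normalization is restricted to, and
#'   ordered by, the design's samples.
#' @return Numeric matrix (protein x sample), each column summing to 1.
#' @export
normalize_total_intensity <- function(pg, design) {
  design <- as_sample_design(design)
  missing_samples <- setdiff(design$sample_id, colnames(pg$intensities))
  if (length(missing_samples) > 0) {
    abort_mr("design mismatch: no intensity column for sample(s) %s",
             paste(missing_samples, collapse = ", "))
  }
  m <- pg$intensities[, design$sample_id, drop = FALSE]
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort_mr("cannot normalize: sample(s) %s have zero total intensity",
             paste(design$sample_id[totals <= 0], collapse = ", "))
  }
  sweep(m, 2, totals, "/")
}

#' Per-condition medians over biological replicates
#'
#' For each protein and condition, the median of the normalized values over
#' that condition's replicates. Zeros count as measured values; for an even
#' replicate count the midpoint of the two central values is used
#' (`stats::median`).
#'
#' @param norm Normalized matrix from [normalize_total_intensity()].
#' @param design The matching `sample_design`.
#' @return Numeric matrix, protein x condition, conditions in
#'   [bait_conditions()] order.
#' @export
median_by_condition <- function(norm, design) {
  design <- as_sample_design(design)
  conds <- bait_conditions()
  out <- matrix(0, nrow = nrow(norm), ncol = length(conds),
                dimnames = list(rownames(norm), conds))
  for (cond in conds) {
    cols <- design$sample_id[design$condition == cond]
    out[, cond] <- apply(norm[, cols, drop = FALSE], 1, stats::median)
  }
  out
}

#' Pseudocount for fold-change stabilization
#'
#' In `derived` mode the pseudocount is 100-fold smaller than the smallest
#' positive median in the table (zeros are excluded, otherwise the derived
#' value would itself be zero and could not stabilize ratios). `fixed` mode
#' uses a supplied value, e.g. to reproduce a previously reported epsilon.
#'
#' @param medians Matrix from [median_by_condition()].
#' @param mode `"derived"` (default) or `"fixed"`.
#' @param value The epsilon to use in `fixed` mode; must be > 0.
#' @return A single positive number.
#' @export
compute_pseudocount <- function(medians, mode = c("derived", "fixed"), value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(value) || !is.numeric(value) || length(value) != 1L ||
        !is.finite(value) || value <= 0) {
      abort_mr("fixed pseudocount requires a single positive value")
    }
    return(as.numeric(value))
  }
  pos <- medians[medians > 0]
  if (length(pos) == 0) {
    abort_mr("cannot derive pseudocount: all medians are zero")
  }
  min(pos) / 100
}

#' Fold changes against both controls
#'
#' For each protein and modification M, computes
#' `fc_beads = (median_M + eps) / (median_beads + eps)` and
#' `fc_unmod = (median_M + eps) / (median_C + eps)`. The pseudocount is
#' added to every median (numerator and denominator alike), so all ratios
#' are finite and a protein absent from both bait and control has fold
#' change exactly 1.
#'
#' @param medians Matrix from [median_by_condition()].
#' @param epsilon Positive pseudocount (see [compute_pseudocount()]).
#' @return Object of class `fold_change_table`: list with matrices
#'   `fc_beads`, `fc_unmod` (protein x modification) and the `epsilon`
#'   used.
#' @export
compute_fold_changes <- function(medians, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    abort_mr("epsilon must be a single positive number")
  }
  mods <- rna_modifications()
  fc_beads <- (medians[, mods, drop = FALSE] + epsilon) /
    (medians[, "beads"] + epsilon)
  fc_unmod <- (medians[, mods, drop = FALSE] + epsilon) /
    (medians[, "C"] + epsilon)
  structure(list(fc_beads = fc_beads, fc_unmod = fc_unmod, epsilon = epsilon),
            class = "fold_change_table")
}

#' Call candidate readers by dual fold-change thresholds
#'
#' A protein is a candidate reader of modification M when its fold change
#' over the beads-only control and over the unmodified-C control both meet
#' their thresholds (defaults 2.0 and 1.5). With `strict = FALSE`
#' (default) the comparison is `>=` ("at least"); `strict = TRUE` uses `>`.
#' Both boundary conventions are supported because either reading is
#' defensible for values landing exactly on a threshold.
#'
#' @param fct A `fold_change_table`.
#' @param t_beads Threshold against the beads-only control (> 0).
#' @param t_unmod Threshold against the unmodified-C control (> 0).
#' @param strict Use `>` instead of `>=` at the boundary.
#' @return Logical matrix, protein x modification.
#' @export
classify_candidates <- function(fct, t_beads = 2.0, t_unmod = 1.5, strict = FALSE) {
  if (t_beads <= 0 || t_unmod <= 0) abort_mr("thresholds must be > 0")
  if (strict) {
    fct$fc_beads > t_beads & fct$fc_unmod > t_unmod
  } else {
    fct$fc_beads >= t_beads & fct$fc_unmod >= t_unmod
  }
}

#' Rank the candidate readers of one modification
#'
#' Candidates are ordered by descending median normalized iBAQ in the bait
#' condition of that modification; ties are broken by descending fold
#' change over the unmodified control, then by `group_id`.
#'
#' @param medians Matrix from [median_by_condition()].
#' @param fct The `fold_change_table`.
#' @param calls Logical call matrix from [classify_candidates()].
#' @param modification One of [rna_modifications()].
#' @return Character vector of `group_id`s, best candidate first (empty if
#'   there are no candidates).
#' @export
rank_candidates <- function(medians, fct, calls, modification) {
  if (!modification %in% rna_modifications()) {
    abort_mr("unknown modification '%s'", modification)
  }
  ids <- rownames(calls)[calls[, modification]]
  if (length(ids) == 0) return(character(0))
  med <- medians[ids, modification]
  fcu <- fct$fc_unmod[ids, modification]
  ids[order(-med, -fcu, ids)]
}
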