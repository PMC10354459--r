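# Reading and validation of MaxQuant-style proteinGroups tables and
# sample-design files, and writing of the ranked candidate table.

#' Quality-control filtering policy for proteinGroups rows
#'
#' MaxQuant flags protein groups that are potential contaminants, decoy
#' ("reverse") hits, or identified only by a modification site. The default
#' policy drops contaminant and reverse rows and keeps only-by-site rows;
#' each switch is independent so that row counts can be reconciled against
#' any published filtering choice.
#'
#' @param drop_contaminant Drop rows flagged `Potential contaminant`.
#' @param drop_reverse Drop rows flagged `Reverse` (decoy database hits).
#' @param drop_only_by_site Drop rows flagged `Only identified by site`.
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(drop_contaminant = TRUE, drop_reverse = TRUE,
                      drop_only_by_site = FALSE) {
  for (v in list(drop_contaminant, drop_reverse, drop_only_by_site)) {
    if (!is.logical(v) || length(v) != 1L || is.na(v)) {
      abort_mr("qc_policy switches must be single TRUE/FALSE values")
    }
  }
  structure(list(drop_contaminant = drop_contaminant,
                 drop_reverse = drop_reverse,
                 drop_only_by_site = drop_only_by_site),
            class = "qc_policy")
}

#' Construct a protein-groups container
#'
#' Bundles per-protein annotation with the protein x sample iBAQ intensity
#' matrix. Zero intensities are kept: in iBAQ tables a zero encodes
#' "not detected" and the downstream medians are taken over all replicates.
#'
#' @param info Data frame with columns `group_id`, `gene_name`,
#'   `majority_ids`, `is_contaminant`, `is_reverse`, `is_only_by_site`.
#' @param intensities Numeric matrix, one row per protein (rownames =
#'   `group_id`), one column per sample; all entries must be finite and
#'   non-negative.
#' @param dropped Named integer vector of row counts removed by QC
#'   filtering (bookkeeping only).
#' @return An object of class `protein_groups` with elements `info`,
#'   `intensities` and `dropped`.
#' @export
protein_groups <- function(info, intensities, dropped = c(total = 0L)) {
  needed <- c("group_id", "gene_name", "majority_ids",
              "is_contaminant", "is_reverse", "is_only_by_site")
  miss <- setdiff(needed, names(info))
  if (length(miss) > 0) {
    abort_mr("protein info is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(info$group_id)) {
    abort_mr("group_id values must be unique within a table")
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != nrow(info)) {
    abort_mr("intensity matrix has %d rows but info has %d", nrow(intensities), nrow(info))
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    abort_mr("intensities must all be finite and >= 0")
  }
  rownames(intensities) <- info$group_id
  structure(list(info = info, intensities = intensities, dropped = dropped),
            class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("protein_groups: %d proteins x %d samples (%d rows dropped by QC)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$dropped[setdiff(names(x$dropped), "total")])))
  invisible(x)
}

# "+" marks a set MaxQuant flag; absent column means the flag is never set
flag_column <- function(raw, candidates) {
  hit <- intersect(candidates, names(raw))
  if (length(hit) == 0) return(rep(FALSE, nrow(raw)))
  trimws(raw[[hit[1]]]) == "+"
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-delimited proteinGroups table, locates per-sample iBAQ
#' columns by a configurable prefix, applies the QC [qc_policy()], and
#' returns a [protein_groups()] container. Every intensity cell must parse
#' to a finite non-negative number; anything else (including `NaN`, blanks
#' or text) is a parse error naming the offending row and column, so silent
#' coercion can never corrupt a screen.
#'
#' @param path Path to the tab-delimited table (UTF-8, header row).
#' @param qc A [qc_policy()] deciding which flagged rows to drop.
#' @param ibaq_prefix Column-name prefix identifying per-sample iBAQ
#'   columns; the sample id is the column name with the prefix removed.
#' @param design Optional [read_design()] result. When supplied, every
#'   sample in the design must have an iBAQ column (otherwise a design
#'   mismatch error) and the intensity matrix is restricted to, and ordered
#'   by, the design's samples. An explicit design takes precedence over
#'   prefix auto-detection.
#' @return A `protein_groups` object. The attribute `column_map` records
#'   the sample id to source-column mapping.
#' @export
read_protein_groups <- function(path, qc = qc_policy(), ibaq_prefix = "iBAQ ",
                                design = NULL) {
  if (!file.exists(path)) abort_mr("proteinGroups file not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) == 0L) {
    abort_mr("format error: %s has no parseable header/data (tab-delimited table expected)", path)
  }

  ibaq_cols <- names(raw)[startsWith(names(raw), ibaq_prefix) &
                            names(raw) != sub(" $", "", ibaq_prefix)]
  if (length(ibaq_cols) == 0) {
    abort_mr("format error: no column starts with iBAQ prefix '%s'", ibaq_prefix)
  }
  sample_ids <- substring(ibaq_cols, nchar(ibaq_prefix) + 1L)

  if (!is.null(design)) {
    design <- as_sample_design(design)
    missing_samples <- setdiff(design$sample_id, sample_ids)
    if (length(missing_samples) > 0) {
      abort_mr("design mismatch: no iBAQ column for sample(s) %s",
               paste(missing_samples, collapse = ", "))
    }
    keep <- match(design$sample_id, sample_ids)
    ibaq_cols <- ibaq_cols[keep]
    sample_ids <- sample_ids[keep]
  }

  n <- nrow(raw)
  group_id <- if ("id" %in% names(raw)) raw[["id"]] else if
    ("Protein IDs" %in% names(raw)) raw[["Protein IDs"]] else as.character(seq_len(n))
  if (anyDuplicated(group_id)) {
    abort_mr("group_id values (column 'id'/'Protein IDs') are not unique")
  }

  gene_name <- if ("Gene names" %in% names(raw)) raw[["Gene names"]] else rep("", n)
  majority <- if ("Majority protein IDs" %in% names(raw)) raw[["Majority protein IDs"]]
    else if ("Protein IDs" %in% names(raw)) raw[["Protein IDs"]] else group_id

  info <- data.frame(
    group_id = group_id,
    gene_name = gene_name,
    majority_ids = majority,
    is_contaminant = flag_column(raw, c("Potential contaminant", "Contaminant")),
    is_reverse = flag_column(raw, "Reverse"),
    is_only_by_site = flag_column(raw, "Only identified by site"),
    stringsAsFactors = FALSE
  )

  mat <- matrix(0, nrow = n, ncol = length(ibaq_cols),
                dimnames = list(group_id, sample_ids))
  for (j in seq_along(ibaq_cols)) {
    cell <- trimws(raw[[ibaq_cols[j]]])
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.finite(val) | val < 0)
    if (length(bad) > 0) {
      abort_mr("parse error: non-numeric or negative intensity '%s' at data row %d, column '%s'",
               cell[bad[1]], bad[1], ibaq_cols[j])
    }
    mat[, j] <- val
  }

  drop <- (qc$drop_contaminant & info$is_contaminant) |
    (qc$drop_reverse & info$is_reverse) |
    (qc$drop_only_by_site & info$is_only_by_site)
  dropped <- c(contaminant = sum(qc$drop_contaminant & info$is_contaminant),
               reverse = sum(qc$drop_reverse & info$is_reverse),
               only_by_site = sum(qc$drop_only_by_site & info$is_only_by_site),
               total = sum(drop))

  pg <- protein_groups(info[!drop, , drop = FALSE], mat[!drop, , drop = FALSE],
                       dropped = dropped)
  attr(pg, "column_map") <- stats::setNames(ibaq_cols, sample_ids)
  pg
}

#' Validate an in-memory sample design
#'
#' @param df Data frame with columns `sample_id`, `condition`, `replicate`.
#' @return The validated design, class `sample_design`. Sample ids must be
#'   unique, every condition of [bait_conditions()] must be present, and
#'   replicates must be positive integers.
#' @export
as_sample_design <- function(df) {
  if (inherits(df, "sample_design")) return(df)
  needed <- c("sample_id", "condition", "replicate")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    abort_mr("design is missing column(s): %s", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  if (anyDuplicated(df$sample_id)) {
    abort_mr("duplicate sample_id in design: %s",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  unknown <- setdiff(unique(df$condition), bait_conditions())
  if (length(unknown) > 0) {
    abort_mr("unknown condition label(s) in design: %s (allowed: %s)",
             paste(unknown, collapse = ", "), paste(bait_conditions(), collapse = ", "))
  }
  absent <- setdiff(bait_conditions(), unique(df$condition))
  if (length(absent) > 0) {
    abort_mr("design must contain every condition; missing: %s",
             paste(absent, collapse = ", "))
  }
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    abort_mr("replicate must be a positive integer for every sample")
  }
  df <- df[, needed]
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Read a sample-design file
#'
#' @param path Tab-delimited file with columns `sample_id`, `condition`
#'   (one of [bait_conditions()]) and `replicate`.
#' @return A validated `sample_design` data frame (see [as_sample_design()]).
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort_mr("design file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_sample_design(df)
}

#' Write the ranked candidate table
#'
#' One row per retained protein with identifiers, per-condition normalized
#' medians, fold changes against both controls, candidate flags per
#' modification and the unique-binder label. Rows are ordered by descending
#' rank (maximum bait-condition median), ties broken by `group_id`, so the
#' output is deterministic.
#'
#' @param pg A [protein_groups()] object.
#' @param medians Matrix from [median_by_condition()].
#' @param fct [compute_fold_changes()] result.
#' @param calls Logical call matrix from [classify_candidates()].
#' @param unique_sets [unique_binders()] result.
#' @param path Output path (tab-delimited).
#' @return Invisibly, the written data frame.
#' @export
write_candidate_table <- function(pg, medians, fct, calls, unique_sets, path) {
  ids <- pg$info$group_id
  for (m in list(rownames(medians), rownames(fct$fc_beads), rownames(calls))) {
    if (!identical(m, ids)) {
      abort_mr("key mismatch: inputs do not share the protein key space")
    }
  }
  mods <- rna_modifications()
  uniq_label <- rep("", length(ids))
  for (m in mods) uniq_label[ids %in% unique_sets$unique[[m]]] <- m

  out <- data.frame(group_id = ids, gene_name = pg$info$gene_name,
                    majority_ids = pg$info$majority_ids,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (cond in colnames(medians)) out[[paste0("median_", cond)]] <- medians[, cond]
  for (m in mods) out[[paste0("fc_beads_", m)]] <- fct$fc_beads[, m]
  for (m in mods) out[[paste0("fc_unmod_", m)]] <- fct$fc_unmod[, m]
  for (m in mods) out[[paste0("candidate_", m)]] <- calls[, m]
  out$unique_binder <- uniq_label

  rank_basis <- apply(medians[, mods, drop = FALSE], 1, max)
  ord <- order(-rank_basis, out$group_id)
  out <- out[ord, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
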