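# Unique-binder classification and full four-set overlap structure.

# canonical label for a subset of modifications, e.g. "m5C+hm5Cm"
region_label <- function(mods) paste(mods, collapse = "+")

# all 15 nonempty subsets of the four modifications, canonical order
all_region_labels <- function() {
  mods <- rna_modifications()
  labels <- character(0)
  for (k in seq_along(mods)) {
    labels <- c(labels, apply(utils::combn(mods, k), 2, region_label))
  }
  labels
}

#' Derive unique binders and Venn region counts from candidate calls
#'
#' A unique binder of modification M is a protein called candidate for M
#' and for no other modification. The 15 Venn regions partition all
#' proteins called for at least one modification by their exact call
#' subset; proteins with zero calls belong to no region.
#'
#' @param calls Logical matrix (protein x modification) from
#'   [classify_candidates()]; all four modifications must be present as
#'   columns.
#' @return Object of class `unique_binder_sets`: list with
#'   * `unique`: named list of four pairwise-disjoint `group_id` vectors;
#'   * `overlap_counts`: named integer vector over all 15 regions (zeros
#'     included);
#'   * `membership`: data frame (`group_id`, `region`) for every protein
#'     with at least one call.
#' @export
unique_binders <- function(calls) {
  mods <- rna_modifications()
  if (!all(mods %in% colnames(calls))) {
    abort_mr("calls must have one column per modification: %s",
             paste(mods, collapse = ", "))
  }
  calls <- calls[, mods, drop = FALSE] & TRUE   # coerce to logical matrix
  if (any(is.na(calls))) abort_mr("calls must not contain NA")

  called_any <- rowSums(calls) > 0
  region <- apply(calls[called_any, , drop = FALSE], 1, function(row) {
    region_label(mods[row])
  })
  membership <- data.frame(group_id = rownames(calls)[called_any],
                           region = as.character(region),
                           stringsAsFactors = FALSE)

  counts <- stats::setNames(integer(length(all_region_labels())), all_region_labels())
  tab <- table(membership$region)
  counts[names(tab)] <- as.integer(tab)

  uniq <- lapply(mods, function(m) {
    membership$group_id[membership$region == m]
  })
  names(uniq) <- mods

  structure(list(unique = uniq, overlap_counts = counts, membership = membership),
            class = "unique_binder_sets")
}

#' @export
print.unique_binder_sets <- function(x, ...) {
  sizes <- vapply(x$unique, length, integer(1))
  cat("unique binders:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
      sprintf("(%d proteins in >=1 region)\n", nrow(x$membership)))
  invisible(x)
}

#' Write Venn region counts
#'
#' @param unique_sets A `unique_binder_sets` object.
#' @param path Output path; tab-delimited with columns `region` (sorted
#'   modification list joined by `+`) and `count`.
#' @return Invisibly, the written data frame.
#' @export
write_venn_counts <- function(unique_sets, path) {
  out <- data.frame(region = names(unique_sets$overlap_counts),
                    count = as.integer(unique_sets$overlap_counts),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write ranked unique binders per modification
#'
#' @param unique_sets A `unique_binder_sets` object.
#' @param pg The matching [protein_groups()] object (for gene names).
#' @param medians,fct,calls Outputs of the enrichment chain, used for
#'   within-modification ranking via [rank_candidates()].
#' @param path Output path; columns `modification`, `group_id`,
#'   `gene_name`, `rank`.
#' @return Invisibly, the written data frame.
#' @export
write_unique_binders <- function(unique_sets, pg, medians, fct, calls, path) {
  rows <- list()
  for (m in rna_modifications()) {
    ranked <- rank_candidates(medians, fct, calls, m)
    ranked <- ranked[ranked %in% unique_sets$unique[[m]]]
    if (length(ranked) == 0) next
    rows[[m]] <- data.frame(
      modification = m,
      group_id = ranked,
      gene_name = pg$info$gene_name[match(ranked, pg$info$group_id)],
      rank = seq_along(ranked),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(modification = character(0), group_id = character(0),
               gene_name = character(0), rank = integer(0))
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
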