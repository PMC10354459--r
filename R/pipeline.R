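# End-to-end orchestration: read -> normalize -> medians -> pseudocount ->
# fold changes -> classify -> unique sets -> optional phenotype enrichment
# and RRM motif flags, with every output written to a directory and all
# parameters echoed into run metadata so published counts can be
# reconciled against parameter choices.

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full reader-screen pipeline
#'
#' Executes the whole analysis on a proteinGroups table and sample design,
#' writing `candidates.tsv`, `unique_binders.tsv`, `venn_counts.tsv`,
#' optionally `enrichment.tsv` (when annotation sets are supplied) and
#' `rrm_flags.tsv` (when a FASTA is supplied), plus `run_metadata.tsv`
#' recording every parameter, the pseudocount used and row counts per
#' stage. All input paths are validated before any computation starts, and
#' identical inputs and configuration give byte-identical outputs.
#'
#' @param protein_groups_path MaxQuant-style proteinGroups table.
#' @param design_path Sample-design file (see [read_design()]).
#' @param out_dir Output directory (created if needed).
#' @param annotation_path Optional GMT annotation file for phenotype
#'   enrichment of each unique-binder set.
#' @param background_path Optional background gene list; default
#'   background is every gene detected in the experiment (all rows
#'   surviving QC).
#' @param fasta_path Optional protein FASTA for RNP1/RNP2 motif flagging.
#' @param qc QC policy, see [qc_policy()].
#' @param t_beads,t_unmod,strict Candidate thresholds and boundary mode,
#'   see [classify_candidates()].
#' @param pseudocount `"derived"` or `"fixed"`, see [compute_pseudocount()].
#' @param pseudocount_value Epsilon for `pseudocount = "fixed"`.
#' @param ibaq_prefix iBAQ column prefix in the proteinGroups table.
#' @param enrich_q_cutoff BH-adjusted significance cutoff echoed into the
#'   enrichment output's `enriched` flag.
#' @param motif_patterns Named degenerate patterns for the motif scan.
#' @param verbose Emit a structured log line (row counts) per stage.
#' @return Invisibly, a list with every intermediate result
#'   (`protein_groups`, `design`, `normalized`, `medians`, `epsilon`,
#'   `fold_changes`, `calls`, `unique_sets`, `enrichment`, `rrm`,
#'   `metadata`, `paths`).
#' @export
run_pipeline <- function(protein_groups_path, design_path, out_dir,
                         annotation_path = NULL, background_path = NULL,
                         fasta_path = NULL, qc = qc_policy(),
                         t_beads = 2.0, t_unmod = 1.5, strict = FALSE,
                         pseudocount = c("derived", "fixed"),
                         pseudocount_value = NULL, ibaq_prefix = "iBAQ ",
                         enrich_q_cutoff = 0.05,
                         motif_patterns = default_rnp_patterns(),
                         verbose = TRUE) {
  pseudocount <- match.arg(pseudocount)
  inputs <- c(protein_groups = protein_groups_path, design = design_path,
              annotation = annotation_path, background = background_path,
              fasta = fasta_path)
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      abort_mr("input '%s' does not exist: %s", nm, inputs[[nm]])
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  design <- read_design(design_path)
  pg <- read_protein_groups(protein_groups_path, qc = qc,
                            ibaq_prefix = ibaq_prefix, design = design)
  stage_log(verbose, "[read] %d proteins retained, %d dropped by QC (%d samples)",
            nrow(pg$intensities), pg$dropped[["total"]], nrow(design))

  norm <- normalize_total_intensity(pg, design)
  medians <- median_by_condition(norm, design)
  epsilon <- compute_pseudocount(medians, mode = pseudocount,
                                 value = pseudocount_value)
  fct <- compute_fold_changes(medians, epsilon)
  calls <- classify_candidates(fct, t_beads = t_beads, t_unmod = t_unmod,
                               strict = strict)
  stage_log(verbose, "[classify] epsilon=%.3g; candidates per modification: %s",
            epsilon, paste(sprintf("%s=%d", colnames(calls), colSums(calls)),
                           collapse = ", "))

  ubs <- unique_binders(calls)
  stage_log(verbose, "[sets] unique binders: %s",
            paste(sprintf("%s=%d", names(ubs$unique),
                          lengths(ubs$unique)), collapse = ", "))

  paths <- list(candidates = file.path(out_dir, "candidates.tsv"),
                unique_binders = file.path(out_dir, "unique_binders.tsv"),
                venn_counts = file.path(out_dir, "venn_counts.tsv"),
                metadata = file.path(out_dir, "run_metadata.tsv"))
  write_candidate_table(pg, medians, fct, calls, ubs, paths$candidates)
  write_unique_binders(ubs, pg, medians, fct, calls, paths$unique_binders)
  write_venn_counts(ubs, paths$venn_counts)

  enrichment <- NULL
  if (!is.null(annotation_path)) {
    terms <- read_gmt(annotation_path)
    background <- if (!is.null(background_path)) read_gene_list(background_path)
      else pg$info$gene_name[nzchar(pg$info$gene_name)]
    ann <- annotation_sets(terms, background)
    per_mod <- list()
    for (m in rna_modifications()) {
      genes <- pg$info$gene_name[match(ubs$unique[[m]], pg$info$group_id)]
      genes <- genes[nzchar(genes)]
      effective <- intersect(unique(norm_gene(genes)), ann$background)
      if (length(effective) == 0) {
        stage_log(verbose, "[enrich] %s: no unique binder maps onto the background; skipped", m)
        next
      }
      res <- enrich(genes, ann)
      res <- cbind(modification = m, res, stringsAsFactors = FALSE)
      res$enriched <- res$q <= enrich_q_cutoff
      per_mod[[m]] <- res
    }
    enrichment <- if (length(per_mod) > 0) do.call(rbind, per_mod) else
      data.frame(modification = character(0), term_id = character(0),
                 term_name = character(0), k = integer(0), K = integer(0),
                 n = integer(0), N = integer(0), p = numeric(0),
                 q = numeric(0), enriched = logical(0))
    rownames(enrichment) <- NULL
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(enrichment, paths$enrichment, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage_log(verbose, "[enrich] %d term tests written", nrow(enrichment))
  }

  rrm <- NULL
  if (!is.null(fasta_path)) {
    seqs <- read_protein_fasta(fasta_path)
    rrm <- flag_rrm_candidates(ubs, seqs, pg, patterns = motif_patterns)
    flags <- rrm$flags
    flags$has_sequence <- TRUE
    if (nrow(rrm$unmatched) > 0) {
      un <- rrm$unmatched
      un$has_RNP1 <- NA
      un$has_RNP2 <- NA
      un$has_sequence <- FALSE
      flags <- rbind(flags, un)
    }
    paths$rrm_flags <- file.path(out_dir, "rrm_flags.tsv")
    utils::write.table(flags, paths$rrm_flags, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage_log(verbose, "[motif] %d candidates scanned, %d without sequence",
              nrow(rrm$flags), nrow(rrm$unmatched))
  }

  metadata <- data.frame(
    key = c("package_version", "t_beads", "t_unmod", "boundary",
            "pseudocount_mode", "epsilon", "qc_drop_contaminant",
            "qc_drop_reverse", "qc_drop_only_by_site", "ibaq_prefix",
            "n_proteins_retained", "n_rows_dropped", "n_samples",
            "enrich_q_cutoff"),
    value = c(as.character(utils::packageVersion("modreader")),
              format(t_beads), format(t_unmod),
              if (strict) "strict (>)" else "inclusive (>=)",
              pseudocount, format(epsilon, digits = 15),
              qc$drop_contaminant, qc$drop_reverse, qc$drop_only_by_site,
              ibaq_prefix, nrow(pg$intensities), pg$dropped[["total"]],
              nrow(design), format(enrich_q_cutoff)),
    stringsAsFactors = FALSE
  )
  utils::write.table(metadata, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(protein_groups = pg, design = design, normalized = norm,
                 medians = medians, epsilon = epsilon, fold_changes = fct,
                 calls = calls, unique_sets = ubs, enrichment = enrichment,
                 rrm = rrm, metadata = metadata, paths = paths))
}

#' Simulate a pulldown dataset to disk
#'
#' Thin wrapper over [simulate_pulldown()] + [write_synthetic()]: writes
#' `proteinGroups.tsv`, `truth.tsv` and `design.tsv` into `out_dir`.
#' Identical parameters and seed give byte-identical files.
#'
#' @param out_dir Output directory.
#' @param params A [synth_params()] object.
#' @return Invisibly, the written file paths.
#' @export
simulate_pulldown_files <- function(out_dir, params = synth_params()) {
  sim <- simulate_pulldown(params)
  write_synthetic(sim, out_dir)
}
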