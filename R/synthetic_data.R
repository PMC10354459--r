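# Synthetic proteinGroups-like datasets with planted ground truth, and
# recovery scoring. The generator emulates the screen's design: 6
# conditions (beads, C, four modified baits) x 3 biological replicates,
# heavy-tailed protein abundances, multiplicative log-normal replicate
# noise, bead-sticky contaminants elevated in every pulldown, and missing
# values recorded as zero.

#' Parameters for the synthetic pulldown generator
#'
#' Defaults describe a realistic whole-lysate screen: a few thousand
#' background proteins with log-normal (heavy-tailed) abundance, a modest
#' bead-sticky contingent, planted unique readers at the per-modification
#' scale the original screen observed, 3 replicates per condition, ~4-fold
#' binding effects, replicate noise of 0.3 on the natural-log scale and
#' 10% random non-detection.
#'
#' @param n_background Proteins binding nothing preferentially.
#' @param n_bead_sticky Proteins elevated in every sample including the
#'   beads-only control (nonspecific matrix binders).
#' @param n_unique_per_mod Planted unique readers per modification: a
#'   single count recycled across the four modifications, or a length-4
#'   vector in [rna_modifications()] order. The default plants the
#'   per-modification scale observed in the original screen
#'   (143, 62, 81, 33).
#' @param n_shared Planted readers of all four modified baits.
#' @param effect_size Fold multiplier applied in the cognate bait
#'   condition(s); must be > 1.
#' @param bead_sticky_factor Fold multiplier applied to bead-sticky
#'   proteins in every condition.
#' @param log_sigma Replicate noise SD on natural-log intensities.
#' @param dropout Probability that a measured value is recorded as 0.
#' @param dropout_mode `"uniform"` (intensity-independent, default) or
#'   `"intensity"` (logistic in log-intensity: low-abundance measurements
#'   drop out preferentially, calibrated so the overall rate equals
#'   `dropout`).
#' @param replicates Biological replicates per condition.
#' @param base_meanlog,base_sdlog Log-normal parameters of the latent
#'   per-protein base abundance (arbitrary iBAQ-like units).
#' @param seed Integer seed; identical parameters and seed give an
#'   identical dataset.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(n_background = 2000, n_bead_sticky = 100,
                         n_unique_per_mod = c(143, 62, 81, 33), n_shared = 25,
                         effect_size = 4, bead_sticky_factor = 8,
                         log_sigma = 0.3, dropout = 0.1,
                         dropout_mode = c("uniform", "intensity"),
                         replicates = 3, base_meanlog = log(1e6),
                         base_sdlog = 2, seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  if (!length(n_unique_per_mod) %in% c(1L, 4L)) {
    abort_mr("n_unique_per_mod must have length 1 or 4")
  }
  n_unique_per_mod <- rep_len(n_unique_per_mod, 4L)
  counts <- c(n_background = n_background, n_bead_sticky = n_bead_sticky,
              n_unique_per_mod, n_shared = n_shared)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_mr("all protein counts must be nonnegative integers")
  }
  if (sum(counts) == 0) abort_mr("at least one protein must be generated")
  if (effect_size <= 1) abort_mr("effect_size must be > 1")
  if (bead_sticky_factor <= 0) abort_mr("bead_sticky_factor must be > 0")
  if (log_sigma < 0) abort_mr("log_sigma must be >= 0")
  if (dropout < 0 || dropout >= 1) abort_mr("dropout must lie in [0, 1)")
  if (replicates < 1 || replicates != floor(replicates)) {
    abort_mr("replicates must be a positive integer")
  }
  structure(list(n_background = as.integer(n_background),
                 n_bead_sticky = as.integer(n_bead_sticky),
                 n_unique_per_mod = stats::setNames(as.integer(n_unique_per_mod),
                                                    rna_modifications()),
                 n_shared = as.integer(n_shared),
                 effect_size = effect_size,
                 bead_sticky_factor = bead_sticky_factor,
                 log_sigma = log_sigma, dropout = dropout,
                 dropout_mode = dropout_mode,
                 replicates = as.integer(replicates),
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# per-sample dropout probabilities; intensity mode solves for the logistic
# midpoint t so that mean(plogis(t - logv)) equals the target rate
dropout_probs <- function(values, params) {
  if (params$dropout == 0) return(rep(0, length(values)))
  if (params$dropout_mode == "uniform") return(rep(params$dropout, length(values)))
  logv <- log(pmax(values, .Machine$double.xmin))
  f <- function(t) mean(stats::plogis(t - logv)) - params$dropout
  t <- stats::uniroot(f, lower = min(logv) - 50, upper = max(logv) + 50)$root
  stats::plogis(t - logv)
}

#' Generate a synthetic pulldown dataset with known truth
#'
#' Each protein gets a latent log-normal base abundance. A sample's value
#' is `base * condition_multiplier * exp(noise)` with `noise ~ N(0,
#' log_sigma^2)`, after which dropout zeroes values at the configured
#' rate. Unique readers carry the `effect_size` multiplier only in their
#' cognate bait, shared readers in all four modified baits, bead-sticky
#' proteins carry `bead_sticky_factor` in every sample (so their fold
#' change over beads stays near 1), and background proteins have
#' multiplier 1 throughout.
#'
#' @param params A [synth_params()] object.
#' @return List with `protein_groups` (data frame in the MaxQuant column
#'   dialect, ready to write or feed to the pipeline), `truth` (data
#'   frame `group_id`, `role`, where role is one of `background`,
#'   `bead_sticky`, `shared_reader`, `unique_<mod>`), `design` (a
#'   `sample_design`) and the `params` used.
#' @export
simulate_pulldown <- function(params = synth_params()) {
  if (!inherits(params, "synth_params")) abort_mr("params must come from synth_params()")
  set.seed(params$seed)
  mods <- rna_modifications()
  conds <- bait_conditions()

  roles <- c(rep("background", params$n_background),
             rep("bead_sticky", params$n_bead_sticky),
             rep(paste0("unique_", mods), times = params$n_unique_per_mod),
             rep("shared_reader", params$n_shared))
  n <- length(roles)
  ids <- sprintf("SYN%05d", seq_len(n))
  genes <- sprintf("sgn-%d", seq_len(n))

  mult <- matrix(1, nrow = n, ncol = length(conds), dimnames = list(ids, conds))
  mult[roles == "bead_sticky", ] <- params$bead_sticky_factor
  for (m in mods) mult[roles == paste0("unique_", m), m] <- params$effect_size
  mult[roles == "shared_reader", mods] <- params$effect_size

  design <- data.frame(
    sample_id = as.vector(t(outer(conds, seq_len(params$replicates), paste, sep = "_"))),
    condition = rep(conds, each = params$replicates),
    replicate = rep(seq_len(params$replicates), times = length(conds)),
    stringsAsFactors = FALSE
  )
  design <- as_sample_design(design)

  base <- stats::rlnorm(n, meanlog = params$base_meanlog, sdlog = params$base_sdlog)
  values <- matrix(0, nrow = n, ncol = nrow(design),
                   dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    noise <- exp(stats::rnorm(n, 0, params$log_sigma))
    values[, j] <- base * mult[, design$condition[j]] * noise
  }
  for (j in seq_len(ncol(values))) {
    p_drop <- dropout_probs(values[, j], params)
    values[stats::runif(nrow(values)) < p_drop, j] <- 0
  }

  tab <- data.frame(
    id = ids,
    `Protein IDs` = ids,
    `Majority protein IDs` = ids,
    `Gene names` = genes,
    Reverse = "",
    `Potential contaminant` = "",
    `Only identified by site` = "",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (s in design$sample_id) {
    tab[[paste0("iBAQ ", s)]] <- format(values[, s], digits = 15, trim = TRUE,
                                        scientific = TRUE)
  }

  list(protein_groups = tab,
       truth = data.frame(group_id = ids, role = roles, stringsAsFactors = FALSE),
       design = design,
       params = params)
}

#' Write a synthetic dataset to disk
#'
#' Writes `proteinGroups.tsv`, `truth.tsv` and `design.tsv` into `dir`.
#' Output is byte-identical for identical parameters and seed.
#'
#' @param sim Result of [simulate_pulldown()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(protein_groups = file.path(dir, "proteinGroups.tsv"),
             truth = file.path(dir, "truth.tsv"),
             design = file.path(dir, "design.tsv"))
  utils::write.table(sim$protein_groups, paths["protein_groups"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$design), paths["design"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Score recovery of planted unique readers
#'
#' For each modification, positives are the planted unique readers of that
#' modification; a true positive is a planted reader appearing in the
#' called unique set. Precision is TP/(TP+FP), recall TP/(TP+FN). A
#' zero-denominator precision or recall is reported as 1 with the
#' corresponding `*_defined` flag set to FALSE (the convention keeps
#' perfect empty-vs-empty comparisons from penalizing a method).
#'
#' @param unique_sets A [unique_binders()] result.
#' @param truth Truth data frame from [simulate_pulldown()].
#' @return Data frame with one row per modification: `modification`,
#'   `n_planted`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `precision_defined`, `recall_defined`.
#' @export
score_recovery <- function(unique_sets, truth) {
  rows <- lapply(rna_modifications(), function(m) {
    planted <- truth$group_id[truth$role == paste0("unique_", m)]
    called <- unique_sets$unique[[m]]
    tp <- length(intersect(called, planted))
    fp <- length(setdiff(called, planted))
    fn <- length(setdiff(planted, called))
    data.frame(
      modification = m, n_planted = length(planted), tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else 1,
      recall = if (tp + fn > 0) tp / (tp + fn) else 1,
      precision_defined = tp + fp > 0,
      recall_defined = tp + fn > 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
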