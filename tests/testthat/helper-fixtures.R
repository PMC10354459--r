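# Shared fixtures: designs, random intensity tables, in-memory containers,
# and an independent straight-line oracle for the normalization ->
# median -> pseudocount -> fold-change -> call chain (no shared code with
# the package implementation: manual column sums, sort-based medians).

make_design <- function(replicates = 3) {
  conds <- c("beads", "C", "m5C", "hm5C", "hm5Cm", "f5C")
  as_sample_design(data.frame(
    sample_id = as.vector(t(outer(conds, seq_len(replicates), paste, sep = "_"))),
    condition = rep(conds, each = replicates),
    replicate = rep(seq_len(replicates), times = length(conds)),
    stringsAsFactors = FALSE
  ))
}

random_raw <- function(n_prot, design, seed, zero_frac = 0.2) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_prot * nrow(design), meanlog = 10, sdlog = 2),
              nrow = n_prot)
  m[stats::runif(length(m)) < zero_frac] <- 0
  for (j in seq_len(ncol(m))) if (all(m[, j] == 0)) m[1, j] <- 1
  dimnames(m) <- list(sprintf("P%03d", seq_len(n_prot)), design$sample_id)
  m
}

make_pg <- function(mat) {
  protein_groups(
    info = data.frame(group_id = rownames(mat),
                      gene_name = paste0("g", seq_len(nrow(mat))),
                      majority_ids = rownames(mat),
                      is_contaminant = FALSE, is_reverse = FALSE,
                      is_only_by_site = FALSE, stringsAsFactors = FALSE),
    intensities = mat
  )
}

# Independent oracle: plain loops, sort-based median, no package calls.
oracle_chain <- function(raw, design, t_beads = 2.0, t_unmod = 1.5,
                         strict = FALSE, eps = NULL) {
  med_sorted <- function(v) {
    v <- sort(v)
    k <- length(v)
    if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
  }
  norm <- raw
  for (j in seq_len(ncol(raw))) norm[, j] <- raw[, j] / sum(raw[, j])
  conds <- c("beads", "C", "m5C", "hm5C", "hm5Cm", "f5C")
  med <- matrix(0, nrow(raw), length(conds),
                dimnames = list(rownames(raw), conds))
  for (cn in conds) {
    cols <- design$sample_id[design$condition == cn]
    for (i in seq_len(nrow(raw))) med[i, cn] <- med_sorted(norm[i, cols])
  }
  if (is.null(eps)) {
    pos <- med[med > 0]
    eps <- min(pos) / 100
  }
  mods <- conds[3:6]
  fcb <- med[, mods, drop = FALSE]
  fcu <- med[, mods, drop = FALSE]
  for (i in seq_len(nrow(med))) {
    for (m in mods) {
      fcb[i, m] <- (med[i, m] + eps) / (med[i, "beads"] + eps)
      fcu[i, m] <- (med[i, m] + eps) / (med[i, "C"] + eps)
    }
  }
  calls <- if (strict) fcb > t_beads & fcu > t_unmod else
    fcb >= t_beads & fcu >= t_unmod
  list(norm = norm, med = med, eps = eps, fcb = fcb, fcu = fcu, calls = calls)
}

# run the package's chain on an in-memory matrix
run_chain <- function(mat, design, t_beads = 2.0, t_unmod = 1.5,
                      strict = FALSE, pseudocount = "derived", eps = NULL) {
  pg <- make_pg(mat)
  norm <- normalize_total_intensity(pg, design)
  med <- median_by_condition(norm, design)
  epsilon <- compute_pseudocount(med, mode = pseudocount, value = eps)
  fct <- compute_fold_changes(med, epsilon)
  calls <- classify_candidates(fct, t_beads, t_unmod, strict)
  list(pg = pg, norm = norm, med = med, eps = epsilon, fct = fct,
       calls = calls, ubs = unique_binders(calls))
}

# numeric matrix straight from a simulated MaxQuant-dialect data frame
sim_matrix <- function(sim) {
  cols <- paste0("iBAQ ", sim$design$sample_id)
  m <- vapply(cols, function(cn) as.numeric(sim$protein_groups[[cn]]),
              numeric(nrow(sim$protein_groups)))
  dimnames(m) <- list(sim$protein_groups$id, sim$design$sample_id)
  m
}

# toy-scale strong-effect generator settings: recovery is forced
strong_params <- function(seed = 101, ...) {
  synth_params(n_background = 200, n_bead_sticky = 20, n_unique_per_mod = 5,
               n_shared = 5, effect_size = 8, log_sigma = 0.2, dropout = 0,
               seed = seed, ...)
}
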