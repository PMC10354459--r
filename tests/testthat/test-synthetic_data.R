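# Synthetic pulldown generation and recovery scoring.

small_params <- strong_params  # defined in helper-fixtures.R

test_that("parameter validation rejects degenerate settings", {
  expect_error(synth_params(effect_size = 1), "effect_size")
  expect_error(synth_params(dropout = 1), "dropout")
  expect_error(synth_params(n_background = -1), "nonnegative")
  expect_error(synth_params(n_background = 0, n_bead_sticky = 0,
                            n_unique_per_mod = 0, n_shared = 0),
               "at least one protein")
  expect_error(simulate_pulldown(list(seed = 1)), "synth_params")
})

test_that("roles partition the proteins and the design matches the layout", {
  sim <- simulate_pulldown(small_params())
  expect_equal(nrow(sim$truth), 200 + 20 + 4 * 5 + 5)
  expect_identical(sim$truth$group_id, sim$protein_groups$id)
  expect_setequal(unique(sim$truth$role),
                  c("background", "bead_sticky", "shared_reader",
                    paste0("unique_", rna_modifications())))
  expect_equal(nrow(sim$design), 18L)
  expect_equal(unname(table(sim$design$condition)[bait_conditions()]),
               rep(3L, 6), ignore_attr = TRUE)
})

test_that("identical seeds give bit-identical files; different seeds differ", {
  p <- small_params()
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  simulate_pulldown_files(d1, p)
  simulate_pulldown_files(d2, p)
  for (f in c("proteinGroups.tsv", "truth.tsv", "design.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  p2 <- small_params(seed = 102)
  d3 <- file.path(tempdir(), "sim_c")
  simulate_pulldown_files(d3, p2)
  expect_false(identical(readLines(file.path(d1, "proteinGroups.tsv")),
                         readLines(file.path(d3, "proteinGroups.tsv"))))
})

test_that("generated files round-trip through the proteinGroups reader", {
  sim <- simulate_pulldown(small_params())
  dir <- file.path(tempdir(), "sim_rt")
  paths <- write_synthetic(sim, dir)
  pg <- read_protein_groups(paths[["protein_groups"]],
                            design = read_design(paths[["design"]]))
  expect_identical(pg$info$group_id, sim$truth$group_id)
  expect_equal(pg$intensities, sim_matrix(sim)[, colnames(pg$intensities)],
               tolerance = 1e-12)
})

test_that("with no planted effects, background-only data yields no candidates in expectation", {
  p <- synth_params(n_background = 10, n_bead_sticky = 0, n_unique_per_mod = 0,
                    n_shared = 0, log_sigma = 0.1, dropout = 0, seed = 5)
  sim <- simulate_pulldown(p)
  res <- run_chain(sim_matrix(sim), sim$design)
  expect_equal(sum(res$calls), 0L)
})

test_that("strong planted effects force complete, uniquely assigned recovery", {
  sim <- simulate_pulldown(small_params())
  res <- run_chain(sim_matrix(sim), sim$design)
  sc <- score_recovery(res$ubs, sim$truth)
  expect_equal(sc$precision, rep(1, 4))
  expect_equal(sc$recall, rep(1, 4))
  # shared readers are called everywhere, hence in the 4-way region
  shared <- sim$truth$group_id[sim$truth$role == "shared_reader"]
  expect_equal(unname(res$ubs$overlap_counts[["m5C+hm5C+hm5Cm+f5C"]]),
               length(shared))
})

test_that("bead-sticky proteins have fold change over beads near 1 and are not called", {
  sim <- simulate_pulldown(small_params())
  res <- run_chain(sim_matrix(sim), sim$design)
  sticky <- sim$truth$group_id[sim$truth$role == "bead_sticky"]
  expect_true(all(abs(log(res$fct$fc_beads[sticky, ])) < log(2)))
  expect_equal(sum(res$calls[sticky, ]), 0L)
})

test_that("recovery scoring follows the stated zero-denominator conventions", {
  truth <- data.frame(group_id = paste0("P", 1:8),
                      role = c(paste0("unique_", rep(rna_modifications(), 2))),
                      stringsAsFactors = FALSE)
  empty <- list(unique = stats::setNames(
    replicate(4, character(0), simplify = FALSE), rna_modifications()))
  sc <- score_recovery(empty, truth)
  expect_equal(sc$recall, rep(0, 4))
  expect_equal(sc$precision, rep(1, 4))       # zero-denominator convention
  expect_false(any(sc$precision_defined))
  expect_true(all(sc$recall_defined))

  perfect <- list(unique = split(truth$group_id, sub("unique_", "", truth$role))[rna_modifications()])
  sc2 <- score_recovery(perfect, truth)
  expect_equal(sc2$precision, rep(1, 4))
  expect_equal(sc2$recall, rep(1, 4))
})

test_that("shuffled truth labels reduce recall to the chance baseline", {
  sim <- simulate_pulldown(small_params())
  res <- run_chain(sim_matrix(sim), sim$design)
  n_total <- nrow(sim$truth)
  set.seed(77)
  mean_recalls <- replicate(100, {
    shuffled <- sim$truth
    shuffled$role <- sample(shuffled$role)
    mean(score_recovery(res$ubs, shuffled)$recall)
  })
  # called unique sets have 5 members; a shuffled planted reader lands in
  # the matching called set with probability 5 / n_total
  expect_equal(mean(mean_recalls), 5 / n_total, tolerance = 0.5)
  expect_lt(mean(mean_recalls), 0.15)
})

test_that("intensity-dependent dropout removes low-abundance values preferentially", {
  p <- synth_params(n_background = 800, n_bead_sticky = 0, n_unique_per_mod = 0,
                    n_shared = 0, dropout = 0.3, dropout_mode = "intensity",
                    log_sigma = 0.2, seed = 9)
  p_unif <- synth_params(n_background = 800, n_bead_sticky = 0,
                         n_unique_per_mod = 0, n_shared = 0, dropout = 0.3,
                         dropout_mode = "uniform", log_sigma = 0.2, seed = 9)
  m <- sim_matrix(simulate_pulldown(p))
  overall_rate <- mean(m == 0)
  expect_equal(overall_rate, 0.3, tolerance = 0.05)
  # dropped values should come from the low-abundance side: compare the
  # base-abundance rank of dropped rows between modes
  base_rank <- rank(rowMeans(m))
  dropped_rank_int <- mean(base_rank[rowSums(m == 0) > 0])
  m_u <- sim_matrix(simulate_pulldown(p_unif))
  base_rank_u <- rank(rowMeans(m_u))
  dropped_rank_unif <- mean(base_rank_u[rowSums(m_u == 0) > 0])
  expect_lt(dropped_rank_int, dropped_rank_unif)
})
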