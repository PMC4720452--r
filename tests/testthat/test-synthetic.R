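test_that("simulated trees are seed-reproducible with the right shape", {
  t1 <- simulate_tree(5, 1, seed = 2)
  t2 <- simulate_tree(5, 1, seed = 2)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.binary(t1))
  expect_equal(length(t1$tip.label), 5)
  t46 <- simulate_tree(46, 18, seed = 9)
  # unrooted binary tree over n taxa: 2n - 3 edges
  expect_equal(nrow(ape::unroot(t46)$edge), 2 * 46 - 3)
  expect_error(simulate_tree(3), "at least 4")
})

test_that("study-shaped defaults give 46 taxa, 338 compound + 366 atomic", {
  sim <- simulate_matrix(simulate_tree(46, 18, seed = 31),
                         simulation_config(seed = 32))
  expect_equal(n_taxa(sim$matrix), 46)
  expect_equal(length(sim$matrix$outgroup), 18)
  expect_equal(n_characters(sim$atomic_matrix), 366)
  expect_equal(length(sim$rules), 25)
  expect_equal(n_characters(sim$matrix), 338)
  out <- atomize(sim$matrix, sim$rules)
  expect_equal(out$report$n_added, 28)
  expect_equal(out$report$n_characters_after, 366)
  # a study-sized file declaring ntax=46 / nchar=366 reads back faithfully
  path <- tempfile(fileext = ".nex")
  write_matrix(out$matrix, path, "nexus")
  m2 <- read_matrix(path, "nexus")
  expect_equal(n_taxa(m2), 46)
  expect_equal(n_characters(m2), 366)
})

test_that("near-zero rate yields homoplasy-free characters", {
  sim <- simulate_matrix(simulate_tree(14, 2, seed = 41),
                         simulation_config(n_taxa = 14, n_characters = 50,
                                           n_outgroup = 2,
                                           substitution_rate = 0.005,
                                           missing_fraction = 0,
                                           compound_sizes = integer(0),
                                           seed = 42))
  expect_equal(ensemble_indices(sim$tree, sim$matrix)$ci, 1)
})

test_that("true change counts bound the fitted steps on the true tree", {
  sim <- simulate_matrix(simulate_tree(12, 1, seed = 51),
                         simulation_config(n_taxa = 12, n_characters = 60,
                                           n_outgroup = 1,
                                           substitution_rate = 0.6,
                                           missing_fraction = 0,
                                           compound_sizes = integer(0),
                                           seed = 52))
  s <- vapply(sim$matrix$chars$id, function(id)
    character_steps(sim$tree, sim$matrix, id), 0L)
  expect_true(all(s <= sim$true_changes))
})

test_that("fossil taxa are more incomplete than complete taxa", {
  sim <- simulate_matrix(simulate_tree(30, 5, seed = 61),
                         simulation_config(n_taxa = 30, n_characters = 200,
                                           n_outgroup = 5,
                                           substitution_rate = 0.3,
                                           missing_fraction = 0.3,
                                           fossil_bias = 4,
                                           compound_sizes = integer(0),
                                           seed = 62))
  miss_frac <- rowMeans(sim$matrix$bits == 0L)
  f <- sim$matrix$taxa %in% sim$fossil_taxa
  expect_gt(mean(miss_frac[f]), mean(miss_frac[!f]) + 0.1)
  expect_gt(mean(miss_frac), 0.2)
  expect_lt(mean(miss_frac), 0.4)
})

test_that("atomizing a synthetic compound inverts the merge", {
  sim <- simulate_matrix(simulate_tree(16, 2, seed = 71),
                         simulation_config(n_taxa = 16, n_characters = 60,
                                           n_outgroup = 2,
                                           substitution_rate = 0.3,
                                           missing_fraction = 0.2,
                                           compound_sizes = c(2L, 2L, 3L),
                                           seed = 72))
  expect_equal(length(sim$rules), 3)
  back <- atomize(sim$matrix, sim$rules)$matrix
  expect_equal(n_characters(back), n_characters(sim$atomic_matrix))
  # wherever the compound cell was determinate the atoms are recovered
  # exactly (rules record which atomic columns they merged)
  for (r in sim$rules) {
    j_comp <- match(r$source_id, sim$matrix$chars$id)
    scored <- popcount10(sim$matrix$bits[, j_comp]) == 1L
    expect_gt(sum(scored), 0)
    for (k in seq_along(r$atom_ids)) {
      jb <- which(back$chars$label == r$target_labels[k])
      expect_length(jb, 1)
      ja <- match(r$atom_ids[k], sim$atomic_matrix$chars$id)
      expect_equal(back$bits[scored, jb],
                   sim$atomic_matrix$bits[scored, ja])
    }
  }
})

test_that("recovery experiment reports RF distances and refuses empty data", {
  rec <- recovery_experiment(simulation_config(n_taxa = 10,
                                               n_characters = 80,
                                               n_outgroup = 1,
                                               substitution_rate = 0.1,
                                               missing_fraction = 0,
                                               compound_sizes = integer(0)),
                             n_reps = 2, seed = 3)
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$rf >= 0))
  expect_error(recovery_experiment(
    simulation_config(n_taxa = 10, n_characters = 0, n_outgroup = 1,
                      compound_sizes = integer(0))), "at least one character")
})

test_that("one taxon with massive missingness destabilises only itself", {
  set.seed(81)
  sim <- simulate_matrix(simulate_tree(12, 1, seed = 82),
                         simulation_config(n_taxa = 12, n_characters = 120,
                                           n_outgroup = 1,
                                           substitution_rate = 0.15,
                                           missing_fraction = 0,
                                           compound_sizes = integer(0),
                                           seed = 83))
  m <- sim$matrix
  wiped <- "t6"
  i <- match(wiped, m$taxa)
  keep <- sample(n_characters(m), 6)  # leave a handful of scored cells
  m$bits[i, -keep] <- 0L
  res <- heuristic_search(m, search_config(n_random_additions = 2, seed = 4))
  # the wildcard wanders across the optimal trees, degrading the full
  # consensus, but the reduced consensus (wildcard pruned from each optimum)
  # recovers the remaining relationships exactly
  cons_all <- strict_consensus(res$mpts)
  expect_gt(rf_distance(cons_all, ape::unroot(sim$tree)), 0)
  reduced <- strict_consensus(lapply(res$mpts, ape::drop.tip, wiped))
  pruned_true <- ape::drop.tip(ape::unroot(sim$tree), wiped)
  expect_equal(rf_distance(reduced, pruned_true), 0)
})
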