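make_jk_matrix <- function(seed = 31, n = 12, nc = 60, rate = 0.4) {
  sim <- simulate_matrix(simulate_tree(n, 1, seed = seed),
                         simulation_config(n_taxa = n, n_characters = nc,
                                           n_outgroup = 1,
                                           substitution_rate = rate,
                                           missing_fraction = 0.1,
                                           compound_sizes = integer(0),
                                           seed = seed + 1))
  sim$matrix
}

test_that("zero removals give delta = 0 exactly and deltas never go negative", {
  m <- make_jk_matrix()
  jk <- run_jackknife(m, removal_counts = c(0, 10, 25), reps_per_count = 4,
                      search = search_config(n_random_additions = 1),
                      seed = 7)
  expect_true(all(jk$delta[jk$n_removed == 0] == 0))
  expect_true(all(jk$delta >= 0))
  expect_equal(jk$n_analysed, 60 - jk$n_removed)
})

test_that("removing every informative character leaves length 0", {
  # two informative characters among constants and missing data
  m <- cm(A = "110000", B = "110000", C = "000000", D = "000000",
          E = "00??00", F = "000000")
  inf_ids <- which(vapply(1:6, function(j)
    min_max_steps(m, j)[["g"]] > 0, TRUE))
  expect_equal(inf_ids, c(1L, 2L))
  m2 <- set_active(m, inf_ids, FALSE)
  res <- heuristic_search(m2, search_config(n_random_additions = 1, seed = 2))
  expect_equal(res$best_score$length, 0)
})

test_that("replicates are reproducible bit-for-bit under a fixed seed", {
  m <- make_jk_matrix(seed = 41)
  cfg <- search_config(n_random_additions = 1)
  a <- run_jackknife(m, c(5, 15), reps_per_count = 3, search = cfg, seed = 99)
  b <- run_jackknife(m, c(5, 15), reps_per_count = 3, search = cfg, seed = 99)
  expect_identical(a$replicate_length, b$replicate_length)
  expect_identical(a$removed_ids, b$removed_ids)
})

test_that("decay data aggregates per-count means", {
  m <- make_jk_matrix(seed = 51)
  jk <- run_jackknife(m, c(0, 12), reps_per_count = 3,
                      search = search_config(n_random_additions = 1),
                      seed = 13)
  dd <- decay_plot_data(jk)
  expect_equal(nrow(dd$points), 6)
  expect_equal(dd$means$mean_delta[dd$means$n_removed == 0], 0)
  expect_equal(nrow(dd$means), 2)
})

test_that("regression recovers an exact linear relationship", {
  fake <- data.frame(n_removed = c(10, 20, 30), n_analysed = c(90, 80, 70),
                     replicate_length = c(180, 160, 140),
                     delta = c(20, 40, 60))
  reg <- length_plot_regression(fake)
  expect_equal(reg$slope, 2)
  expect_equal(reg$intercept, 0)
  expect_equal(reg$n_points, 3)
  expect_error(length_plot_regression(fake[c(1, 1, 1), ]), "distinct")
})

test_that("homoplasy-free characters add about one step each", {
  sim <- simulate_matrix(simulate_tree(15, 1, seed = 61),
                         simulation_config(n_taxa = 15, n_characters = 80,
                                           n_outgroup = 1,
                                           substitution_rate = 0.05,
                                           missing_fraction = 0,
                                           compound_sizes = integer(0),
                                           seed = 62))
  jk <- run_jackknife(sim$matrix, removal_counts = c(10, 25, 40),
                      reps_per_count = 5,
                      search = search_config(n_random_additions = 1),
                      seed = 63)
  reg <- length_plot_regression(jk)
  # every character contributes ~m_i = 1 step (binary-dominated, CI ~ 1)
  expect_gt(reg$slope, 0.8)
  expect_lt(reg$slope, 1.35)
})

test_that("a matrix compared with itself shows no differences", {
  m <- make_jk_matrix(seed = 71, n = 10, nc = 40)
  cmp <- compare_matrices(m, m, removal_fracs = c(0.1, 0.25, 0.4),
                          reps_per_count = 3,
                          search = search_config(n_random_additions = 1),
                          seed = 5)
  expect_equal(cmp$full_length_difference, 0)
  expect_equal(cmp$ri_a, cmp$ri_b)
  m2 <- make_jk_matrix(seed = 72, n = 11, nc = 40)
  expect_error(compare_matrices(m, m2), "taxon set")
})
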