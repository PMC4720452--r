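quartet <- ape::read.tree(text = "((A,B),(C,D));")

test_that("steps on the quartet match the enumeration oracle", {
  m <- cm(A = "00", B = "01", C = "10", D = "11")
  expect_equal(character_steps(quartet, m, 1), 1)
  expect_equal(character_steps(quartet, m, 2), 2)
  expect_equal(character_steps(quartet, m, 1),
               oracle_steps(quartet, m, 1))
  expect_equal(character_steps(quartet, m, 2),
               oracle_steps(quartet, m, 2))
  expect_equal(tree_length(quartet, m), 3)
})

test_that("constant and all-missing characters cost nothing", {
  m <- cm(A = "1?", B = "1?", C = "1?", D = "1?")
  expect_equal(character_steps(quartet, m, 1), 0)
  expect_equal(tree_length(quartet, m), 0)
})

test_that("length is linear in character weights", {
  set.seed(5)
  m <- random_matrix(8, 12, n_states = 3)
  tr <- random_tree(8)
  L <- tree_length(tr, m)
  m$chars$weight <- 2
  expect_equal(tree_length(tr, m), 2 * L)
})

test_that("steps match brute-force enumeration on random small instances", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    m <- random_matrix(n, 1, n_states = sample(2:4, 1),
                       p_missing = 0.15, p_poly = 0.1)
    expect_equal(character_steps(tr, m, 1), oracle_steps(tr, m, 1),
                 info = paste("rep", rep))
  }
})

test_that("ordered characters follow linear costs", {
  m <- cm(A = "0", B = "2", C = "1", D = "2", ordered = TRUE)
  expect_equal(character_steps(quartet, m, 1),
               oracle_steps(quartet, m, 1, ordered = TRUE))
  set.seed(9)
  for (rep in 1:10) {
    n <- 5
    tok <- as.character(sample(0:2, n, replace = TRUE))
    m <- tryCatch(character_matrix(paste0("t", 1:n), matrix(tok, n, 1),
                                   ordered = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) next
    tr <- random_tree(n)
    expect_equal(character_steps(tr, m, 1),
                 oracle_steps(tr, m, 1, ordered = TRUE))
  }
})

test_that("length is invariant under re-rooting", {
  set.seed(13)
  m <- random_matrix(7, 10, n_states = 3, p_missing = 0.2)
  tr <- random_tree(7)
  L <- tree_length(tr, m)
  for (tip in paste0("t", 1:7)) {
    rooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(tree_length(rooted, m), L)
  }
})

test_that("length agrees with phangorn's Fitch on random trees", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  for (rep in 1:5) {
    n <- 10; nc <- 25
    tok <- random_tokens(n, nc, n_states = 3, p_poly = 0)
    rownames(tok) <- paste0("t", 1:n)
    m <- character_matrix(paste0("t", 1:n), tok)
    tr <- random_tree(n)
    pd <- phangorn::phyDat(tok, type = "USER", levels = c("0", "1", "2"),
                           ambiguity = "?")
    expect_equal(tree_length(tr, m), phangorn::fitch(tr, pd))
  }
})

test_that("min/max conceivable steps match brute force over all topologies", {
  # published example shape: binary character 3 vs 2 on five taxa
  m <- cm(t1 = "0", t2 = "0", t3 = "0", t4 = "1", t5 = "1")
  expect_equal(min_max_steps(m, 1), c(m = 1, g = 2))
  skip_if_not_installed("phangorn")
  set.seed(31)
  for (rep in 1:12) {
    n <- 5
    m <- random_matrix(n, 1, n_states = sample(2:3, 1), p_missing = 0.1,
                       p_poly = 0.15)
    trees <- phangorn::allTrees(n, tip.label = paste0("t", 1:n))
    ss <- vapply(trees, function(t) character_steps(t, m, 1), 0L)
    expect_equal(unname(min_max_steps(m, 1)),
                 c(min(ss), max(ss)), info = paste("rep", rep))
  }
})

test_that("three observed unordered states give m = 2; constants give 0", {
  m <- cm(A = "0", B = "1", C = "2", D = "1")
  expect_equal(min_max_steps(m, 1)[["m"]], 2)
  mc <- cm(A = "1", B = "1", C = "1", D = "1")
  expect_equal(min_max_steps(mc, 1), c(m = 0, g = 0))
})

test_that("per-character retention is 1 for a clean synapomorphy", {
  m <- cm(A = "0", B = "0", C = "1", D = "1")
  sc <- ensemble_indices(quartet, m)
  pc <- sc$per_character
  expect_equal(pc$s, 1)
  expect_equal(pc$m, 1)
  expect_equal(pc$g, 2)
  expect_equal((pc$g - pc$s) / (pc$g - pc$m), 1)
  expect_equal(sc$ri, 1)
})

test_that("a homoplasy-free matrix scores CI = RI = 1 on its tree", {
  sim <- simulate_matrix(simulate_tree(12, 2, seed = 4),
                         simulation_config(n_taxa = 12, n_characters = 40,
                                           n_outgroup = 2,
                                           substitution_rate = 0.01,
                                           missing_fraction = 0,
                                           compound_sizes = integer(0),
                                           seed = 8))
  sc <- ensemble_indices(sim$tree, sim$matrix)
  expect_equal(sc$ci, 1)
  expect_equal(sc$ri, 1)
  expect_equal(sc$fit, sum(sim$matrix$chars$active))  # F = nchar iff h = 0
})

test_that("RI is exactly invariant under duplication of the character set", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(6:9, 1)
    m <- random_matrix(n, sample(8:15, 1), n_states = 3, p_missing = 0.15)
    tr <- random_tree(n)
    ri1 <- ensemble_indices(tr, m)$ri
    dup <- m
    dup$chars <- rbind(m$chars, transform(m$chars, id = id + 100L))
    dup$bits <- cbind(m$bits, m$bits)
    dup$inap <- cbind(m$inap, m$inap)
    expect_identical(ensemble_indices(tr, dup)$ri, ri1)
  }
})

test_that("implied-weights fit follows the concave closed form", {
  m <- cm(A = "00", B = "01", C = "10", D = "11")
  sc <- ensemble_indices(quartet, m, k = 3)
  # char 1: h = 0 -> 1.0; char 2: h = 1 -> 0.75
  expect_equal(sc$per_character$h, c(0, 1))
  expect_equal(implied_weights_fit(quartet, m, k = 3), 1 + 0.75)
  expect_error(implied_weights_fit(quartet, m, k = 0), "positive")
  # F increases with k when homoplasy is present
  expect_lt(implied_weights_fit(quartet, m, k = 3),
            implied_weights_fit(quartet, m, k = 10))
})
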