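rooted_quartet <- ape::read.tree(text = "((A,B),(C,D));")

test_that("a clean synapomorphy maps to the CD stem", {
  m <- cm(A = "0", B = "0", C = "1", D = "1")
  anc <- ancestral_states(rooted_quartet, m, "acctran")
  expect_equal(nrow(anc$changes), 1)
  cd <- ape::getMRCA(rooted_quartet, c("C", "D"))
  expect_equal(anc$changes$child_node, cd)
  expect_equal(anc$changes$from, 0L)
  expect_equal(anc$changes$to, 1L)
  expect_false(anc$changes$ambiguous)
})

test_that("constant characters imply no changes anywhere", {
  m <- cm(A = "1", B = "1", C = "1", D = "1")
  anc <- ancestral_states(rooted_quartet, m)
  expect_equal(nrow(anc$changes), 0)
})

test_that("unrooted input is refused with rooting advice", {
  m <- cm(A = "0", B = "0", C = "1", D = "1", E = "1")
  tr <- random_tree(5)
  m$taxa <- tr$tip.label
  expect_error(ancestral_states(tr, m), "root")
})

test_that("acctran and deltran place the same total change differently", {
  # 1100 on ((A,(B,C)),D): two equally parsimonious placements -- a stem
  # gain with a reversal in C (accelerated) or parallel gains in A and B
  # (delayed)
  m <- cm(A = "1", B = "1", C = "0", D = "0")
  tr <- ape::read.tree(text = "((A,(B,C)),D);")
  both <- ancestral_states(tr, m, "both")
  expect_equal(sum(both$acctran$changes$steps), 2)
  expect_equal(sum(both$deltran$changes$steps), 2)
  edges_a <- both$acctran$changes$child_node
  edges_d <- both$deltran$changes$child_node
  expect_false(identical(sort(edges_a), sort(edges_d)))
  expect_true(any(both$acctran$ambiguous))
  # acctran favours the reversal (change on C's branch), deltran the
  # parallel terminal gains
  expect_true(match("C", tr$tip.label) %in% edges_a)
  expect_true(all(match(c("A", "B"), tr$tip.label) %in% edges_d))
})

test_that("changes per character sum to the character's tree steps", {
  set.seed(91)
  for (rep in 1:6) {
    n <- sample(6:9, 1)
    m <- random_matrix(n, 12, n_states = 3, p_missing = 0.15, p_poly = 0.05)
    tr <- ape::root(random_tree(n), outgroup = "t1", resolve.root = TRUE)
    for (res in c("acctran", "deltran")) {
      anc <- ancestral_states(tr, m, res)
      per_char <- tapply(anc$changes$steps, anc$changes$character_id, sum)
      for (j in 1:12) {
        want <- character_steps(tr, m, j)
        got <- if (as.character(j) %in% names(per_char))
          per_char[[as.character(j)]] else 0L
        expect_equal(got, want, info = paste(res, "char", j))
      }
    }
  }
})

test_that("counts are invariant to ladderization", {
  set.seed(95)
  m <- random_matrix(8, 15, n_states = 2)
  tr <- ape::root(random_tree(8), outgroup = "t1", resolve.root = TRUE)
  a <- ancestral_states(tr, m, "acctran")
  b <- ancestral_states(ape::ladderize(tr), m, "acctran")
  expect_equal(nrow(a$changes), nrow(b$changes))
  expect_equal(sum(a$changes$steps), sum(b$changes$steps))
})

test_that("constructed stem changes are counted as synapomorphies", {
  # five characters change only on the (D,E,F) stem
  m <- cm(A = "00000", B = "00000", C = "00000",
          D = "11111", E = "11111", F = "11111",
          outgroup = "A")
  tr <- ape::read.tree(text = "(A,(B,(C,(D,(E,F)))));")
  syn <- count_synapomorphies(tr, m, c("D", "E", "F"))
  expect_equal(syn$unambiguous, 5)
  expect_equal(syn$ambiguous, 0)
  # a clade identical to everything else has no stem changes
  syn0 <- count_synapomorphies(tr, m, c("E", "F"))
  expect_equal(syn0$unambiguous + syn0$ambiguous, 0)
  expect_error(count_synapomorphies(tr, m, c("B", "D")), "monophyletic")
})

test_that("terminal autapomorphies are counted on the leaf branch", {
  # D has a unique state in exactly 4 characters, no homoplasy elsewhere
  m <- cm(A = "000000", B = "000011", C = "000011", D = "111100",
          E = "000000")
  tr <- ape::read.tree(text = "(A,(E,((B,C),D)));")
  apo <- count_apomorphies(tr, m, "D")
  expect_equal(apo$unambiguous + apo$ambiguous, 4)
  # a taxon identical to its sister has none
  apo0 <- count_apomorphies(tr, m, "B")
  expect_equal(apo0$unambiguous + apo0$ambiguous, 0)
  expect_error(count_apomorphies(tr, m, "Z"), "unknown taxon")
})

test_that("outgroup rooting places the root outside the ingroup", {
  sim <- simulate_matrix(simulate_tree(10, 3, seed = 14),
                         simulation_config(n_taxa = 10, n_characters = 30,
                                           n_outgroup = 3,
                                           substitution_rate = 0.2,
                                           missing_fraction = 0,
                                           compound_sizes = integer(0),
                                           seed = 15))
  res <- heuristic_search(sim$matrix, search_config(n_random_additions = 1,
                                                    seed = 2))
  rooted <- root_on_outgroup(res$mpts[[1]], sim$matrix$outgroup)
  expect_true(ape::is.rooted(rooted))
  anc <- ancestral_states(rooted, sim$matrix)
  expect_equal(sum(anc$changes$steps), res$best_score$length)
})
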