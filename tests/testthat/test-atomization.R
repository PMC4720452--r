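test_that("a compound shape/size character is split by its state map", {
  # compound states: 0 = round+large, 1 = keyhole+large, 2 = keyhole+small
  m <- cm(A = "0", B = "1", C = "2", D = "1")
  rule <- atomization_rule(1, c("shape", "size"),
                           list("0" = c(0L, 0L), "1" = c(1L, 0L),
                                "2" = c(1L, 1L)))
  out <- atomize(m, list(rule))
  expect_equal(n_characters(out$matrix), 2)
  expect_equal(out$matrix$chars$label, c("shape", "size"))
  shp <- vapply(m$taxa, function(t)
    state_set(out$matrix, t, out$matrix$chars$id[1])$states, 0L)
  siz <- vapply(m$taxa, function(t)
    state_set(out$matrix, t, out$matrix$chars$id[2])$states, 0L)
  expect_equal(unname(shp), c(0L, 1L, 1L, 1L))
  expect_equal(unname(siz), c(0L, 0L, 1L, 0L))
  expect_equal(out$report$n_rules_applied, 1)
  expect_equal(out$report$n_added, 1)
})

test_that("missing/inapplicable/polymorphic source cells propagate", {
  m <- cm(A = "0", B = "?", C = "-", D = "[02]")
  rule <- atomization_rule(1, c("x", "y"),
                           list("0" = c(0L, 0L), "2" = c(1L, 1L)))
  out <- atomize(m, list(rule))$matrix
  for (id in out$chars$id) {
    expect_equal(state_set(out, "B", id)$kind, "missing")
    expect_equal(state_set(out, "C", id)$kind, "inapplicable")
    expect_equal(state_set(out, "D", id)$states, c(0L, 1L))  # union
  }
})

test_that("atomize validates rules and reports uncovered states", {
  m <- cm(A = "0", B = "1", C = "2", D = "1")
  expect_error(atomization_rule(1, "only_one", list("0" = 0L)),
               "at least 2")
  expect_error(atomization_rule(1, c("x", "y"),
                                list("0" = c(0L, 0L), "1" = c(1L, 0L))),
               "constant")
  rule <- atomization_rule(1, c("x", "y"),
                           list("0" = c(0L, 0L), "1" = c(1L, 1L)))
  expect_error(atomize(m, list(rule)), "taxon 'C'")
  expect_error(atomize(m, list(rule, rule)), "duplicate source")
})

test_that("empty rule list is the identity and tallies follow the contract", {
  set.seed(3)
  m <- random_matrix(8, 15, n_states = 3)
  out <- atomize(m, list())
  expect_true(same_state_grid(m, out$matrix))
  expect_equal(out$report$n_added, 0)
  # n_after = n_before - n_rules + sum(|targets|)
  rules <- list(
    atomization_rule(1, c("a", "b"), list("0" = c(0L, 0L), "1" = c(1L, 0L),
                                          "2" = c(1L, 1L))),
    atomization_rule(4, c("p", "q", "r"),
                     list("0" = c(0L, 0L, 0L), "1" = c(1L, 1L, 0L),
                          "2" = c(1L, 0L, 1L))))
  out2 <- atomize(m, rules)
  expect_equal(out2$report$n_characters_after, 15 - 2 + 5)
  expect_equal(n_taxa(out2$matrix), 8)  # taxon count never changes
})

test_that("rules survive the TSV round trip", {
  rules <- list(
    atomization_rule(3, c("a", "b"), list("0" = c(0L, 0L), "1" = c(1L, 1L))),
    atomization_rule(7, c("p", "q", "r"),
                     list("0" = c(0L, 0L, 0L), "1" = c(1L, 1L, 0L),
                          "2" = c(0L, 1L, 1L))))
  path <- tempfile(fileext = ".tsv")
  write_atomization_rules(rules, path)
  back <- read_atomization_rules(path)
  expect_equal(length(back), 2)
  expect_equal(back[[2]]$source_id, 7L)
  expect_equal(back[[2]]$state_map[["2"]], c(0L, 1L, 1L))
})

test_that("summed minimum steps of atoms >= compound minimum on fixed trees", {
  # brute-force property on small instances
  set.seed(11)
  for (rep in 1:8) {
    n <- 6
    src <- sample(0:2, n, replace = TRUE)
    while (length(unique(src)) < 3) src <- sample(0:2, n, replace = TRUE)
    m <- character_matrix(paste0("t", 1:n),
                          matrix(as.character(src), n, 1))
    rule <- atomization_rule(1, c("x", "y"),
                             list("0" = c(0L, 0L), "1" = c(1L, 0L),
                                  "2" = c(1L, 1L)))
    out <- atomize(m, list(rule))$matrix
    tr <- random_tree(n)
    s_src <- character_steps(tr, m, 1)
    s_atoms <- sum(vapply(out$chars$id, function(id)
      character_steps(tr, out, id), 0L))
    expect_gte(s_atoms, s_src)
  }
})

test_that("reduce_states merges a three-state column to two", {
  m <- cm(A = "0", B = "1", C = "2", D = "?")
  r <- reduce_states(m, 1, c("0" = 0L, "1" = 1L, "2" = 1L))
  expect_equal(state_set(r, "C", 1)$states, 1L)
  expect_equal(state_set(r, "D", 1)$kind, "missing")  # missing unchanged
  expect_error(reduce_states(m, 1, c("0" = 0L, "1" = 1L, "2" = 2L)),
               "does not reduce")
  expect_error(reduce_states(m, 1, c("0" = 0L, "1" = 0L, "2" = 0L)),
               "constant")
})
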