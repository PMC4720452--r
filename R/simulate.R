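# Synthetic morphological matrices with known truth.  Characters evolve on
# a known tree under a symmetric Mk-style process (per-edge change
# probability derived from a per-character rate expressed in expected
# changes per root-to-tip path), then fossil-style taxon-biased missingness
# is overlaid, and optionally sets of atomic binary characters are merged
# into artificial compound characters whose inverse atomization rules are
# recorded.  The defaults emulate the shape of a large fossil-grade
# matrix: 46 taxa (18 outside the ingroup), 366 atomic characters, and 25
# compound characters that atomize into 53 columns (28 extra characters).

#' Simulation configuration
#'
#' @param n_taxa number of taxa
#' @param n_characters number of atomic characters to simulate
#' @param n_outgroup number of basal outgroup taxa (the first
#'   `n_outgroup` labels)
#' @param state_probs named numeric vector: probability that a character has
#'   2, 3, ... states
#' @param substitution_rate expected state changes per character per
#'   root-to-tip path; low values give nearly homoplasy-free data
#' @param missing_fraction overall expected fraction of missing ("?") cells
#' @param fossil_fraction fraction of non-outgroup taxa designated
#'   incomplete "fossils"
#' @param fossil_bias multiplier on the missingness of fossil taxa relative
#'   to complete taxa
#' @param compound_sizes integer vector: sizes of the artificial compound
#'   characters to build by merging that many atomic binary characters
#'   (empty for none); the default 22 pairs + 3 triples merges 53 atoms into
#'   25 compounds
#' @param seed integer seed
#' @return a list of class `simulation_config`
#' @export
simulation_config <- function(n_taxa = 46, n_characters = 366,
                              n_outgroup = 18,
                              state_probs = c("2" = 0.8, "3" = 0.15,
                                              "4" = 0.05),
                              substitution_rate = 1.5,
                              missing_fraction = 0.3,
                              fossil_fraction = 0.5, fossil_bias = 3,
                              compound_sizes = c(rep(2L, 22), rep(3L, 3)),
                              seed = NULL) {
  stopifnot(n_taxa >= 4, n_characters >= 0, n_outgroup >= 1,
            n_outgroup < n_taxa, substitution_rate > 0,
            missing_fraction >= 0, missing_fraction < 1, fossil_bias >= 1)
  if (length(compound_sizes) && any(compound_sizes < 2))
    stop("compound characters must merge at least 2 atoms")
  structure(list(n_taxa = n_taxa, n_characters = n_characters,
                 n_outgroup = n_outgroup, state_probs = state_probs,
                 substitution_rate = substitution_rate,
                 missing_fraction = missing_fraction,
                 fossil_fraction = fossil_fraction,
                 fossil_bias = fossil_bias,
                 compound_sizes = as.integer(compound_sizes), seed = seed),
            class = "simulation_config")
}

#' Simulate a random tree with a basal outgroup grade
#'
#' The ingroup topology is drawn uniformly over labelled topologies; the
#' outgroup taxa (the first `n_outgroup` labels) subtend it as a pectinate
#' basal grade, mirroring how non-ingroup taxa root empirical matrices.
#'
#' @param n_taxa total number of taxa (>= 4)
#' @param n_outgroup number of basal outgroup taxa
#' @param seed integer seed
#' @return a rooted `phylo` with unit edge lengths; tip labels `t1..tn`,
#'   outgroup taxa in attribute `"outgroup"`
#' @export
simulate_tree <- function(n_taxa, n_outgroup = 1, seed = NULL) {
  if (n_taxa < 4) stop("need at least 4 taxa")
  stopifnot(n_outgroup >= 1, n_outgroup <= n_taxa - 2)
  if (!is.null(seed)) set.seed(seed)
  labels <- paste0("t", seq_len(n_taxa))
  og <- labels[seq_len(n_outgroup)]
  ig <- labels[-seq_len(n_outgroup)]
  in_tr <- ape::rtopology(length(ig), rooted = TRUE, tip.label = ig)
  nwk_in <- sub(";$", "", ape::write.tree(in_tr))
  nwk <- nwk_in
  for (o in rev(og)) nwk <- paste0("(", o, ",", nwk, ")")
  tr <- ape::read.tree(text = paste0(nwk, ";"))
  tr$edge.length <- rep(1, nrow(tr$edge))
  attr(tr, "outgroup") <- og
  tr
}

# evolve one character down the tree; returns list(states per tip, n_changes)
sim_one_character <- function(pre_edges, n, root, n_states, p_edge) {
  st <- integer(n + attr(pre_edges, "nnode"))
  st[root] <- sample.int(n_states, 1L) - 1L
  changes <- 0L
  for (k in seq_len(nrow(pre_edges))) {
    u <- pre_edges[k, 1]; v <- pre_edges[k, 2]
    if (runif(1) < p_edge) {
      others <- setdiff(seq_len(n_states) - 1L, st[u])
      st[v] <- if (length(others) == 1L) others else sample(others, 1L)
      changes <- changes + 1L
    } else st[v] <- st[u]
  }
  list(tips = st[seq_len(n)], changes = changes)
}

#' Simulate a character matrix on a tree
#'
#' @param tree a rooted `phylo` (e.g. from [simulate_tree()])
#' @param config a [simulation_config()]
#' @return a list with `matrix` (the `CharacterMatrix` actually analysed:
#'   compound-merged if `compound_sizes` is non-empty), `atomic_matrix` (the
#'   fully atomic matrix before merging), `rules` (the inverse
#'   [atomization_rule()]s recovering the atoms), `tree`, `true_changes`
#'   (per atomic character), and `fossil_taxa`
#' @export
simulate_matrix <- function(tree, config = simulation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- length(tree$tip.label)
  if (config$n_characters < 1) stop("need at least one character")
  tr <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]
  attr(pre_edges, "nnode") <- tr$Nnode
  root <- n + 1L
  depth <- tree_depth_edges(tree)
  p_edge <- 1 - exp(-config$substitution_rate / depth)

  nst <- as.integer(names(config$state_probs))
  tokens <- base::matrix("0", n, config$n_characters)
  true_changes <- integer(config$n_characters)
  n_states_vec <- integer(config$n_characters)
  for (j in seq_len(config$n_characters)) {
    k <- nst[sample.int(length(nst), 1L, prob = config$state_probs)]
    # condition on variability: a column scored identically for every taxon
    # carries no signal and real matrices exclude it
    for (attempt in seq_len(1000L)) {
      sim <- sim_one_character(pre_edges, n, root, k, p_edge)
      if (length(unique(sim$tips)) > 1L) break
    }
    if (length(unique(sim$tips)) == 1L) {
      # rate so low that change never arose: force a single true change
      ed <- pre_edges[sample.int(nrow(pre_edges), 1L), ]
      sim <- force_one_change(pre_edges, n, root, k, ed)
    }
    tokens[, j] <- as.character(sim$tips)
    true_changes[j] <- sim$changes
    n_states_vec[j] <- k
  }

  outgroup <- attr(tree, "outgroup")
  if (is.null(outgroup)) outgroup <- tree$tip.label[1]
  m <- character_matrix(tree$tip.label, tokens, outgroup = outgroup)

  # taxon-biased missingness, scaled so the overall expectation matches
  ingroup <- setdiff(tree$tip.label, outgroup)
  n_fossil <- round(config$fossil_fraction * length(ingroup))
  fossil <- ingroup[sample.int(length(ingroup), n_fossil)]
  bias <- ifelse(m$taxa %in% fossil, config$fossil_bias, 1)
  p_tax <- pmin(0.95, config$missing_fraction * bias / mean(bias))
  if (config$missing_fraction > 0) {
    drop <- base::matrix(runif(n * config$n_characters), n) <
      base::matrix(p_tax, n, config$n_characters)
    m$bits[drop] <- 0L
    m$inap[drop] <- FALSE
  }

  atomic <- m
  rules <- list()
  compound <- m
  if (length(config$compound_sizes)) {
    mg <- merge_into_compounds(atomic, config$compound_sizes,
                               n_states_vec, true_changes)
    compound <- mg$matrix
    rules <- mg$rules
  }
  list(matrix = compound, atomic_matrix = atomic, rules = rules,
       tree = tree, true_changes = true_changes, fossil_taxa = fossil)
}

tree_depth_edges <- function(tree) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  dep <- integer(n + tr$Nnode)
  for (k in rev(seq_len(nrow(tr$edge))))  # preorder
    dep[tr$edge[k, 2]] <- dep[tr$edge[k, 1]] + 1L
  max(dep[seq_len(n)])
}

force_one_change <- function(pre_edges, n, root, n_states, ed) {
  st <- integer(n + attr(pre_edges, "nnode"))
  st[root] <- 0L
  below <- ed[2]
  # mark the subtree under the chosen edge
  in_sub <- logical(length(st))
  in_sub[below] <- TRUE
  for (k in seq_len(nrow(pre_edges)))
    if (in_sub[pre_edges[k, 1]]) in_sub[pre_edges[k, 2]] <- TRUE
  st[in_sub] <- 1L
  list(tips = st[seq_len(n)], changes = 1L)
}

# Merge groups of binary atomic characters into compound columns.  The
# compound's states enumerate the observed joint combinations; the recorded
# rule maps each compound state back to its atom tuple, so atomize()
# inverts the merge wherever all constituents were scored.
merge_into_compounds <- function(atomic, sizes, n_states_vec, true_changes) {
  pool <- which(n_states_vec == 2L)
  if (length(pool) < sum(sizes))
    stop("not enough binary characters to build the requested compounds")
  m <- atomic
  rules <- list()
  drop_ids <- integer(0)
  # try a group of atoms; NULL if the joint coding is degenerate (fewer than
  # two observed combinations, or a target would come out constant)
  try_group <- function(js) {
    combos <- list()
    cells <- vector("list", n_taxa(m))
    for (i in seq_len(n_taxa(m))) {
      part_bits <- atomic$bits[i, js]
      if (any(part_bits == 0L)) { cells[[i]] <- integer(0); next }
      parts <- lapply(part_bits, bits_to_states)
      tuples <- expand.grid(parts, KEEP.OUT.ATTRS = FALSE)
      codes <- integer(nrow(tuples))
      for (r in seq_len(nrow(tuples))) {
        key <- paste(unlist(tuples[r, ]), collapse = ",")
        if (is.null(combos[[key]])) combos[[key]] <- length(combos)
        codes[r] <- combos[[key]]
      }
      cells[[i]] <- codes
    }
    if (length(combos) < 2L || length(combos) > 10L) return(NULL)
    # every atom must still vary across the observed combos
    tup <- do.call(rbind, lapply(names(combos), function(key)
      as.integer(strsplit(key, ",", fixed = TRUE)[[1]])))
    if (any(apply(tup, 2, function(v) length(unique(v))) < 2L)) return(NULL)
    list(combos = combos, cells = cells)
  }
  for (gi in seq_along(sizes)) {
    got <- NULL
    for (attempt in seq_len(50L)) {
      if (length(pool) < sizes[gi]) break
      js <- sort(pool[sample.int(length(pool), sizes[gi])])
      got <- try_group(js)
      if (!is.null(got)) break
    }
    if (is.null(got)) next
    pool <- setdiff(pool, js)
    first_j <- js[1]
    for (i in seq_len(n_taxa(m))) {
      m$bits[i, first_j] <- states_to_bits(got$cells[[i]])
      m$inap[i, first_j] <- FALSE
    }
    m$chars$label[first_j] <- paste0("compound", gi)
    state_map <- list()
    for (key in names(got$combos))
      state_map[[as.character(got$combos[[key]])]] <-
        as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    rule <- atomization_rule(
      atomic$chars$id[first_j],
      paste0("compound", gi, c("_a", "_b", "_c")[seq_along(js)]),
      state_map)
    rule$atom_ids <- atomic$chars$id[js]  # provenance of the merged atoms
    rules[[length(rules) + 1L]] <- rule
    drop_ids <- c(drop_ids, atomic$chars$id[js[-1]])
  }
  if (length(drop_ids)) m <- subset_matrix(m, drop_characters = drop_ids)
  list(matrix = m, rules = rules)
}

#' Simulate, search, and compare against the generating tree
#'
#' Validation harness: simulates a matrix without missing data or compound
#' merging, runs [heuristic_search()], and measures the Robinson-Foulds
#' distance between the strict consensus of the optima and the true tree.
#'
#' @param config a [simulation_config()]
#' @param search a [search_config()]
#' @param n_reps number of independent simulate-search repetitions
#' @param seed integer seed
#' @return a `data.frame` with one row per repetition: `rf`, `n_mpts`,
#'   `best_length`
#' @export
recovery_experiment <- function(config = simulation_config(
                                  n_taxa = 20, n_characters = 200,
                                  n_outgroup = 1,
                                  state_probs = c("3" = 0.5, "4" = 0.5),
                                  substitution_rate = 0.25,
                                  missing_fraction = 0,
                                  compound_sizes = integer(0)),
                                search = search_config(n_random_additions = 3),
                                n_reps = 1, seed = NULL) {
  if (config$n_characters < 1) stop("need at least one character to search")
  if (!is.null(seed)) set.seed(seed)
  config$seed <- NULL
  search$seed <- NULL
  rows <- lapply(seq_len(n_reps), function(r) {
    tr <- simulate_tree(config$n_taxa, config$n_outgroup)
    sim <- simulate_matrix(tr, config)
    res <- heuristic_search(sim$matrix, search)
    cons <- strict_consensus(res$mpts)
    data.frame(rf = rf_distance(cons, ape::unroot(tr)),
               n_mpts = length(res$mpts),
               best_length = res$best_score$length)
  })
  do.call(rbind, rows)
}
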