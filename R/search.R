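# Maximum-parsimony tree search: exhaustive enumeration for small taxon
# sets, and random-addition-sequence Wagner trees refined by branch swapping
# (NNI/SPR/TBR) for everything else.  The objective is either plain
# (weighted) tree length or the implied-weights score, which down-weights
# homoplastic characters through the concave fit k/(k + h).

#' Search configuration
#'
#' @param n_random_additions number of random addition sequences
#' @param swap branch swapper: `"tbr"` (default), `"spr"`, `"nni"`, or
#'   `"none"` (Wagner trees only)
#' @param objective `"equal_weights_length"` or `"implied_weights_fit"`
#' @param k implied-weights concavity (used only under the implied
#'   objective; default 3, the long-standing default of parsimony programs)
#' @param max_trees_held cap on the number of equally optimal trees retained
#' @param seed integer seed, or `NULL` to use the ambient RNG state
#' @param bootstrap_additions addition sequences per bootstrap replicate
#'   (replicate searches are conventionally lighter than the main search)
#' @return a list of class `search_config`
#' @export
search_config <- function(n_random_additions = 10,
                          swap = c("tbr", "spr", "nni", "none"),
                          objective = c("equal_weights_length",
                                        "implied_weights_fit"),
                          k = 3, max_trees_held = 100, seed = NULL,
                          bootstrap_additions = 1) {
  swap <- match.arg(swap)
  objective <- match.arg(objective)
  stopifnot(n_random_additions >= 1, max_trees_held >= 1, k > 0,
            bootstrap_additions >= 1)
  structure(list(n_random_additions = as.integer(n_random_additions),
                 swap = swap, objective = objective, k = k,
                 max_trees_held = as.integer(max_trees_held),
                 seed = seed,
                 bootstrap_additions = as.integer(bootstrap_additions)),
            class = "search_config")
}

swap_code <- function(swap) {
  switch(swap, none = 0L, nni = 1L, spr = 2L, tbr = 3L)
}

search_inputs <- function(matrix, objective, weights = NULL) {
  enc <- encode_matrix(matrix)
  if (!is.null(weights)) enc$w <- weights
  implied <- objective == "implied_weights_fit"
  mmin <- if (implied)
    vapply(matrix$chars$id, function(id) min_max_steps(matrix, id)[["m"]], 0)
  else rep(0, n_characters(matrix))
  list(enc = enc, implied = implied, mmin = as.integer(mmin))
}

edge_to_phylo <- function(edge, taxa) {
  n <- length(taxa)
  structure(list(edge = edge, Nnode = max(edge) - n, tip.label = taxa),
            class = "phylo")
}

finish_search <- function(res, matrix, objective, k, seed, score = TRUE) {
  trees <- lapply(res$edges, edge_to_phylo, taxa = matrix$taxa)
  trees <- dedupe_trees(trees)
  best <- if (score) ensemble_indices(trees[[1]], matrix, k = k) else NULL
  structure(list(best_score = best,
                 best_objective = res$best_obj,
                 objective = objective,
                 mpts = trees,
                 n_rearrangements =
                   if (!is.null(res$n_rearrangements)) res$n_rearrangements
                   else res$n_topologies,
                 seed = seed),
            class = "SearchResult")
}

#' @export
print.SearchResult <- function(x, ...) {
  cat("SearchResult:", length(x$mpts), "optimal tree(s), length",
      if (!is.null(x$best_score)) x$best_score$length else x$replicate_length,
      "\n")
  cat("  objective:", x$objective,
      if (x$objective == "implied_weights_fit")
        sprintf("(fit %.4f, k = %g)", x$best_score$fit, x$best_score$k)
      else "", "\n")
  cat("  rearrangements examined:", format(x$n_rearrangements, big.mark = ","),
      "\n")
  invisible(x)
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology ((2n-5)!! of them) and returns
#' all optima.  Refuses more than 9 taxa.
#'
#' @param matrix a `CharacterMatrix`
#' @param objective,k see [search_config()]
#' @param max_trees_held cap on retained optima
#' @return a `SearchResult`
#' @export
exhaustive_search <- function(matrix, objective = "equal_weights_length",
                              k = 3, max_trees_held = 1000) {
  nt <- n_taxa(matrix)
  if (nt > 9) stop("exhaustive search is limited to 9 taxa (got ", nt, ")")
  if (nt < 3) stop("need at least 3 taxa")
  si <- search_inputs(matrix, objective)
  res <- cpp_exhaustive(si$enc$X, si$enc$ordered, si$enc$w, si$mmin,
                        si$implied, k, as.integer(max_trees_held))
  out <- finish_search(res, matrix, objective, k, seed = NULL)
  out$n_topologies <- res$n_topologies
  out
}

#' Heuristic maximum-parsimony search
#'
#' For each random addition sequence a Wagner tree is grown greedily (each
#' taxon joined at the best available branch) and refined by the configured
#' branch swapper to a local optimum; optima are pooled over sequences and
#' deduplicated by bipartition sets.  Deterministic given `config$seed`.
#'
#' @param matrix a `CharacterMatrix`
#' @param config a [search_config()]
#' @param weights optional per-character weight override (used by resampling
#'   procedures; 0 removes a character from the replicate)
#' @return a `SearchResult`
#' @export
heuristic_search <- function(matrix, config = search_config(),
                             weights = NULL) {
  nt <- n_taxa(matrix)
  if (nt < 4) stop("heuristic search needs at least 4 taxa")
  if (!is.null(config$seed)) set.seed(config$seed)
  si <- search_inputs(matrix, config$objective, weights)
  if (all(si$enc$w == 0)) stop("no active characters to analyse")
  orders <- t(vapply(seq_len(config$n_random_additions),
                     function(i) sample.int(nt) - 1L, integer(nt)))
  res <- cpp_mp_search(si$enc$X, si$enc$ordered, si$enc$w, si$mmin,
                       orders, swap_code(config$swap), si$implied,
                       config$k, config$max_trees_held)
  out <- finish_search(res, matrix, config$objective, config$k, config$seed,
                       score = is.null(weights))
  if (!is.null(weights)) {
    # report the replicate-weighted length rather than the full-matrix score
    out$replicate_length <- if (si$implied) NA_real_ else res$best_obj
  }
  out
}
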