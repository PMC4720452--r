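# Nonparametric bootstrap over characters: each replicate resamples the
# active characters with replacement to the original count (implemented as
# integer reweighting), re-searches, and records the bipartitions of the
# replicate's strict consensus.  Supports are absolute percentages.

#' Character bootstrap with absolute support values
#'
#' @param matrix a `CharacterMatrix`
#' @param reps number of replicates (the conventional headline run uses 100)
#' @param config a [search_config()]; each replicate searches with
#'   `config$bootstrap_additions` random addition sequences
#' @param seed integer seed for the whole procedure
#' @return a `bootstrap_result`: list with `consensus` (majority-rule tree,
#'   node labels = absolute percentages), `frequencies` (split percentage
#'   table), `reps` and `seed`.  Use [map_supports()] to transfer the
#'   percentages onto another tree (e.g. an MPT).
#' @export
bootstrap <- function(matrix, reps = 100, config = search_config(),
                      seed = NULL) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  act <- which(matrix$chars$active)
  if (!length(act)) stop("no active characters to resample")
  rep_cfg <- config
  rep_cfg$n_random_additions <- config$bootstrap_additions
  rep_cfg$seed <- NULL  # replicates share the ambient seeded stream
  rep_cfg$objective <- config$objective
  base_w <- matrix$chars$weight * as.numeric(matrix$chars$active)
  all_keys <- vector("list", reps)
  for (r in seq_len(reps)) {
    counts <- tabulate(sample(act, length(act), replace = TRUE),
                       nbins = n_characters(matrix))
    res <- heuristic_search(matrix, rep_cfg, weights = base_w * counts)
    cons <- strict_consensus(res$mpts)
    all_keys[[r]] <- split_keys(cons)
  }
  tab <- table(unlist(all_keys))
  freq <- setNames(100 * as.numeric(tab) / reps, names(tab))
  keep <- freq > 50
  sides <- lapply(names(freq)[keep], function(k)
    strsplit(k, "\r", fixed = TRUE)[[1]])
  cons <- build_tree_from_splits(sides, sort(matrix$taxa),
                                 support = freq[keep])
  structure(list(consensus = cons,
                 frequencies = data.frame(split = names(freq),
                                          percent = unname(freq),
                                          stringsAsFactors = FALSE),
                 reps = reps, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("bootstrap_result:", x$reps, "replicates;",
      sum(x$frequencies$percent > 50), "splits above 50%\n")
  invisible(x)
}

#' Write bootstrap percentages onto the nodes of a tree
#'
#' Each internal node of `tree` receives the percentage of bootstrap
#' replicates containing its bipartition (0 if never seen).
#'
#' @param tree a `phylo` over the matrix taxa
#' @param boot a [bootstrap()] result
#' @return `tree` with integer node labels
#' @export
map_supports <- function(tree, boot) {
  freq <- setNames(boot$frequencies$percent, boot$frequencies$split)
  n <- length(tree$tip.label)
  ref <- min(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  nn <- n + tr$Nnode
  desc <- vector("list", nn)
  desc[seq_len(n)] <- as.list(tr$tip.label)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  labs <- character(tr$Nnode)
  for (v in (n + 1L):nn) {
    s <- desc[[v]]
    if (ref %in% s) s <- setdiff(tree$tip.label, s)
    if (length(s) < 2L || length(s) > n - 2L) { labs[v - n] <- ""; next }
    key <- paste(sort(s), collapse = "\r")
    pct <- if (key %in% names(freq)) freq[[key]] else 0
    labs[v - n] <- format(round(pct))
  }
  # reorder.phylo permutes edge rows, not node numbers
  tree$node.label <- labs
  tree
}
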