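# Unrooted trees are compared by their sets of non-trivial bipartitions
# (splits).  A split is stored canonically as the sorted label set of the
# side not containing the lexicographically smallest taxon.

split_sides <- function(tree) {
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
  sides <- list()
  for (v in (n + 1L):nn) {
    s <- desc[[v]]
    if (ref %in% s) s <- setdiff(tree$tip.label, s)
    if (length(s) >= 2L && length(s) <= n - 2L)
      sides[[length(sides) + 1L]] <- sort(s)
  }
  unique(sides)
}

split_keys <- function(tree) {
  vapply(split_sides(tree), paste, "", collapse = "\r")
}

# signature for whole-topology equality (unrooted)
topology_key <- function(tree) {
  paste(sort(split_keys(tree)), collapse = "\n")
}

dedupe_trees <- function(trees) {
  keys <- vapply(trees, topology_key, "")
  trees[!duplicated(keys)]
}

quote_label <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.|]", x), paste0("'", x, "'"), x)
}

# Build an unrooted tree from a compatible set of canonical split sides.
# Optional `support` values (same order as `sides`) become node labels.
build_tree_from_splits <- function(sides, labels, support = NULL) {
  labels <- sort(labels)
  ref <- labels[1]
  rest <- setdiff(labels, ref)
  if (length(sides)) {
    ord <- order(-vapply(sides, length, 0L))
    sides <- sides[ord]
    if (!is.null(support)) support <- support[ord]
  }
  nw <- function(tipset, avail) {
    remaining <- tipset
    kids <- integer(0)
    for (i in avail) {
      if (all(sides[[i]] %in% remaining)) {
        kids <- c(kids, i)
        remaining <- setdiff(remaining, sides[[i]])
      }
    }
    parts <- character(0)
    for (ci in kids) {
      inner_avail <- avail[vapply(avail, function(j)
        !identical(j, ci) && all(sides[[j]] %in% sides[[ci]]), TRUE)]
      lab <- if (!is.null(support)) format(round(support[ci])) else ""
      parts <- c(parts, paste0(nw(sides[[ci]], inner_avail), lab))
    }
    parts <- c(parts, quote_label(remaining))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  text <- paste0("(", quote_label(ref), ",", nw(rest, seq_along(sides)), ");")
  tr <- ape::read.tree(text = text)
  ape::unroot(tr)
}

#' Strict consensus of a set of trees
#'
#' Returns the unrooted tree whose bipartitions are exactly those shared by
#' every input tree; conflicting regions collapse to polytomies.
#'
#' @param trees a list (or `multiPhylo`) of `phylo` objects over one leaf set
#' @return a `phylo`
#' @export
strict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  if (length(trees) == 0L) stop("no trees supplied")
  leafset <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), leafset))
      stop("trees have mismatched leaf sets")
  if (length(trees) == 1L) return(trees[[1]])
  keys <- lapply(trees, split_keys)
  shared <- Reduce(intersect, keys)
  sides <- lapply(shared, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  build_tree_from_splits(sides, leafset)
}

#' Majority-rule consensus with split frequencies
#'
#' Splits occurring in more than `p` of the input trees are retained; the
#' percentage of trees containing each retained split is written to the node
#' labels.
#'
#' @param trees list of `phylo` over one leaf set
#' @param p retention threshold as a fraction (default strict majority, 0.5)
#' @return a `phylo` with integer percentage node labels; the full split
#'   frequency table is attached as attribute `"frequencies"`
#' @export
majority_consensus <- function(trees, p = 0.5) {
  trees <- as_tree_list(trees)
  leafset <- sort(trees[[1]]$tip.label)
  keys <- lapply(trees, split_keys)
  tab <- table(unlist(keys))
  freq <- 100 * as.numeric(tab) / length(trees)
  names(freq) <- names(tab)
  keep <- freq > 100 * p
  sides <- lapply(names(freq)[keep], function(k)
    strsplit(k, "\r", fixed = TRUE)[[1]])
  tr <- build_tree_from_splits(sides, leafset, support = freq[keep])
  attr(tr, "frequencies") <- data.frame(split = names(freq),
                                        percent = unname(freq),
                                        stringsAsFactors = FALSE)
  tr
}

#' Robinson-Foulds distance between two unrooted trees
#' @param a,b `phylo` objects over the same leaf set
#' @return integer: the number of bipartitions present in exactly one tree
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have mismatched leaf sets")
  ka <- split_keys(a)
  kb <- split_keys(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  trees
}
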