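# Mapping character changes onto a tree.  A Sankoff-style down-pass (unit
# costs for unordered characters, linear costs for ordered ones) is followed
# by a top-down assignment in which every node takes a state that is
# conditionally optimal given its parent's state; such assignments always
# realise the character's minimum steps.  Where several states are
# conditionally optimal the ACCTRAN resolution prefers a change (pushing
# transformations rootward, favouring reversals), DELTRAN prefers the
# parent's state (pushing them tipward, favouring parallelisms).  A change
# is reported as ambiguous when the two resolutions disagree about it, the
# usual working definition of an "unambiguous" synapomorphy.

BIG_COST <- 1e7

#' Root a tree on its outgroup
#'
#' @param tree a `phylo`
#' @param outgroup taxon labels; if the set is not monophyletic in the
#'   unrooted tree, rooting falls back to the first outgroup taxon
#' @return a rooted `phylo`
#' @export
root_on_outgroup <- function(tree, outgroup) {
  outgroup <- intersect(outgroup, tree$tip.label)
  if (!length(outgroup)) stop("no outgroup taxa present in the tree")
  tr <- ape::unroot(tree)
  out <- tryCatch(ape::root(tr, outgroup = outgroup, resolve.root = TRUE),
                  error = function(e) NULL)
  if (is.null(out))
    out <- ape::root(tr, outgroup = outgroup[1], resolve.root = TRUE)
  out
}

#' Most-parsimonious ancestral state assignment
#'
#' @param tree a rooted `phylo` over the matrix taxa
#' @param matrix a `CharacterMatrix`
#' @param resolution `"acctran"` (default), `"deltran"`, or `"both"`
#' @return for a single resolution, a list of class `ancestral_states` with
#'   `states` (node x character matrix of state codes, ape node numbering),
#'   `ambiguous` (same shape, flags nodes with several conditionally optimal
#'   states), `changes` (one row per state change: `parent_node`,
#'   `child_node`, `child_label`, `character_id`, `from`, `to`, `steps`,
#'   `ambiguous` -- a change is flagged ambiguous when ACCTRAN and DELTRAN
#'   disagree about it) and `resolution`; for `"both"`, a list with
#'   elements `acctran` and `deltran`
#' @export
ancestral_states <- function(tree, matrix,
                             resolution = c("acctran", "deltran", "both")) {
  resolution <- match.arg(resolution)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; see root_on_outgroup()")
  check_tree_matrix(tree, matrix)
  if (resolution == "both")
    return(list(acctran = ancestral_states(tree, matrix, "acctran"),
                deltran = ancestral_states(tree, matrix, "deltran")))

  enc <- encode_matrix(matrix, tip_order = tree$tip.label)
  nchr <- nrow(enc$X)
  ord <- enc$ordered
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  nn <- n + tr$Nnode
  root <- n + 1L

  minplus <- function(D) {
    rmin <- do.call(pmin, lapply(1:10, function(s) D[, s]))
    E <- pmin(D, rmin + 1)
    if (any(ord)) {
      Eo <- D
      for (s in 2:10) Eo[, s] <- pmin(Eo[, s], Eo[, s - 1] + 1)
      for (s in 9:1) Eo[, s] <- pmin(Eo[, s], Eo[, s + 1] + 1)
      E[ord, ] <- Eo[ord, ]
    }
    E
  }

  down <- vector("list", nn)
  for (tip in seq_len(n)) {
    D <- base::matrix(BIG_COST, nchr, 10)
    for (s in 0:9)
      D[bitwAnd(enc$X[, tip], bitwShiftL(1L, s)) > 0L, s + 1] <- 0
    down[[tip]] <- D
  }
  kids <- vector("list", nn)
  for (k in seq_len(nrow(tr$edge)))
    kids[[tr$edge[k, 1]]] <- c(kids[[tr$edge[k, 1]]], tr$edge[k, 2])
  node_order <- unique(tr$edge[, 1])  # postorder: children before parents
  for (v in node_order) {
    D <- base::matrix(0, nchr, 10)
    for (ch in kids[[v]]) D <- D + minplus(down[[ch]])
    down[[v]] <- D
  }

  assign_states <- function(prefer_change) {
    chosen <- base::matrix(NA_integer_, nn, nchr)
    ambig <- base::matrix(FALSE, nn, nchr)
    Troot <- down[[root]]
    chosen[root, ] <- max.col(-Troot, ties.method = "first") - 1L
    ambig[root, ] <- rowSums(Troot <=
      Troot[cbind(seq_len(nchr), chosen[root, ] + 1L)] + 1e-9) > 1L
    for (k in rev(seq_len(nrow(tr$edge)))) {  # preorder
      u <- tr$edge[k, 1]; v <- tr$edge[k, 2]
      P <- chosen[u, ]
      Cm <- base::matrix(1, nchr, 10)
      Cm[cbind(seq_len(nchr), P + 1L)] <- 0
      if (any(ord)) {
        A <- abs(outer(P[ord], 0:9, "-"))
        Cm[ord, ] <- A
      }
      tot <- down[[v]] + Cm
      mins <- do.call(pmin, lapply(1:10, function(s) tot[, s]))
      cand <- tot <= mins + 1e-9
      ambig[v, ] <- rowSums(cand) > 1L
      if (prefer_change) {
        cand_alt <- cand
        cand_alt[cbind(seq_len(nchr), P + 1L)] <- FALSE
        has_alt <- rowSums(cand_alt) > 0L
        pick <- ifelse(has_alt,
                       max.col(cand_alt, ties.method = "first"),
                       P + 1L)
      } else {
        keeps <- cand[cbind(seq_len(nchr), P + 1L)]
        pick <- ifelse(keeps, P + 1L, max.col(cand, ties.method = "first"))
      }
      chosen[v, ] <- pick - 1L
    }
    list(chosen = chosen, ambig = ambig)
  }

  acc <- assign_states(TRUE)
  del <- assign_states(FALSE)
  use <- if (resolution == "acctran") acc else del
  other <- if (resolution == "acctran") del else acc
  chosen <- use$chosen

  # a change is ambiguous when the two resolutions disagree about it
  tiplab <- tree$tip.label
  rows <- list()
  for (k in seq_len(nrow(tr$edge))) {
    u <- tr$edge[k, 1]; v <- tr$edge[k, 2]
    diffs <- which(chosen[u, ] != chosen[v, ])
    if (!length(diffs)) next
    shared <- other$chosen[u, diffs] == chosen[u, diffs] &
      other$chosen[v, diffs] == chosen[v, diffs]
    rows[[length(rows) + 1L]] <- data.frame(
      parent_node = u, child_node = v,
      child_label = if (v <= n) tiplab[v] else paste0("node", v),
      character_id = matrix$chars$id[diffs],
      from = chosen[u, diffs], to = chosen[v, diffs],
      steps = ifelse(ord[diffs], abs(chosen[u, diffs] - chosen[v, diffs]),
                     1L),
      ambiguous = !shared,
      stringsAsFactors = FALSE)
  }
  changes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_node = integer(0), child_node = integer(0),
               child_label = character(0), character_id = integer(0),
               from = integer(0), to = integer(0), steps = integer(0),
               ambiguous = logical(0))
  colnames(chosen) <- matrix$chars$id
  structure(list(states = chosen, ambiguous = use$ambig, changes = changes,
                 resolution = resolution),
            class = "ancestral_states")
}

node_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tr$Nnode)
  desc[seq_len(n)] <- as.list(tree$tip.label)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc[[node]]
}

changes_on_edge <- function(anc, child_node) {
  anc$changes[anc$changes$child_node == child_node, , drop = FALSE]
}

#' Count synapomorphies on a clade's stem branch
#'
#' @param tree rooted `phylo`
#' @param matrix a `CharacterMatrix`
#' @param clade character vector of tip labels defining the clade
#' @param resolution `"acctran"` or `"deltran"`
#' @return list with `unambiguous` and `ambiguous` change counts and the
#'   underlying `changes` table for the stem branch
#' @export
count_synapomorphies <- function(tree, matrix, clade,
                                 resolution = "acctran") {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; see root_on_outgroup()")
  bad <- setdiff(clade, tree$tip.label)
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  n <- length(tree$tip.label)
  node <- if (length(clade) == 1L) match(clade, tree$tip.label)
  else ape::getMRCA(tree, clade)
  if (!setequal(node_descendants(tree, node), clade))
    stop("clade is not monophyletic in this tree")
  if (node == n + 1L) stop("clade spans the whole tree (no stem branch)")
  anc <- ancestral_states(tree, matrix, resolution)
  ch <- changes_on_edge(anc, node)
  list(unambiguous = sum(!ch$ambiguous), ambiguous = sum(ch$ambiguous),
       changes = ch)
}

#' Count apomorphies on a terminal branch
#'
#' @inheritParams count_synapomorphies
#' @param taxon a single tip label
#' @return list with `unambiguous` and `ambiguous` change counts and the
#'   terminal branch's `changes` table
#' @export
count_apomorphies <- function(tree, matrix, taxon, resolution = "acctran") {
  tip <- match(taxon, tree$tip.label)
  if (is.na(tip)) stop("unknown taxon: ", taxon)
  anc <- ancestral_states(tree, matrix, resolution)
  ch <- changes_on_edge(anc, tip)
  list(unambiguous = sum(!ch$ambiguous), ambiguous = sum(ch$ambiguous),
       changes = ch)
}
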