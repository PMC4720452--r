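# Tree scoring.  Trees are ape "phylo" objects (rooted or unrooted storage,
# polytomies allowed); parsimony length is rooting-invariant.  Unordered
# characters are scored by the Hartigan/Fitch pass, ordered characters by a
# Sankoff pass with linear costs; missing and inapplicable cells take any
# state freely, polymorphic cells any member state.

check_tree_matrix <- function(tree, matrix) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!setequal(tree$tip.label, matrix$taxa))
    stop("tree leaves do not match matrix taxa")
  if (length(tree$tip.label) != length(matrix$taxa))
    stop("duplicate tree leaves")
  invisible(TRUE)
}

# per-character observed steps for all characters (0 for inactive)
all_character_steps <- function(tree, matrix) {
  check_tree_matrix(tree, matrix)
  enc <- encode_matrix(matrix, tip_order = tree$tip.label)
  s <- cpp_tree_steps(tree$edge, length(tree$tip.label), enc$X,
                      enc$ordered, enc$w)
  names(s) <- matrix$chars$id
  s
}

#' Observed steps of one character on a tree
#'
#' @param tree an ape `phylo` whose tips are the matrix taxa
#' @param matrix a `CharacterMatrix`
#' @param character_id 1-based character id
#' @return integer: the minimum number of state changes the tree requires
#' @export
character_steps <- function(tree, matrix, character_id) {
  j <- match(character_id, matrix$chars$id)
  if (is.na(j)) stop("unknown character id: ", character_id)
  if (!matrix$chars$active[j]) stop("character ", character_id, " is inactive")
  check_tree_matrix(tree, matrix)
  sub <- matrix
  sub$chars <- matrix$chars[j, , drop = FALSE]
  sub$bits <- matrix$bits[, j, drop = FALSE]
  sub$inap <- matrix$inap[, j, drop = FALSE]
  enc <- encode_matrix(sub, tip_order = tree$tip.label)
  as.integer(cpp_tree_steps(tree$edge, length(tree$tip.label), enc$X,
                            enc$ordered, enc$w))
}

#' Weighted parsimony length of a tree
#'
#' @inheritParams character_steps
#' @return sum of `weight_i * steps_i` over active characters
#' @export
tree_length <- function(tree, matrix) {
  s <- all_character_steps(tree, matrix)
  act <- matrix$chars$active
  sum(matrix$chars$weight[act] * s[act])
}

#' Minimum and maximum conceivable steps of a character
#'
#' `m` is the fewest steps the character can require on any tree, `g` the
#' most.  For an unordered character `m` is one less than the smallest set of
#' states that intersects every scored cell, and `g` is the number of scored
#' cells minus the size of the largest state class (polymorphic cells count
#' towards the class of any member state).  For an ordered character `m` is
#' the unavoidable range of the cell choices and `g` sums, over unit
#' intervals of the state scale, the smaller of the cell counts forced to
#' either side.
#'
#' @inheritParams character_steps
#' @return named numeric vector `c(m = ..., g = ...)`
#' @export
min_max_steps <- function(matrix, character_id) {
  j <- match(character_id, matrix$chars$id)
  if (is.na(j)) stop("unknown character id: ", character_id)
  col <- matrix$bits[, j]
  col <- col[col != 0L]  # missing/inapplicable cells are free
  if (length(col) == 0L) return(c(m = 0, g = 0))
  if (matrix$chars$ordered[j]) {
    lo <- vapply(col, function(b) min(bits_to_states(b)), 0L)
    hi <- vapply(col, function(b) max(bits_to_states(b)), 0L)
    m <- max(0L, max(lo) - min(hi))
    allst <- sort(unique(unlist(lapply(col, bits_to_states))))
    g <- 0L
    if (length(allst) > 1L) {
      for (t in seq(min(allst), max(allst) - 1L)) {
        below <- sum(hi <= t)
        above <- sum(lo > t)
        g <- g + min(below, above)
      }
    }
    return(c(m = m, g = g))
  }
  obs <- sort(unique(unlist(lapply(col, bits_to_states))))
  # m: minimum state set hitting every cell, minus one (exact search over
  # subsets of the <= 10 observed states, smallest first)
  m <- NA_integer_
  for (size in seq_along(obs)) {
    combos <- utils::combn(obs, size, simplify = FALSE)
    for (cs in combos) {
      mask <- states_to_bits(cs)
      if (all(bitwAnd(col, mask) > 0L)) { m <- size - 1L; break }
    }
    if (!is.na(m)) break
  }
  class_size <- vapply(obs, function(s)
    sum(bitwAnd(col, states_to_bits(s)) > 0L), 0L)
  g <- length(col) - max(class_size)
  c(m = m, g = g)
}

#' Length, ensemble CI/RI and implied-weights fit of a tree
#'
#' The ensemble consistency index is `sum(m) / sum(s)` and the ensemble
#' retention index `(sum(g) - sum(s)) / (sum(g) - sum(m))`, both over active
#' characters; characters with `g == m` (no possible homoplasy) are excluded
#' from the RI sums.  The retention index is unchanged by duplicating the
#' character set, which makes it comparable across matrices of different
#' size.  `fit` is the implied-weights score `sum(k / (k + h_i))`.
#'
#' @inheritParams character_steps
#' @param k implied-weights concavity (default 3)
#' @return an object of class `TreeScore`: list with `length`, `ci`, `ri`,
#'   `fit`, `k` and the per-character table `per_character`
#' @export
ensemble_indices <- function(tree, matrix, k = 3) {
  s <- all_character_steps(tree, matrix)
  act <- which(matrix$chars$active)
  mg <- vapply(matrix$chars$id[act], function(id)
    min_max_steps(matrix, id), c(m = 0, g = 0))
  w <- matrix$chars$weight[act]
  si <- s[act]
  mi <- mg["m", ]
  gi <- mg["g", ]
  hi <- pmax(0, si - mi)
  len <- sum(w * si)
  ci <- if (sum(w * si) > 0) sum(w * mi) / sum(w * si) else NA_real_
  keep <- gi > mi
  ri <- if (any(keep))
    sum(w[keep] * (gi[keep] - si[keep])) / sum(w[keep] * (gi[keep] - mi[keep]))
  else NA_real_
  fit <- sum(w * k / (k + hi))
  structure(list(length = len, ci = ci, ri = ri, fit = fit, k = k,
                 per_character = data.frame(
                   character_id = matrix$chars$id[act], s = si, m = mi,
                   g = gi, h = hi, weight = w, row.names = NULL)),
            class = "TreeScore")
}

#' @export
print.TreeScore <- function(x, ...) {
  cat(sprintf("TreeScore: length %g, CI %s, RI %s, fit %.4f (k = %g)\n",
              x$length,
              ifelse(is.na(x$ci), "undefined", sprintf("%.4f", x$ci)),
              ifelse(is.na(x$ri), "undefined", sprintf("%.4f", x$ri)),
              x$fit, x$k))
  invisible(x)
}

#' Implied-weights fit of a tree
#'
#' `F = sum(w_i * k / (k + h_i))` with homoplasy `h_i = s_i - m_i`; equals
#' the number of active characters exactly when the tree implies no
#' homoplasy.  Searches under the implied-weights objective maximise `F`.
#'
#' @inheritParams ensemble_indices
#' @return numeric fit value
#' @export
implied_weights_fit <- function(tree, matrix, k = 3) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("concavity k must be a positive number")
  ensemble_indices(tree, matrix, k = k)$fit
}
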