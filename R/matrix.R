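#' Construct a discrete character matrix
#'
#' The central container of the package: an ordered set of taxa scored for an
#' ordered set of discrete characters (states 0-9), with missing ("?"),
#' inapplicable ("-") and polymorphic cells, a designated outgroup, and
#' per-character metadata (1-based published id, ordered flag, activity,
#' weight).
#'
#' @param taxa character vector of unique taxon labels (rows)
#' @param cells a list-matrix or character matrix of cell codes: for the
#'   character-matrix form each entry is a token such as `"0"`, `"?"`, `"-"`
#'   or `"01"` (several digits = polymorphic)
#' @param outgroup subset of `taxa` used for rooting (may be empty)
#' @param ordered logical vector (recycled) marking additively ordered
#'   characters; default all unordered
#' @param ids integer character ids; default `1:nchar`
#' @param labels character labels; default `"char<i>"`
#' @param weights non-negative numeric weights, default 1
#' @return an object of class `CharacterMatrix`
#' @export
character_matrix <- function(taxa, cells, outgroup = character(0),
                             ordered = FALSE, ids = NULL, labels = NULL,
                             weights = 1) {
  taxa <- as.character(taxa)
  if (is.character(cells) && is.matrix(cells)) {
    nt <- nrow(cells); nc <- ncol(cells)
    if (nc == 0L) stop("matrix has no characters")
    bits <- matrix(0L, nt, nc)
    inap <- matrix(FALSE, nt, nc)
    for (i in seq_len(nt)) {
      for (j in seq_len(nc)) {
        tok <- cells[i, j]
        if (tok == "?") next
        if (tok == "-") { inap[i, j] <- TRUE; next }
        st <- suppressWarnings(as.integer(strsplit(tok, "")[[1]]))
        if (anyNA(st)) stop("bad cell token '", tok, "'")
        bits[i, j] <- states_to_bits(st)
      }
    }
  } else stop("cells must be a character matrix of state tokens")
  nc <- ncol(bits)
  if (is.null(ids)) ids <- seq_len(nc)
  if (is.null(labels)) labels <- paste0("char", ids)
  chars <- data.frame(id = as.integer(ids), label = as.character(labels),
                      ordered = rep_len(as.logical(ordered), nc),
                      active = TRUE,
                      weight = rep_len(as.numeric(weights), nc),
                      stringsAsFactors = FALSE)
  new_character_matrix(taxa, chars, bits, inap, outgroup)
}

# low-level constructor + validator
new_character_matrix <- function(taxa, chars, bits, inap, outgroup) {
  m <- structure(list(taxa = taxa, chars = chars, bits = bits, inap = inap,
                      outgroup = outgroup),
                 class = "CharacterMatrix")
  validate_character_matrix(m)
}

validate_character_matrix <- function(m) {
  with(m, {
    if (length(taxa) == 0L) stop("matrix has no taxa")
    if (nrow(chars) == 0L) stop("matrix has no characters")
    if (anyDuplicated(taxa)) stop("duplicate taxon labels")
    if (anyDuplicated(chars$id)) stop("duplicate character ids")
    if (!is.matrix(bits) || nrow(bits) != length(taxa) ||
        ncol(bits) != nrow(chars))
      stop("cell grid does not match taxa x characters")
    if (anyNA(bits)) stop("cell grid has holes (NA cells)")
    if (any(bits < 0L | bits > FULL_MASK)) stop("cell mask out of range")
    if (!all(dim(inap) == dim(bits))) stop("inapplicability grid mismatch")
    if (!all(outgroup %in% taxa)) stop("outgroup taxa not in matrix")
    if (any(chars$weight < 0)) stop("negative character weight")
    for (j in which(chars$ordered)) {
      st <- observed_states_of(bits[, j])
      if (length(st) > 1L && !all(diff(sort(st)) == 1L))
        stop("ordered character ", chars$id[j],
             " has non-consecutive states")
    }
  })
  m
}

observed_states_of <- function(col_bits) {
  bits_to_states(Reduce(bitwOr, col_bits, 0L))
}

#' @export
print.CharacterMatrix <- function(x, ...) {
  cat("CharacterMatrix:", length(x$taxa), "taxa x", nrow(x$chars),
      "characters\n")
  cat("  active characters:", sum(x$chars$active),
      "| ordered:", sum(x$chars$ordered), "\n")
  nm <- sum(x$bits == 0L & !x$inap)
  ni <- sum(x$inap)
  np <- sum(popcount10(x$bits) > 1L)
  cat(sprintf("  cells: %d missing, %d inapplicable, %d polymorphic (of %d)\n",
              nm, ni, np, length(x$bits)))
  if (length(x$outgroup))
    cat("  outgroup:", length(x$outgroup), "taxa\n")
  invisible(x)
}

#' Number of taxa / characters
#' @param matrix a `CharacterMatrix`
#' @export
n_taxa <- function(matrix) length(matrix$taxa)

#' @rdname n_taxa
#' @export
n_characters <- function(matrix) nrow(matrix$chars)

#' Drop taxa and/or characters from a matrix
#'
#' Character ids of the retained columns are kept as published (not
#' renumbered), so downstream reports stay citable.
#'
#' @param matrix a `CharacterMatrix`
#' @param drop_taxa taxon labels to remove
#' @param drop_characters character ids to remove
#' @return a new `CharacterMatrix`; the input is unchanged
#' @export
subset_matrix <- function(matrix, drop_taxa = character(0),
                          drop_characters = integer(0)) {
  stopifnot(inherits(matrix, "CharacterMatrix"))
  bad <- setdiff(drop_taxa, matrix$taxa)
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  bad <- setdiff(drop_characters, matrix$chars$id)
  if (length(bad)) stop("unknown character ids: ", paste(bad, collapse = ", "))
  keep_t <- !(matrix$taxa %in% drop_taxa)
  keep_c <- !(matrix$chars$id %in% drop_characters)
  if (!any(keep_t)) stop("cannot drop all taxa")
  if (!any(keep_c)) stop("cannot drop all characters")
  new_character_matrix(
    matrix$taxa[keep_t],
    matrix$chars[keep_c, , drop = FALSE],
    matrix$bits[keep_t, keep_c, drop = FALSE],
    matrix$inap[keep_t, keep_c, drop = FALSE],
    intersect(matrix$outgroup, matrix$taxa[keep_t]))
}

#' Activate or deactivate characters without removing them
#' @param matrix a `CharacterMatrix`
#' @param ids character ids to touch
#' @param active logical
#' @export
set_active <- function(matrix, ids, active) {
  j <- match(ids, matrix$chars$id)
  if (anyNA(j)) stop("unknown character ids: ",
                     paste(ids[is.na(j)], collapse = ", "))
  matrix$chars$active[j] <- active
  matrix
}

# grid equality used by round-trip tests: taxa, ids, masks, inapplicability,
# ordered flags
same_state_grid <- function(a, b) {
  identical(a$taxa, b$taxa) &&
    identical(a$chars$id, b$chars$id) &&
    identical(a$chars$ordered, b$chars$ordered) &&
    identical(unname(a$bits), unname(b$bits)) &&
    identical(unname(a$inap), unname(b$inap))
}

# Encode the active characters of a matrix for the scoring kernels:
# n_char x n_tip mask matrix (missing/inapplicable -> full mask), plus
# weights (0 for inactive), ordered flags, and per-character minimum steps.
encode_matrix <- function(matrix, tip_order = NULL) {
  bits <- matrix$bits
  if (!is.null(tip_order)) {
    idx <- match(tip_order, matrix$taxa)
    if (anyNA(idx)) stop("tree tips do not match matrix taxa")
    bits <- bits[idx, , drop = FALSE]
  }
  X <- t(bits)
  X[X == 0L] <- FULL_MASK
  w <- matrix$chars$weight * as.numeric(matrix$chars$active)
  list(X = X, ordered = matrix$chars$ordered, w = w)
}
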