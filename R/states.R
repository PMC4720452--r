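# Cell state sets are stored as 10-bit masks: bit s (0-9) set <=> state s is
# a member.  Mask 0 with inap = FALSE means missing ("?"), with inap = TRUE
# inapplicable ("-").  Both score identically (free assignment) but are kept
# apart so files round-trip.

FULL_MASK <- 1023L

states_to_bits <- function(states) {
  if (length(states) == 0L) return(0L)
  stopifnot(all(states >= 0L & states <= 9L))
  as.integer(sum(bitwShiftL(1L, unique(as.integer(states)))))
}

bits_to_states <- function(bits) {
  which(bitwAnd(bits, bitwShiftL(1L, 0:9)) > 0L) - 1L
}

popcount10 <- function(bits) {
  n <- integer(length(bits))
  for (s in 0:9) n <- n + (bitwAnd(bits, bitwShiftL(1L, s)) > 0L)
  n
}

#' Describe one cell of a character matrix
#'
#' @param matrix a `CharacterMatrix`
#' @param taxon taxon label
#' @param character_id 1-based character id (as published)
#' @return a list with elements `kind` (one of `"determinate"`,
#'   `"polymorphic"`, `"missing"`, `"inapplicable"`) and `states`
#'   (integer vector, empty for missing/inapplicable cells).
#' @export
state_set <- function(matrix, taxon, character_id) {
  stopifnot(inherits(matrix, "CharacterMatrix"))
  i <- match(taxon, matrix$taxa)
  if (is.na(i)) stop("unknown taxon: ", taxon)
  j <- match(character_id, matrix$chars$id)
  if (is.na(j)) stop("unknown character id: ", character_id)
  b <- matrix$bits[i, j]
  if (b == 0L) {
    kind <- if (matrix$inap[i, j]) "inapplicable" else "missing"
    return(list(kind = kind, states = integer(0)))
  }
  st <- bits_to_states(b)
  list(kind = if (length(st) == 1L) "determinate" else "polymorphic",
       states = st)
}
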