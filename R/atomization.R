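# Compound characters conflate logically independent attributes in a single
# column (e.g. "fossa: absent / round / keyhole-shaped" mixing presence and
# shape).  Atomization replaces such a column by two or more atomic columns
# through an explicit state map, so that each attribute is scored on its own.

#' Define an atomization rule
#'
#' @param source_id id of the compound character to replace
#' @param target_labels labels for the >= 2 atomic characters that replace it
#' @param state_map named list: each name is a source state (as character),
#'   each value an integer vector of target states, one per target character.
#'   Use `NA` for "inapplicable for this target".
#' @param ordered logical (recycled) for the target characters
#' @return an object of class `AtomizationRule`
#' @export
atomization_rule <- function(source_id, target_labels, state_map,
                             ordered = FALSE) {
  if (length(target_labels) < 2L)
    stop("a rule must produce at least 2 target characters")
  nt <- length(target_labels)
  for (v in state_map)
    if (length(v) != nt)
      stop("every state_map entry needs one target state per target character")
  # each target must vary across the map, otherwise it would be constant
  for (k in seq_len(nt)) {
    vals <- unique(stats::na.omit(vapply(state_map, `[`, 0, k)))
    if (length(vals) < 2L)
      stop("target '", target_labels[k], "' of rule for character ",
           source_id, " would be constant")
  }
  structure(list(source_id = as.integer(source_id),
                 target_labels = as.character(target_labels),
                 state_map = state_map,
                 ordered = rep_len(as.logical(ordered), nt)),
            class = "AtomizationRule")
}

#' Atomize compound characters
#'
#' Applies a set of [atomization_rule()]s to a matrix.  Each compound column
#' is replaced, at its position, by its target columns (which receive fresh
#' ids above the current maximum).  Missing and inapplicable source cells
#' propagate unchanged to all targets; a polymorphic source cell maps to the
#' union of its member states' target tuples, per target.
#'
#' @param matrix a `CharacterMatrix`
#' @param rules list of `AtomizationRule`s touching distinct source ids
#' @return a list with `matrix` (the recoded `CharacterMatrix`) and `report`
#'   (a `RecodingReport`: rule and character tallies)
#' @export
atomize <- function(matrix, rules) {
  stopifnot(inherits(matrix, "CharacterMatrix"))
  if (length(rules) == 0L)
    return(list(matrix = matrix,
                report = recoding_report(0L, n_characters(matrix),
                                         n_characters(matrix))))
  src <- vapply(rules, function(r) r$source_id, 0L)
  if (anyDuplicated(src)) stop("rules touch duplicate source characters")
  miss <- setdiff(src, matrix$chars$id)
  if (length(miss)) stop("unknown source characters: ",
                         paste(miss, collapse = ", "))
  j_by_id <- match(src, matrix$chars$id)
  if (!all(matrix$chars$active[j_by_id]))
    stop("source characters must be active")

  next_id <- max(matrix$chars$id) + 1L
  nt_tax <- n_taxa(matrix)
  cols_bits <- lapply(seq_len(n_characters(matrix)),
                      function(j) matrix$bits[, j])
  cols_inap <- lapply(seq_len(n_characters(matrix)),
                      function(j) matrix$inap[, j])
  chars <- split(matrix$chars, seq_len(nrow(matrix$chars)))

  for (r in rules) {
    j <- match(r$source_id, vapply(chars, function(d) d$id, 0L))
    src_bits <- cols_bits[[j]]
    src_inap <- cols_inap[[j]]
    ntgt <- length(r$target_labels)
    tgt_bits <- base::matrix(0L, nt_tax, ntgt)
    tgt_inap <- base::matrix(FALSE, nt_tax, ntgt)
    for (i in seq_len(nt_tax)) {
      if (src_bits[i] == 0L) {  # missing / inapplicable propagates
        tgt_inap[i, ] <- src_inap[i]
        next
      }
      for (s in bits_to_states(src_bits[i])) {
        tup <- r$state_map[[as.character(s)]]
        if (is.null(tup))
          stop("state ", s, " of character ", r$source_id,
               " (taxon '", matrix$taxa[i], "') is not covered by the rule")
        for (k in seq_len(ntgt)) {
          if (is.na(tup[k])) tgt_inap[i, k] <- TRUE
          else tgt_bits[i, k] <- bitwOr(tgt_bits[i, k],
                                        states_to_bits(tup[k]))
        }
      }
      # a cell that received states is not inapplicable after all
      tgt_inap[i, tgt_bits[i, ] > 0L] <- FALSE
    }
    new_defs <- lapply(seq_len(ntgt), function(k) {
      data.frame(id = next_id + k - 1L, label = r$target_labels[k],
                 ordered = r$ordered[k], active = TRUE,
                 weight = chars[[j]]$weight, stringsAsFactors = FALSE)
    })
    next_id <- next_id + ntgt
    before <- seq_len(j - 1L)
    after <- seq_along(chars)[-seq_len(j)]
    chars <- c(chars[before], new_defs, chars[after])
    cols_bits <- c(cols_bits[before], lapply(seq_len(ntgt), function(k)
      tgt_bits[, k]), cols_bits[after])
    cols_inap <- c(cols_inap[before], lapply(seq_len(ntgt), function(k)
      tgt_inap[, k]), cols_inap[after])
  }

  chars_df <- do.call(rbind, chars)
  rownames(chars_df) <- NULL
  out <- new_character_matrix(matrix$taxa, chars_df,
                              do.call(cbind, cols_bits),
                              do.call(cbind, cols_inap),
                              matrix$outgroup)
  rep <- recoding_report(length(rules), n_characters(matrix),
                         n_characters(out))
  list(matrix = out, report = rep)
}

recoding_report <- function(n_rules, n_before, n_after,
                            reduced = data.frame()) {
  structure(list(n_rules_applied = n_rules,
                 n_characters_before = n_before,
                 n_characters_after = n_after,
                 n_added = n_after - n_before,
                 reduced_state_characters = reduced),
            class = "RecodingReport")
}

#' @export
print.RecodingReport <- function(x, ...) {
  cat("RecodingReport:", x$n_rules_applied, "rules applied;",
      x$n_characters_before, "->", x$n_characters_after,
      "characters (", x$n_added, "added )\n")
  if (nrow(x$reduced_state_characters))
    cat("  state reductions:", nrow(x$reduced_state_characters),
        "characters\n")
  invisible(x)
}

#' Merge states of one character
#'
#' Recode a single column through an old-state to new-state map, e.g. to
#' collapse a three-state character to two states.
#'
#' @param matrix a `CharacterMatrix`
#' @param character_id id of the column to recode
#' @param merge_map named integer vector: names are old states, values new
#'   states; must reach fewer states than it consumes
#' @return the recoded `CharacterMatrix`
#' @export
reduce_states <- function(matrix, character_id, merge_map) {
  stopifnot(inherits(matrix, "CharacterMatrix"))
  j <- match(character_id, matrix$chars$id)
  if (is.na(j)) stop("unknown character id: ", character_id)
  old <- as.integer(names(merge_map))
  new <- as.integer(merge_map)
  if (anyNA(old) || anyNA(new)) stop("merge_map must map integer states")
  if (length(unique(new)) >= length(unique(old)))
    stop("merge_map does not reduce the state count")
  if (length(unique(new)) < 2L)
    stop("merging to a single state would make the character constant")
  obs <- observed_states_of(matrix$bits[, j])
  miss <- setdiff(obs, old)
  if (length(miss)) stop("states not covered by merge_map: ",
                         paste(miss, collapse = ", "))
  recode_one <- function(b) {
    if (b == 0L) return(b)
    states_to_bits(unique(new[match(bits_to_states(b), old)]))
  }
  matrix$bits[, j] <- vapply(matrix$bits[, j], recode_one, 0L)
  validate_character_matrix(matrix)
}

#' Read atomization rules from a TSV table
#'
#' Columns: `source_id`, `target_labels` (pipe-separated), `state_map`
#' (entries `old=t1,t2,...` separated by `;`, `NA` allowed for a target).
#'
#' @param path TSV file path
#' @return list of [atomization_rule()]s
#' @export
read_atomization_rules <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_id", "target_labels", "state_map")
  if (!all(need %in% names(tab)))
    stop("rule table needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    labs <- strsplit(tab$target_labels[i], "|", fixed = TRUE)[[1]]
    entries <- strsplit(tab$state_map[i], ";", fixed = TRUE)[[1]]
    sm <- list()
    for (e in entries) {
      kv <- strsplit(trimws(e), "=", fixed = TRUE)[[1]]
      sm[[trimws(kv[1])]] <- suppressWarnings(
        as.integer(strsplit(kv[2], ",", fixed = TRUE)[[1]]))
    }
    atomization_rule(as.integer(tab$source_id[i]), labs, sm)
  })
}

#' Write atomization rules to the TSV form read by [read_atomization_rules()]
#' @param rules list of `AtomizationRule`s
#' @param path output path
#' @export
write_atomization_rules <- function(rules, path) {
  rows <- lapply(rules, function(r) {
    sm <- paste(vapply(names(r$state_map), function(s)
      paste0(s, "=", paste(r$state_map[[s]], collapse = ",")), ""),
      collapse = ";")
    data.frame(source_id = r$source_id,
               target_labels = paste(r$target_labels, collapse = "|"),
               state_map = sm, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
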