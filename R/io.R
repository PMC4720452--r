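# NEXUS (DATA/CHARACTERS + ASSUMPTIONS typeset + SETS taxset) and TNT xread
# readers/writers for discrete morphological matrices.  Both dialects carry
# states 0-9, "?" missing, "-" inapplicable; polymorphism is "(01)"/"{01}" in
# NEXUS and "[01]"/"{01}" in TNT.  Interleaved matrices (repeated taxon rows)
# are concatenated.

#' Read a character matrix
#'
#' @param path file path
#' @param dialect `"nexus"` or `"tnt"`
#' @return a validated [character_matrix()] object
#' @export
read_matrix <- function(path, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (dialect == "nexus") parse_nexus(txt) else parse_tnt(txt)
}

#' Write a character matrix
#'
#' The emitted file re-reads (with [read_matrix()]) to a matrix with an
#' identical state grid, ordered flags, and outgroup.
#'
#' @param matrix a `CharacterMatrix`
#' @param path output file path
#' @param dialect `"nexus"` or `"tnt"`
#' @return `path`, invisibly
#' @export
write_matrix <- function(matrix, path, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(matrix, "CharacterMatrix"))
  validate_character_matrix(matrix)
  if (dialect == "nexus") write_nexus(matrix, path) else write_tnt(matrix, path)
  invisible(path)
}

# --- cell tokenisation ------------------------------------------------------

# parse one row of cell symbols into (bits, inap); poly_open/close name the
# polymorphism delimiters of the dialect
parse_cell_string <- function(s, poly_open, poly_close, where) {
  chars <- strsplit(s, "")[[1]]
  bits <- integer(0)
  inap <- logical(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "?") {
      bits <- c(bits, 0L); inap <- c(inap, FALSE)
    } else if (ch == "-") {
      bits <- c(bits, 0L); inap <- c(inap, TRUE)
    } else if (grepl("^[0-9]$", ch)) {
      bits <- c(bits, states_to_bits(as.integer(ch)))
      inap <- c(inap, FALSE)
    } else if (ch %in% poly_open) {
      close_ch <- poly_close[match(ch, poly_open)]
      j <- i + 1L
      st <- integer(0)
      while (j <= length(chars) && chars[j] != close_ch) {
        if (grepl("^[0-9]$", chars[j])) st <- c(st, as.integer(chars[j]))
        else if (!chars[j] %in% c(" ", ","))
          stop("unknown state symbol '", chars[j], "' in ", where,
               " at position ", j)
        j <- j + 1L
      }
      if (j > length(chars)) stop("unclosed polymorphism in ", where)
      if (length(st) == 0L) stop("empty polymorphism in ", where)
      bits <- c(bits, states_to_bits(st))
      inap <- c(inap, FALSE)
      i <- j
    } else {
      stop("unknown state symbol '", ch, "' in ", where, " at position ", i)
    }
    i <- i + 1L
  }
  list(bits = bits, inap = inap)
}

format_cell <- function(bits, inap, open, close) {
  if (bits == 0L) return(if (inap) "-" else "?")
  st <- bits_to_states(bits)
  if (length(st) == 1L) return(as.character(st))
  paste0(open, paste(st, collapse = ""), close)
}

# split a matrix row into taxon label (possibly 'quoted') and the rest
split_row <- function(line) {
  line <- trimws(line)
  if (startsWith(line, "'")) {
    m <- regmatches(line, regexpr("^'[^']*'", line))
    name <- gsub("'", "", m)
    rest <- trimws(substring(line, nchar(m) + 1L))
  } else {
    m <- regmatches(line, regexpr("^\\S+", line))
    name <- m
    rest <- trimws(substring(line, nchar(m) + 1L))
  }
  list(name = name, cells = rest)
}

parse_index_list <- function(s) {
  out <- integer(0)
  for (tok in strsplit(trimws(s), "\\s+")[[1]]) {
    if (grepl("^[0-9]+-[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    }
  }
  out
}

# --- NEXUS ------------------------------------------------------------------

parse_nexus <- function(txt) {
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) stop("not a NEXUS file")
  body <- gsub("\\[[^]]*\\]", " ", txt)  # square brackets are comments
  dim_m <- regmatches(body, regexpr(
    "DIMENSIONS[^;]*;", body, ignore.case = TRUE))
  if (!length(dim_m)) stop("no DIMENSIONS statement")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", dim_m,
                         ignore.case = TRUE))
  nchr <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dim_m,
                         ignore.case = TRUE))
  mat_m <- regmatches(body, regexpr(
    "\\bMATRIX\\b[^;]*;", body, ignore.case = TRUE))
  if (!length(mat_m)) stop("no MATRIX block")
  rows <- strsplit(sub(";$", "", sub("^\\s*MATRIX", "", mat_m,
                                     ignore.case = TRUE)), "\n")[[1]]
  parsed <- parse_matrix_rows(rows, poly_open = c("(", "{"),
                              poly_close = c(")", "}"))
  check_declared_dims(parsed, ntax, nchr)
  ordered <- rep(FALSE, nchr)
  ts <- regmatches(body, regexpr("TYPESET[^;]*;", body, ignore.case = TRUE))
  if (length(ts)) {
    grp <- regmatches(ts, gregexpr("\\bord\\s*:[^,;]*", ts,
                                   ignore.case = TRUE))[[1]]
    for (g in grp)
      ordered[parse_index_list(sub("^\\s*ord\\s*:", "", g,
                                   ignore.case = TRUE))] <- TRUE
  }
  outgroup <- character(0)
  tx <- regmatches(body, regexpr("TAXSET\\s+outgroup[^;]*;", body,
                                 ignore.case = TRUE))
  if (length(tx)) {
    idx <- parse_index_list(sub(";$", "", sub(".*=", "", tx)))
    outgroup <- parsed$taxa[idx]
  }
  build_from_parsed(parsed, ordered, outgroup)
}

write_nexus <- function(m, path) {
  nt <- n_taxa(m); nc <- n_characters(m)
  labs <- ifelse(grepl("[ '(){}\\[\\];]", m$taxa),
                 paste0("'", m$taxa, "'"), m$taxa)
  pad <- max(nchar(labs)) + 2L
  lines <- c("#NEXUS", "", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nt, nc),
             "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
             "  MATRIX")
  for (i in seq_len(nt)) {
    row <- paste(vapply(seq_len(nc), function(j)
      format_cell(m$bits[i, j], m$inap[i, j], "(", ")"), ""), collapse = "")
    lines <- c(lines, sprintf("    %-*s%s", pad, labs[i], row))
  }
  lines <- c(lines, "  ;", "END;")
  ord <- which(m$chars$ordered)
  if (length(ord)) {
    unord <- setdiff(seq_len(nc), ord)
    lines <- c(lines, "", "BEGIN ASSUMPTIONS;",
               sprintf("  TYPESET * cladatom = ord: %s, unord: %s;",
                       paste(ord, collapse = " "),
                       paste(unord, collapse = " ")),
               "END;")
  }
  if (length(m$outgroup)) {
    lines <- c(lines, "", "BEGIN SETS;",
               sprintf("  TAXSET outgroup = %s;",
                       paste(match(m$outgroup, m$taxa), collapse = " ")),
               "END;")
  }
  writeLines(lines, path)
}

# --- TNT --------------------------------------------------------------------

parse_tnt <- function(txt) {
  txt <- gsub("'[^']*'", " ", txt)  # quoted titles/comments
  pos <- regexpr("xread", txt, ignore.case = TRUE)
  if (pos < 0) stop("no xread block")
  rest <- substring(txt, pos + 5L)
  hdr <- regmatches(rest, regexpr("^\\s*([0-9]+)\\s+([0-9]+)", rest))
  if (!length(hdr)) stop("xread header must declare nchar ntax")
  nums <- as.integer(strsplit(trimws(hdr), "\\s+")[[1]])
  nchr <- nums[1]; ntax <- nums[2]
  body <- substring(rest, nchar(hdr) + 1L)
  end <- regexpr(";", body, fixed = TRUE)
  if (end < 0) stop("xread block not terminated by ';'")
  rows <- strsplit(substring(body, 1L, end - 1L), "\n")[[1]]
  parsed <- parse_matrix_rows(rows, poly_open = c("[", "{"),
                              poly_close = c("]", "}"))
  check_declared_dims(parsed, ntax, nchr)
  ordered <- rep(FALSE, nchr)
  cc <- regmatches(txt, regexpr("ccode\\s*\\+[^;]*;", txt,
                                ignore.case = TRUE))
  if (length(cc)) {
    idx <- parse_index_list(gsub("[^0-9 -]", " ", sub("ccode\\s*\\+", "", cc)))
    ordered[idx + 1L] <- TRUE  # ccode is 0-based
  }
  build_from_parsed(parsed, ordered, character(0))
}

write_tnt <- function(m, path) {
  nt <- n_taxa(m); nc <- n_characters(m)
  labs <- gsub("[^A-Za-z0-9_.]", "_", m$taxa)
  if (anyDuplicated(labs)) stop("taxon labels collide after TNT sanitising")
  pad <- max(nchar(labs)) + 2L
  lines <- c("xread", "'written by cladatom'", sprintf("%d %d", nc, nt))
  for (i in seq_len(nt)) {
    row <- paste(vapply(seq_len(nc), function(j)
      format_cell(m$bits[i, j], m$inap[i, j], "[", "]"), ""), collapse = "")
    lines <- c(lines, sprintf("%-*s%s", pad, labs[i], row))
  }
  lines <- c(lines, ";")
  ord <- which(m$chars$ordered)
  if (length(ord))
    lines <- c(lines, sprintf("ccode + %s;", paste(ord - 1L, collapse = " ")))
  lines <- c(lines, "proc /;")
  writeLines(lines, path)
}

# --- shared -----------------------------------------------------------------

parse_matrix_rows <- function(rows, poly_open, poly_close) {
  taxa <- character(0)
  cells <- list()
  for (line in rows) {
    if (!nzchar(trimws(line))) next
    sr <- split_row(line)
    parsed <- parse_cell_string(sr$cells, poly_open, poly_close,
                                paste0("row '", sr$name, "'"))
    if (sr$name %in% taxa) {  # interleaved continuation
      k <- match(sr$name, taxa)
      cells[[k]]$bits <- c(cells[[k]]$bits, parsed$bits)
      cells[[k]]$inap <- c(cells[[k]]$inap, parsed$inap)
    } else {
      taxa <- c(taxa, sr$name)
      cells[[length(taxa)]] <- parsed
    }
  }
  list(taxa = taxa, cells = cells)
}

check_declared_dims <- function(parsed, ntax, nchr) {
  if (length(parsed$taxa) != ntax)
    stop("declared NTAX=", ntax, " but found ", length(parsed$taxa), " rows")
  for (k in seq_along(parsed$taxa)) {
    got <- length(parsed$cells[[k]]$bits)
    if (got != nchr)
      stop("row '", parsed$taxa[k], "' has ", got,
           " characters, declared NCHAR=", nchr)
  }
}

build_from_parsed <- function(parsed, ordered, outgroup) {
  nt <- length(parsed$taxa)
  nc <- length(parsed$cells[[1]]$bits)
  bits <- do.call(rbind, lapply(parsed$cells, function(z) z$bits))
  inap <- do.call(rbind, lapply(parsed$cells, function(z) z$inap))
  chars <- data.frame(id = seq_len(nc), label = paste0("char", seq_len(nc)),
                      ordered = ordered, active = TRUE, weight = 1,
                      stringsAsFactors = FALSE)
  new_character_matrix(parsed$taxa, chars, bits, inap, outgroup)
}
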