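# Shared fixtures and independent brute-force oracles.

# build a CharacterMatrix from named row strings, e.g.
# cm(A = "01", B = "0?", C = "1[01]")  (brackets/parens = polymorphic)
cm <- function(..., ordered = FALSE, outgroup = character(0)) {
  rows <- list(...)
  taxa <- names(rows)
  toks <- lapply(rows, function(s) {
    out <- character(0)
    chars <- strsplit(s, "")[[1]]
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch %in% c("[", "(", "{")) {
        j <- i + 1L
        close_ch <- c("]", ")", "}")[match(ch, c("[", "(", "{"))]
        while (chars[j] != close_ch) j <- j + 1L
        out <- c(out, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
        i <- j
      } else out <- c(out, ch)
      i <- i + 1L
    }
    out
  })
  character_matrix(taxa, do.call(rbind, toks), ordered = ordered,
                   outgroup = outgroup)
}

# Brute-force minimum steps: enumerate every assignment of observed states
# to internal nodes and tips (tips restricted to their cell sets; free cells
# range over all observed states).
oracle_steps <- function(tree, matrix, character_id, ordered = NULL) {
  j <- match(character_id, matrix$chars$id)
  if (is.null(ordered)) ordered <- matrix$chars$ordered[j]
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  cells <- lapply(match(tr$tip.label, matrix$taxa), function(i) {
    b <- matrix$bits[i, j]
    if (b == 0L) integer(0) else {
      s <- integer(0)
      for (st in 0:9) if (bitwAnd(b, bitwShiftL(1L, st)) > 0L) s <- c(s, st)
      s
    }
  })
  obs <- sort(unique(unlist(cells)))
  if (length(obs) <= 1L) return(0L)
  cost <- if (ordered) function(a, b) abs(a - b) else
    function(a, b) as.integer(a != b)
  tipsets <- lapply(cells, function(s) if (length(s)) s else obs)
  internal <- (n + 1L):nn
  grid_int <- expand.grid(rep(list(obs), length(internal)))
  grid_tip <- expand.grid(tipsets)
  best <- Inf
  for (gi in seq_len(nrow(grid_int))) {
    asg <- integer(nn)
    asg[internal] <- as.integer(grid_int[gi, ])
    for (ti in seq_len(nrow(grid_tip))) {
      asg[seq_len(n)] <- as.integer(grid_tip[ti, ])
      tot <- 0L
      for (k in seq_len(nrow(tr$edge)))
        tot <- tot + cost(asg[tr$edge[k, 1]], asg[tr$edge[k, 2]])
      if (tot < best) best <- tot
    }
  }
  best
}

random_tree <- function(n) {
  ape::unroot(ape::rtopology(n, rooted = FALSE,
                             tip.label = paste0("t", seq_len(n))))
}

# random token matrix with missing cells and occasional polymorphisms
random_tokens <- function(n, nc, n_states = 2, p_missing = 0.1,
                          p_poly = 0.05) {
  tok <- matrix(as.character(sample(0:(n_states - 1), n * nc,
                                    replace = TRUE)), n, nc)
  poly <- runif(n * nc) < p_poly & n_states > 1
  tok[poly] <- vapply(which(poly), function(i)
    paste(sample(0:(n_states - 1), 2), collapse = ""), "")
  tok[runif(n * nc) < p_missing] <- "?"
  tok
}

random_matrix <- function(n, nc, ...) {
  character_matrix(paste0("t", seq_len(n)), random_tokens(n, nc, ...))
}
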