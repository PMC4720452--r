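# Character jackknife by tree-length decay.  Random character subsets are
# removed without replacement, the reduced matrix is re-searched, and the
# relationship between removed/analysed character counts and best tree
# length is summarised by two bivariate analyses: the decay of tree length
# as characters are removed, and an OLS regression of tree length on the
# number of characters analysed.  Comparing the regression lines of two
# matrices over the same taxa separates a change in character conflict from
# a mere change in character count.

#' Run a character-jackknife experiment
#'
#' For each removal count and replicate, draws that many active characters
#' uniformly without replacement, removes them (weight 0), re-runs
#' [heuristic_search()] under the equal-weights objective, and records the
#' replicate tree length.  Deterministic given `seed`.
#'
#' @param matrix a `CharacterMatrix`
#' @param removal_counts integer vector of how many characters to remove
#' @param reps_per_count replicates per removal count
#' @param search a [search_config()] used for every replicate search (its
#'   `seed` is ignored; the experiment's `seed` governs everything)
#' @param seed integer seed
#' @return a `data.frame` of class `jackknife_replicates` with columns
#'   `n_removed`, `n_analysed`, `replicate_length`, `delta`
#'   (full-matrix length minus replicate length) and `removed_ids`
#'   (comma-separated 1-based character ids); the full-matrix length is
#'   attached as attribute `"full_length"`
#' @export
run_jackknife <- function(matrix, removal_counts, reps_per_count = 20,
                          search = search_config(n_random_additions = 2),
                          seed = NULL) {
  act_ids <- matrix$chars$id[matrix$chars$active]
  n_act <- length(act_ids)
  if (any(removal_counts >= n_act))
    stop("removal counts must be smaller than the number of active ",
         "characters (", n_act, ")")
  if (any(removal_counts < 0)) stop("negative removal count")
  if (!is.null(seed)) set.seed(seed)
  search$seed <- NULL  # replicates consume the experiment's seeded stream
  base_w <- matrix$chars$weight * as.numeric(matrix$chars$active)
  full <- heuristic_search(matrix, search)
  full_len <- full$best_score$length
  # per-character steps of the full-matrix optimum: every replicate search is
  # effectively seeded with this tree, so a replicate can never score worse
  # than the full optimum restricted to its characters
  s_full <- all_character_steps(full$mpts[[1]], matrix)
  rows <- list()
  for (cnt in removal_counts) {
    for (r in seq_len(reps_per_count)) {
      removed <- if (cnt > 0) sort(sample(act_ids, cnt)) else integer(0)
      w <- base_w
      w[matrix$chars$id %in% removed] <- 0
      len <- if (cnt > 0)
        min(heuristic_search(matrix, search, weights = w)$replicate_length,
            sum(w * s_full))
      else full_len
      rows[[length(rows) + 1L]] <- data.frame(
        n_removed = cnt, n_analysed = n_act - cnt,
        replicate_length = len, delta = full_len - len,
        removed_ids = paste(removed, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "full_length") <- full_len
  class(out) <- c("jackknife_replicates", class(out))
  out
}

#' Tree-length decay data from jackknife replicates
#'
#' @param replicates a [run_jackknife()] result
#' @return list with `points` (`n_removed`, `delta` per replicate) and
#'   `means` (mean delta per removal count)
#' @export
decay_plot_data <- function(replicates) {
  if (nrow(replicates) == 0L) stop("no replicates")
  points <- replicates[, c("n_removed", "delta")]
  means <- aggregate(delta ~ n_removed, data = points, FUN = mean)
  names(means)[2] <- "mean_delta"
  list(points = points, means = means)
}

#' OLS regression of tree length on characters analysed
#'
#' @param replicates a [run_jackknife()] result
#' @return a `RegressionSummary`: list with `slope`, `intercept`,
#'   `n_points`, `which`
#' @export
length_plot_regression <- function(replicates) {
  x <- replicates$n_analysed
  y <- replicates$replicate_length
  if (length(unique(x)) < 3L)
    stop("need replicates at >= 3 distinct analysed-character counts")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n_points = length(x),
                 which = "length_vs_analysed"),
            class = "RegressionSummary")
}

#' @export
print.RegressionSummary <- function(x, ...) {
  cat(sprintf("RegressionSummary (%s): length = %.3f + %.4f * n, %d points\n",
              x$which, x$intercept, x$slope, x$n_points))
  invisible(x)
}

#' Compare two matrices by jackknife tree-length decay
#'
#' Runs the same jackknife protocol on both matrices (which must share a
#' taxon set), fits the length-vs-analysed regression for each, and reports
#' the full-matrix length difference, the predicted length difference at
#' matched character counts from the regression lines (evaluated over the
#' overlapping range of analysed-character counts), and the retention index
#' of each matrix's best tree.  A positive `regression_difference` means the
#' first matrix needs more steps per analysed character count, i.e. carries
#' more character conflict.
#'
#' @param matrix_a,matrix_b `CharacterMatrix` objects over the same taxa
#' @param removal_fracs fractions of characters to remove (per matrix)
#' @param reps_per_count replicates per removal count
#' @param search a [search_config()] for all searches
#' @param seed integer seed
#' @return a list of class `matrix_comparison`
#' @export
compare_matrices <- function(matrix_a, matrix_b,
                             removal_fracs = seq(0.05, 0.5, by = 0.05),
                             reps_per_count = 20,
                             search = search_config(n_random_additions = 2),
                             seed = NULL) {
  if (!setequal(matrix_a$taxa, matrix_b$taxa))
    stop("matrices do not share a taxon set")
  if (!is.null(seed)) set.seed(seed)
  counts_of <- function(m) {
    n_act <- sum(m$chars$active)
    unique(pmax(1L, pmin(n_act - 1L, round(removal_fracs * n_act))))
  }
  jk_a <- run_jackknife(matrix_a, counts_of(matrix_a), reps_per_count, search)
  jk_b <- run_jackknife(matrix_b, counts_of(matrix_b), reps_per_count, search)
  reg_a <- length_plot_regression(jk_a)
  reg_b <- length_plot_regression(jk_b)
  len_a <- attr(jk_a, "full_length")
  len_b <- attr(jk_b, "full_length")
  lo <- max(min(jk_a$n_analysed), min(jk_b$n_analysed))
  hi <- min(max(jk_a$n_analysed), max(jk_b$n_analysed))
  grid <- seq(lo, hi, length.out = 25)
  pred_a <- reg_a$intercept + reg_a$slope * grid
  pred_b <- reg_b$intercept + reg_b$slope * grid
  # retention index of each matrix's best tree (search once more, seeded on)
  ri_of <- function(m) {
    res <- heuristic_search(m, search)
    res$best_score$ri
  }
  structure(list(
    full_length_a = len_a, full_length_b = len_b,
    full_length_difference = len_a - len_b,
    regression_a = reg_a, regression_b = reg_b,
    matched_count_range = c(lo, hi),
    regression_difference = mean(pred_a - pred_b),
    regression_difference_midrange =
      (pred_a - pred_b)[13],
    ri_a = ri_of(matrix_a), ri_b = ri_of(matrix_b),
    jackknife_a = jk_a, jackknife_b = jk_b),
    class = "matrix_comparison")
}

#' @export
print.matrix_comparison <- function(x, ...) {
  cat("matrix_comparison\n")
  cat(sprintf("  full-matrix lengths: %g vs %g (difference %g)\n",
              x$full_length_a, x$full_length_b, x$full_length_difference))
  cat(sprintf("  regression lines differ by %.1f steps over matched counts %d-%d\n",
              x$regression_difference, x$matched_count_range[1],
              x$matched_count_range[2]))
  cat(sprintf("  retention index: %.4f vs %.4f\n", x$ri_a, x$ri_b))
  invisible(x)
}
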