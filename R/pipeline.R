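# End-to-end orchestration: input (file or synthetic preset) -> atomization
# -> heuristic search -> bootstrap -> consensus -> diagnostics -> optional
# jackknife comparison, with every stage's outputs and seed written under an
# output directory and summarised in a JSON run manifest.

#' Run the full analysis pipeline
#'
#' `config` is a YAML file path or an equivalent named list.  Recognised
#' fields: `out_dir`; `seed`; either `input` (list with `path`, `dialect`,
#' optional `outgroup` labels) or `synthetic: true` with optional
#' [simulation_config()] overrides under `simulation`; optional
#' `atomization_rules` (TSV path); `search` ([search_config()] overrides);
#' `bootstrap` (`reps`, or `false` to skip); `diagnostics` (`true` to map
#' apomorphies on the first optimal tree); `compare` (list with `path` and
#' `dialect` of a second matrix, jackknifed against the first).
#'
#' @param config file path or list
#' @return a `RunManifest` (list), invisibly; all outputs are files under
#'   `out_dir`
#' @export
run_study_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  manifest <- list(package_version = as.character(packageVersion("cladatom")),
                   seed = seed, config = config, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    val
  }

  input_info <- list()
  m <- t_stage("input", {
    if (isTRUE(config$synthetic)) {
      sc <- do.call(simulation_config, config$simulation %||% list())
      tr <- simulate_tree(sc$n_taxa, sc$n_outgroup)
      sim <- simulate_matrix(tr, sc)
      write_matrix(sim$matrix, file.path(out_dir, "input_matrix.nex"),
                   "nexus")
      ape::write.tree(sim$tree, file.path(out_dir, "true_tree.nwk"))
      if (length(sim$rules)) {
        write_atomization_rules(sim$rules,
                                file.path(out_dir, "atomization_rules.tsv"))
        input_info$rules_path <- file.path(out_dir, "atomization_rules.tsv")
      }
      input_info$synthetic <- TRUE
      sim$matrix
    } else {
      inp <- config$input %||% stop("config needs input or synthetic: true")
      input_info$checksum <- unname(tools::md5sum(inp$path))
      mm <- read_matrix(inp$path, inp$dialect %||% "nexus")
      if (!is.null(inp$outgroup)) mm$outgroup <- inp$outgroup
      mm
    }
  })
  manifest$stages$input <- c(manifest$stages$input, input_info)
  if (is.null(config$atomization_rules) &&
      !is.null(input_info$rules_path))
    config$atomization_rules <- input_info$rules_path

  if (!is.null(config$atomization_rules)) {
    m <- t_stage("atomize", {
      rules <- read_atomization_rules(config$atomization_rules)
      res <- atomize(m, rules)
      rep <- res$report
      writeLines(jsonlite::toJSON(unclass(rep)[1:4], auto_unbox = TRUE,
                                  pretty = TRUE),
                 file.path(out_dir, "recoding_report.json"))
      write_matrix(res$matrix, file.path(out_dir, "atomized_matrix.nex"),
                   "nexus")
      res$matrix
    })
  }

  scfg <- do.call(search_config, config$search %||% list())
  res <- t_stage("search", {
    r <- heuristic_search(m, scfg)
    ape::write.tree(do.call(c, lapply(r$mpts, identity)),
                    file.path(out_dir, "mpts.nwk"))
    r
  })
  cons <- t_stage("consensus", {
    cn <- strict_consensus(res$mpts)
    ape::write.tree(cn, file.path(out_dir, "strict_consensus.nwk"))
    cn
  })
  manifest$result <- list(n_mpts = length(res$mpts),
                          best_length = res$best_score$length,
                          ci = res$best_score$ci, ri = res$best_score$ri)

  if (!identical(config$bootstrap, FALSE)) {
    bt <- t_stage("bootstrap", {
      reps <- config$bootstrap$reps %||% 100
      b <- bootstrap(m, reps = reps, config = scfg)
      ape::write.tree(b$consensus,
                      file.path(out_dir, "bootstrap_consensus.nwk"))
      ape::write.tree(map_supports(res$mpts[[1]], b),
                      file.path(out_dir, "mpt_with_supports.nwk"))
      write.table(b$frequencies,
                  file.path(out_dir, "bootstrap_frequencies.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      b
    })
  }

  if (isTRUE(config$diagnostics) && length(m$outgroup)) {
    t_stage("diagnostics", {
      tr <- root_on_outgroup(res$mpts[[1]], m$outgroup)
      anc <- ancestral_states(tr, m, "acctran")
      write.table(anc$changes, file.path(out_dir, "apomorphy_list.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      anc
    })
  }

  if (!is.null(config$compare)) {
    t_stage("compare", {
      m2 <- read_matrix(config$compare$path,
                        config$compare$dialect %||% "nexus")
      cmp <- compare_matrices(m, m2, search = scfg)
      sink(file.path(out_dir, "comparison_report.txt"))
      print(cmp)
      sink()
      cmp
    })
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              force = TRUE),
             manifest_path)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
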