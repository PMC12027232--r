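#' Read a pipeline run configuration
#'
#' YAML configuration with any of the keys: `expression` (TPM table path),
#' `cq` (Cq table path), `annotation` (sample annotation path shared by both
#' inputs; `expression_annotation` / `cq_annotation` override it when the
#' RNA-seq and qPCR panels cover different samples), `screen` (block mirroring
#' [screen_criteria()] field names), `methods` (stability method list),
#' `pair_rank`, `normalize` (block with `target`, `references`, `calibrator`),
#' `output_dir`, `seed`, `log_level`.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$expression) && is.null(config$cq)) {
    stop("config must name an expression table, a cq table, or both")
  }
  for (key in c("expression", "cq", "annotation", "expression_annotation",
                "cq_annotation")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config path for '", key, "' does not exist: ", p)
    }
  }
  if (!is.null(config$methods)) {
    bad <- setdiff(config$methods,
                   c("delta_ct", "genorm", "bestkeeper", "normfinder"))
    if (length(bad) > 0L) stop("unknown stability method(s): ",
                               paste(bad, collapse = ", "))
  }
  if (!is.null(config$normalize)) {
    if (is.null(config$cq)) stop("normalization requested but no cq path given")
    need <- c("target", "references", "calibrator")
    miss <- need[!need %in% names(config$normalize)]
    if (length(miss) > 0L) stop("normalize block missing: ",
                                paste(miss, collapse = ", "))
  }
  invisible(config)
}

config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  keep <- config[setdiff(names(config), "config_path")]
  yaml::write_yaml(keep[order(names(keep))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full reference-gene analysis pipeline
#'
#' Reproduces the full analysis path on any input pair: candidate screening
#' on the TPM matrix (when `expression` is configured), the four stability
#' statistics plus comprehensive ranking on the Cq matrix (when `cq` is
#' configured), and optional 2^-ddCt normalization of a target gene. Stages
#' communicate only through files in the output directory, each stage's
#' output is re-runnable in isolation, and a JSON manifest records the config
#' fingerprint, the files written and any warnings. Given identical inputs
#' the reports are byte-identical (only the manifest timestamp differs).
#'
#' @param config A [read_run_config()] list, or a path to a YAML config.
#' @param output_dir Output directory (default `config$output_dir`, else
#'   `"refstab_run"`); created if needed.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results (`screen`, `stability`, `normalization`).
#' @export
run_full_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out_dir <- output_dir %||% config$output_dir %||% "refstab_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(config_hash = config_fingerprint(config),
                   package_version = as.character(utils::packageVersion("refstab")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), warnings = list())
  results <- list()
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!identical(config$log_level, "quiet")) message(line)
  }
  collect_warnings <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      manifest$warnings[[length(manifest$warnings) + 1L]] <<-
        list(stage = stage, message = conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  run_stage <- function(stage, expr) {
    say("stage: ", stage)
    tryCatch(collect_warnings(stage, expr), error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run.log"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  annotation_for <- function(key) {
    path <- config[[key]] %||% config$annotation
    if (is.null(path)) NULL else read_sample_annotation(path)
  }

  if (!is.null(config$expression)) {
    run_stage("screen", {
      expr <- read_expression_table(config$expression,
                                    annotation = annotation_for("expression_annotation"))
      crit <- do.call(screen_criteria, config$screen %||% list())
      results$screen <- apply_criteria(expr, crit)
      path <- file.path(out_dir, "screen_report.tsv")
      write_screen_report(results$screen, path)
      manifest$stages$screen <- list(
        input = config$expression, output = "screen_report.tsv",
        total_genes = results$screen$total_genes,
        stage_counts = as.list(results$screen$stage_counts),
        shortlist = results$screen$shortlist)
      say("  survivors: ", length(results$screen$survivors),
          "; shortlist: ", length(results$screen$shortlist))
    })
  }

  if (!is.null(config$cq)) {
    run_stage("stability", {
      cqm <- read_cq_table(config$cq,
                           annotation = annotation_for("cq_annotation"))
      methods <- config$methods %||% c("delta_ct", "genorm", "bestkeeper",
                                       "normfinder")
      tab <- evaluate_stability(cqm, methods = methods,
                                pair_rank = config$pair_rank %||% "tied")
      results$stability <- tab
      path <- file.path(out_dir, "ranking.tsv")
      write_ranking_report(tab, path)
      mres <- attr(tab, "method_results")
      if (!is.null(mres$genorm)) {
        v <- mres$genorm$pairwise_variation
        utils::write.table(
          data.frame(pair = names(v), v = sprintf("%.15g", v)),
          file.path(out_dir, "pairwise_variation.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$stages$stability$n_sufficient <-
          pairwise_variation_cutoff(mres$genorm)
      }
      manifest$stages$stability <- c(
        manifest$stages$stability %||% list(),
        list(input = config$cq, output = "ranking.tsv", methods = methods,
             best_genes = tab$gene_id[tab$final_rank <= 2]))
      say("  best genes: ",
          paste(tab$gene_id[tab$final_rank <= 2], collapse = ", "))
      results$cq <- cqm
    })
  }

  if (!is.null(config$normalize)) {
    run_stage("normalize", {
      nb <- config$normalize
      res <- ddct(results$cq, target = nb$target,
                  references = unlist(nb$references),
                  calibrator = nb$calibrator)
      results$normalization <- res
      path <- file.path(out_dir, "fold_changes.tsv")
      out <- res
      num <- vapply(out, is.numeric, logical(1))
      out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$stages$normalize <- list(target = nb$target,
                                         references = unlist(nb$references),
                                         calibrator = nb$calibrator,
                                         output = "fold_changes.tsv")
    })
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(list(manifest = manifest), results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
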