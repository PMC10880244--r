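# End-to-end pipeline: simulate/load -> score -> bootstrap-evaluate ->
# rank -> report. Configuration is a plain named list (typically read
# from YAML); every numeric output is reproducible from the recorded
# seed.

#' Pipeline configuration
#'
#' @param models character vector of model names (see [score_model()]).
#' @param endpoint `"PFS"`, `"OS"` or `"BOR"`.
#' @param output_dir directory for all artifacts (created if needed).
#' @param B bootstrap resamples.
#' @param seed master seed; recorded in every output artifact.
#' @param tie_tol ranking tie tolerance (`NULL` = one bootstrap SE).
#' @param scenario name of an [effect_scenarios()] preset used to
#'   simulate the dataset when no files are given.
#' @param n_patients,n_genes simulated problem size (with `scenario`).
#' @param clinical_path,expression_path optional paths to an existing
#'   dataset (overrides `scenario`).
#' @param gene_sets_path optional GMT with the signature gene sets; for
#'   simulated data the generator's true blocks are used by default.
#' @param gene_set_map named character vector mapping model signature
#'   roles (proliferation, icr, panel, inflammatory, lkb1_loss, nrf2,
#'   neuroendocrine) to gene-set names in the GMT.
#' @param log_level `"info"` or `"quiet"`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(models, endpoint = "PFS", output_dir,
                            B = 1000, seed = 42, tie_tol = NULL,
                            scenario = "predictive_only",
                            n_patients = 500, n_genes = 200,
                            clinical_path = NULL, expression_path = NULL,
                            gene_sets_path = NULL,
                            gene_set_map = NULL,
                            log_level = "info") {
  if (length(models) == 0) {
    icibench_error("icibench_config_error", "model list is empty")
  }
  bad <- setdiff(models, MODEL_NAMES)
  if (length(bad) > 0) {
    icibench_error("icibench_config_error",
                   paste0("unknown model(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(
    models = models, endpoint = match.arg(endpoint, c("PFS", "OS", "BOR")),
    output_dir = output_dir, B = B, seed = as.integer(seed),
    tie_tol = tie_tol, scenario = scenario, n_patients = n_patients,
    n_genes = n_genes, clinical_path = clinical_path,
    expression_path = expression_path, gene_sets_path = gene_sets_path,
    gene_set_map = gene_set_map, log_level = log_level
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [icibench] ", ...)
}

default_gene_set_map <- c(
  proliferation = "proliferation", icr = "immune", panel = "panel",
  inflammatory = "immune", lkb1_loss = "proliferation",
  nrf2 = "panel", neuroendocrine = "proliferation")

#' Run the full benchmarking pipeline
#'
#' Stages: obtain the dataset (simulate a preset scenario or read the
#' configured TSVs), score every configured model, validate and write the
#' prediction TSVs, bootstrap-evaluate each model, rank against the TMB
#' baseline, and write a report bundle: `predictions/<model>.tsv`,
#' `evaluation/<model>.json`, `ranking.json` and a human-readable
#' `report.txt` with the per-model DSS table. Re-running with the same
#' configuration reproduces every numeric output exactly. Any stage
#' failure aborts with the stage name.
#'
#' @param config a [pipeline_config()] (or a named list of its
#'   arguments).
#' @return invisibly, a list with the dataset, scores, evaluation
#'   results and the [rank_models()] ranking.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$output_dir, "predictions"), showWarnings = FALSE)
  dir.create(file.path(cfg$output_dir, "evaluation"), showWarnings = FALSE)

  # -- data ----------------------------------------------------------
  dataset <- stage("data", {
    if (!is.null(cfg$clinical_path)) {
      pipe_log(cfg, "reading dataset from ", cfg$clinical_path)
      read_trial(cfg$clinical_path, cfg$expression_path)
    } else {
      pipe_log(cfg, "simulating scenario '", cfg$scenario, "' (n = ",
               cfg$n_patients, ")")
      sc <- effect_scenarios(cfg$n_patients, cfg$n_genes, seed = cfg$seed)
      if (!cfg$scenario %in% names(sc)) {
        icibench_error("icibench_config_error",
                       paste0("unknown scenario '", cfg$scenario, "'"))
      }
      simulate_trial(sc[[cfg$scenario]])
    }
  })

  gene_sets <- stage("gene_sets", {
    pool <- if (!is.null(cfg$gene_sets_path)) {
      read_gene_sets(cfg$gene_sets_path)
    } else {
      truth <- attr(dataset, "truth")
      if (is.null(truth)) list() else truth$gene_sets
    }
    map <- cfg$gene_set_map
    if (is.null(map)) map <- default_gene_set_map
    out <- list()
    for (role in names(map)) {
      if (map[[role]] %in% names(pool)) out[[role]] <- pool[[map[[role]]]]
    }
    out
  })

  # -- scoring -------------------------------------------------------
  scores <- stage("scoring", {
    lapply(stats::setNames(cfg$models, cfg$models), function(m) {
      pipe_log(cfg, "scoring model ", m)
      sc <- score_model(dataset, m, subchallenge = cfg$endpoint,
                        gene_sets = gene_sets)
      rep_val <- validate_predictions(dataset, sc)
      if (nrow(rep_val) > 0) {
        icibench_error("icibench_value_error", paste0(
          "model ", m, " produced invalid predictions"))
      }
      write_predictions(
        sc, file.path(cfg$output_dir, "predictions", paste0(m, ".tsv")))
      sc
    })
  })

  # -- evaluation ----------------------------------------------------
  results <- stage("evaluation", {
    lapply(scores, function(sc) {
      pipe_log(cfg, "bootstrap-evaluating ", sc$model_name,
               " (B = ", cfg$B, ")")
      res <- bootstrap_evaluate(dataset, sc, cfg$endpoint, B = cfg$B,
                                seed = cfg$seed)
      out <- list(model_name = res$model_name, endpoint = res$endpoint,
                  point = as.list(res$point), B = res$B, seed = res$seed,
                  dss_quartiles = as.list(stats::quantile(
                    res$draws[, "dss"], c(0.25, 0.5, 0.75))))
      jsonlite::write_json(
        out, file.path(cfg$output_dir, "evaluation",
                       paste0(res$model_name, ".json")),
        auto_unbox = TRUE, digits = NA)
      res
    })
  })

  # -- ranking -------------------------------------------------------
  ranking <- stage("ranking", {
    reference <- results[["baseline_tmb"]]
    if (is.null(reference)) {
      ref_score <- baseline_score(dataset, "TMB", cfg$endpoint)
      reference <- bootstrap_evaluate(dataset, ref_score, cfg$endpoint,
                                      B = cfg$B, seed = cfg$seed)
    }
    rk <- rank_models(unname(results), reference, tie_tol = cfg$tie_tol)
    jsonlite::write_json(
      list(reference = rk$reference, eligible = rk$eligible,
           tie_set = rk$tie_set, top_performers = rk$top_performers,
           tie_tol = rk$tie_tol, seed = cfg$seed, table = rk$table),
      file.path(cfg$output_dir, "ranking.json"),
      auto_unbox = TRUE, digits = NA)
    rk
  })

  # -- report --------------------------------------------------------
  stage("report", {
    lines <- c(
      "icibench pipeline report",
      paste0("package version: ",
             as.character(utils::packageVersion("icibench"))),
      paste0("endpoint: ", cfg$endpoint, "  B: ", cfg$B,
             "  seed: ", cfg$seed),
      paste0("dataset: ", n_patients(dataset), " patients, ",
             nrow(dataset$expression), " genes",
             if (is.null(cfg$clinical_path))
               paste0(" (simulated scenario '", cfg$scenario, "')")
             else ""),
      "",
      "model ranking by DSS (difference in squared scaled basal metrics):",
      utils::capture.output(print(ranking$table, digits = 4, row.names = FALSE)),
      "",
      paste0("top performers: ",
             if (length(ranking$top_performers))
               paste(ranking$top_performers, collapse = ", ")
             else "(none)"))
    writeLines(lines, file.path(cfg$output_dir, "report.txt"))
  })
  pipe_log(cfg, "pipeline complete: ", cfg$output_dir)

  invisible(list(dataset = dataset, scores = scores, results = results,
                 ranking = ranking))
}
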