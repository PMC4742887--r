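#' Read a pipeline configuration file
#'
#' YAML or JSON (by extension). The configuration is a plain named
#' list; see [run_pipeline()] for the recognised fields.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_format("config must be .yaml/.yml or .json, got '%s'", ext)
  }
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_format("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full screen-analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC -> hit calling -> cross-arm
#' comparison -> network classification -> enrichment, writing every
#' artifact plus a manifest of MD5 file hashes into `out_dir`.
#' Re-running with the same configuration and seed reproduces
#' byte-identical artifacts; disabling a downstream stage never alters
#' upstream outputs.
#'
#' Recognised config fields (all optional unless noted):
#' * `seed` — integer; seeds the simulation stage.
#' * `input_csv` / `library_csv` — analyse an existing screen CSV
#'   (with its library table) instead of simulating.
#' * `simulation` — named list of [simulation_config()] arguments
#'   (ignored when `input_csv` is given); `simulation$planted_hits`
#'   may be an inline table or a CSV path.
#' * `library_size` — synthetic library size when simulating
#'   (default 571).
#' * `layout_spec` — per-plate role counts (default
#'   [default_screen_layout()]); used for simulation and the layout
#'   deviation report.
#' * `hit_calling` — named list of [hit_call_config()] arguments.
#' * `network` — list with `edge_files` (character vector of TSV edge
#'   lists) and optional `mrfs`, `symbol_map`.
#' * `enrichment` — list with `gmt` (path) and optional `alpha`,
#'   `method`.
#' * `stages` — character subset of
#'   `c("screen", "qc", "hits", "compare", "network", "enrich")`;
#'   default all (network/enrich only when inputs are configured).
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return the run manifest, invisibly: list with `artifacts` (named
#'   MD5 hashes), `stages_run`, and key result objects (`dataset`,
#'   `calls`, `comparison`, ...).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop_format("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("screen", "qc", "hits", "compare", "network", "enrich")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop_format("unknown pipeline stage: %s", bad[1])
  artifacts <- character()
  emit <- function(name) artifacts <<- c(artifacts, name)
  path_of <- function(name) file.path(out_dir, name)
  result <- list(stages_run = character())

  # config snapshot first, so a failed run still records its inputs
  jsonlite::write_json(config, path_of("config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  emit("config.json")

  # --- screen stage: simulate or load -------------------------------
  screen_in <- pipeline_stage("screen", {
    if (!is.null(config$input_csv)) {
      if (is.null(config$library_csv)) {
        stop("'library_csv' is required alongside 'input_csv'")
      }
      lib <- read_library_csv(config$library_csv)
      list(dataset = read_screen_csv(config$input_csv, lib), truth = NULL)
    } else {
      sim_args <- config$simulation %||% list()
      if (is.character(sim_args$planted_hits)) {
        sim_args$planted_hits <- readr::read_csv(
          sim_args$planted_hits,
          col_types = readr::cols(gene = readr::col_character(),
                                  .default = readr::col_double()),
          progress = FALSE)
      }
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      lib <- synthetic_kinase_library(config$library_size %||% 571)
      sim <- simulate_screen(do.call(simulation_config, sim_args), lib,
                             config$layout_spec %||% default_screen_layout())
      list(dataset = sim$dataset, truth = sim$truth)
    }
  })
  dataset <- screen_in$dataset
  truth <- screen_in$truth
  result$dataset <- dataset
  if ("screen" %in% stages) {
    write_screen_csv(dataset, path_of("screen.csv"))
    emit("screen.csv")
    if (!is.null(truth)) {
      readr::write_csv(truth, path_of("ground_truth.csv"), progress = FALSE)
      emit("ground_truth.csv")
    }
    layout_report <- validate_layout(dataset, config$layout_spec %||%
                                       default_screen_layout())
    readr::write_csv(layout_report, path_of("layout_deviations.csv"),
                     progress = FALSE)
    emit("layout_deviations.csv")
    result$stages_run <- c(result$stages_run, "screen")
  }

  hc <- do.call(hit_call_config, config$hit_calling %||% list())

  if ("qc" %in% stages) {
    qc <- pipeline_stage("qc", qc_report(dataset, hc))
    readr::write_csv(qc$z_factors, path_of("qc_z_factors.csv"), progress = FALSE)
    readr::write_csv(qc$control_scoring, path_of("qc_control_scoring.csv"),
                     progress = FALSE)
    emit("qc_z_factors.csv"); emit("qc_control_scoring.csv")
    result$qc <- qc
    result$stages_run <- c(result$stages_run, "qc")
  }

  calls <- NULL
  if (any(c("hits", "compare", "network", "enrich") %in% stages)) {
    calls <- pipeline_stage("hits", call_screen(dataset, hc))
    result$calls <- calls
  }
  if ("hits" %in% stages) {
    scores <- pipeline_stage("hits", score_wells(dataset, hc))
    readr::write_csv(scores, path_of("well_scores.csv"), progress = FALSE)
    readr::write_csv(calls, path_of("hit_calls.csv"), progress = FALSE)
    cno <- pipeline_stage("hits", cell_number_only_report(dataset, hc))
    readr::write_csv(cno$genes, path_of("cell_number_only_genes.csv"),
                     progress = FALSE)
    emit("well_scores.csv"); emit("hit_calls.csv")
    emit("cell_number_only_genes.csv")
    result$cell_number_only <- cno
    result$stages_run <- c(result$stages_run, "hits")
  }

  comparison <- NULL
  if (any(c("compare", "network", "enrich") %in% stages)) {
    comparison <- pipeline_stage("compare", {
      compare_arms(calls[calls$arm == "vehicle", ],
                   calls[calls$arm == "sensitizer", ],
                   length(dataset$library))
    })
    result$comparison <- comparison
  }
  if ("compare" %in% stages) {
    jsonlite::write_json(
      list(counts = as.list(comparison$counts),
           rates_percent = as.list(comparison$rates_percent),
           double_hits = comparison$double_hits,
           union_hits = comparison$union_hits),
      path_of("comparison.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    emit("comparison.json")
    result$stages_run <- c(result$stages_run, "compare")
  }

  if ("network" %in% stages && !is.null(config$network$edge_files)) {
    net <- pipeline_stage("network", {
      graphs <- lapply(config$network$edge_files, read_edge_list,
                       symbol_map = config$network$symbol_map %||%
                         default_symbol_map())
      graph <- do.call(merge_graphs, graphs)
      mrfs <- if (is.null(config$network$mrfs)) mrf_set()
              else mrf_set(config$network$mrfs)
      cls <- classify_regulators(graph, comparison$union_hits, mrfs)
      list(graph = graph, classification = cls,
           summary = summarize_network(cls))
    })
    pairs_flat <- net$classification$pairs
    pairs_flat$intermediaries <- vapply(pairs_flat$intermediaries,
                                        paste, character(1), collapse = ";")
    readr::write_csv(pairs_flat, path_of("network_pairs.csv"), progress = FALSE)
    readr::write_csv(net$classification$kinases, path_of("network_kinases.csv"),
                     progress = FALSE)
    export_subnetwork(net$classification, path_of("subnetwork.sif"),
                      path_of("subnetwork_nodes.tsv"))
    emit("network_pairs.csv"); emit("network_kinases.csv")
    emit("subnetwork.sif"); emit("subnetwork_nodes.tsv")
    result$network <- net
    result$stages_run <- c(result$stages_run, "network")
  }

  if ("enrich" %in% stages && !is.null(config$enrichment$gmt)) {
    enr <- pipeline_stage("enrich", {
      sets <- read_gmt(config$enrichment$gmt)
      binomial_enrichment(comparison$union_hits, dataset$library, sets,
                          alpha = config$enrichment$alpha %||% 0.05,
                          method = config$enrichment$method %||% "binomial")
    })
    readr::write_csv(enr, path_of("enrichment.csv"), progress = FALSE)
    emit("enrichment.csv")
    result$enrichment <- enr
    result$stages_run <- c(result$stages_run, "enrich")
  }

  hashes <- tools::md5sum(file.path(out_dir, artifacts))
  names(hashes) <- artifacts
  manifest <- list(artifacts = as.list(hashes), stages_run = result$stages_run)
  jsonlite::write_json(manifest, path_of("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  result$artifacts <- hashes
  invisible(result)
}
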