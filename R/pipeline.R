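#' Write a cross-validation metrics report
#'
#' Plain-text TSV report: overall accuracy, best hyperparameters,
#' confusion counts, and per-class precision/recall.
#'
#' @param res a [grid_search_cv()] result.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- res$metrics
  writeLines(c(
    sprintf("mean_cv_accuracy\t%.6f", res$mean_accuracy),
    sprintf("pooled_accuracy\t%.6f", m$accuracy),
    sprintf("best_n_estimators\t%d", res$best$n_estimators[1L]),
    sprintf("best_max_depth\t%d", res$best$max_depth[1L]),
    sprintf("best_learning_rate\t%g", res$best$learning_rate[1L]),
    sprintf("confusion_TP\t%d", m$confusion[["TP"]]),
    sprintf("confusion_FP\t%d", m$confusion[["FP"]]),
    sprintf("confusion_FN\t%d", m$confusion[["FN"]]),
    sprintf("confusion_TN\t%d", m$confusion[["TN"]]),
    sprintf("precision_class1\t%.6f", m$per_class$precision[1L]),
    sprintf("recall_class1\t%.6f", m$per_class$recall[1L]),
    sprintf("precision_class0\t%.6f", m$per_class$precision[2L]),
    sprintf("recall_class0\t%.6f", m$per_class$recall[2L])
  ), con)
  invisible(path)
}

graph_file_key <- function(fname) {
  sub("\\.csv$", "", basename(fname))
}

#' Run the classification pipeline
#'
#' Executes the requested stages in order, writing every intermediate
#' artifact in its documented plain-text format plus a JSON manifest
#' echoing the configuration and seeds, so a run is reproducible from
#' its output directory alone. Stages:
#' \describe{
#'   \item{synthetic}{generate choices and per-(player, game) graphs
#'     (graph level) or raw signal epochs (signal level).}
#'   \item{graphs}{signal level only: preprocess epochs, estimate
#'     coherence, threshold into graphs.}
#'   \item{embed}{anonymous-walk embeddings of all graphs (reads
#'     `graphs/` if the synthetic stage was not run in-process).}
#'   \item{features}{difference vectors + labels -> `dataset.tsv`.}
#'   \item{classify}{grid-searched stratified CV -> `metrics.tsv`.}
#' }
#'
#' @param out_dir output directory (created if needed).
#' @param scenario a [scenario_config()] for synthetic stages.
#' @param l walk length (default 5).
#' @param epsilon,delta Monte-Carlo bound parameters (defaults 0.1,
#'   0.01).
#' @param classifier a [classifier_config()].
#' @param level `"graph"` (fast; graphs generated directly) or
#'   `"signal"` (full path through preprocessing and coherence).
#' @param preprocess,graph_cfg configs for the signal-level path.
#' @param stages character vector of stages, or `"all"`.
#' @param embedding `"sample"` or `"exact"`.
#' @param seed master seed for embedding sampling and CV folds.
#' @return Invisibly, a list with the in-memory artifacts of the stages
#'   that ran (`choices`, `graphs`, `embeddings`, `dataset`, `cv`).
#' @export
run_pipeline <- function(out_dir, scenario = scenario_config(), l = 5L,
                         epsilon = 0.1, delta = 0.01,
                         classifier = classifier_config(),
                         level = c("graph", "signal"),
                         preprocess = preprocess_config(),
                         graph_cfg = graph_config(),
                         stages = "all", embedding = "sample", seed = 1L) {
  level <- match.arg(level)
  all_stages <- c("synthetic", "graphs", "embed", "features", "classify")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages)) {
    cw_stop("coherwalk_config_error", "unknown stage(s): %s",
            paste(setdiff(stages, all_stages), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  if ("synthetic" %in% stages) {
    res$choices <- generate_choices(scenario)
    write_choices(res$choices, file.path(out_dir, "choices.tsv"))
    if (level == "graph") {
      res$graphs <- generate_scenario_graphs(scenario, res$choices)
    } else {
      dir.create(file.path(out_dir, "signals"), showWarnings = FALSE)
      true_graphs <- generate_scenario_graphs(scenario, res$choices)
      res$signals <- list()
      for (k in names(true_graphs)) {
        ep <- generate_epoch_signals(true_graphs[[k]], scenario,
                                     seed = derive_seed(scenario$seed, 6L,
                                                        match(k, names(true_graphs))))
        res$signals[[k]] <- ep
        write_epoch_matrix(ep, file.path(out_dir, "signals",
                                         paste0(gsub("::", "__", k), ".tsv")))
      }
    }
  }

  if ("graphs" %in% stages && level == "signal") {
    if (is.null(res$signals)) {
      cw_stop("coherwalk_missing_artifact_error",
              "graphs stage needs signal epochs; run the synthetic stage %s",
              "at signal level first")
    }
    res$graphs <- lapply(res$signals, function(ep) {
      build_graph(coherence_matrix(preprocess_epoch(ep, preprocess), graph_cfg),
                  graph_cfg)
    })
  }

  if (any(c("graphs", "synthetic") %in% stages) && !is.null(res$graphs)) {
    gdir <- file.path(out_dir, "graphs")
    dir.create(gdir, showWarnings = FALSE)
    for (k in names(res$graphs)) {
      write_graph(res$graphs[[k]],
                  file.path(gdir, paste0(gsub("::", "__", k), ".csv")))
    }
  }

  if ("embed" %in% stages) {
    if (is.null(res$graphs)) {
      gdir <- file.path(out_dir, "graphs")
      files <- list.files(gdir, pattern = "\\.csv$", full.names = TRUE)
      if (length(files) == 0L) {
        cw_stop("coherwalk_missing_artifact_error",
                "no graphs in memory and none found under %s", gdir)
      }
      res$graphs <- stats::setNames(
        lapply(files, read_graph),
        gsub("__", "::", vapply(files, graph_file_key, character(1)))
      )
    }
    plan <- sampling_plan(l, epsilon, delta)
    res$embeddings <- embed_graphs(res$graphs, l, embedding, plan,
                                   base_seed = seed)
    write_embeddings(res$embeddings, file.path(out_dir, "embeddings.tsv"))
  }

  if ("features" %in% stages) {
    if (is.null(res$choices)) {
      cpath <- file.path(out_dir, "choices.tsv")
      if (!file.exists(cpath)) {
        cw_stop("coherwalk_missing_artifact_error", "missing %s", cpath)
      }
      res$choices <- read_choices(cpath)
    }
    if (is.null(res$embeddings)) {
      epath <- file.path(out_dir, "embeddings.tsv")
      if (!file.exists(epath)) {
        cw_stop("coherwalk_missing_artifact_error", "missing %s", epath)
      }
      res$embeddings <- read_embeddings(epath)
    }
    res$dataset <- assemble_dataset(res$embeddings, res$choices)
    write_dataset(res$dataset, file.path(out_dir, "dataset.tsv"))
  }

  if ("classify" %in% stages) {
    if (is.null(res$dataset)) {
      dpath <- file.path(out_dir, "dataset.tsv")
      if (!file.exists(dpath)) {
        cw_stop("coherwalk_missing_artifact_error", "missing %s", dpath)
      }
      res$dataset <- read_dataset(dpath)
    }
    cc <- classifier
    cc$seed <- seed
    res$cv <- grid_search_cv(res$dataset, cc)
    write_metrics(res$cv, file.path(out_dir, "metrics.tsv"))
  }

  manifest <- list(
    package = "coherwalk",
    stages = stages, level = level, walk_length = l,
    epsilon = epsilon, delta = delta, embedding = embedding, seed = seed,
    scenario = scenario[setdiff(names(scenario), "salience")],
    salience = as.vector(t(scenario$salience)),
    classifier = unclass(classifier)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
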