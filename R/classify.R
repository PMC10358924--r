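#' Classifier and cross-validation configuration
#'
#' Gradient-boosted trees with a hyperparameter grid searched over
#' number of estimators, maximal tree depth and learning rate, evaluated
#' by stratified k-fold cross-validation (default 3 folds).
#'
#' @param n_estimators_grid integer vector of boosting-round counts.
#' @param max_depth_grid integer vector of maximal tree depths.
#' @param learning_rate_grid numeric vector of learning rates (eta).
#' @param n_folds number of CV folds (>= 2; default 3).
#' @param seed integer seed controlling fold assignment.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_estimators_grid = c(50L, 100L, 200L),
                              max_depth_grid = c(3L, 5L, 7L),
                              learning_rate_grid = c(0.01, 0.1, 0.3),
                              n_folds = 3L, seed = 1L) {
  if (length(n_estimators_grid) == 0L || length(max_depth_grid) == 0L ||
      length(learning_rate_grid) == 0L) {
    cw_stop("coherwalk_config_error", "hyperparameter grids must be non-empty")
  }
  if (n_folds < 2L) cw_stop("coherwalk_config_error", "n_folds must be >= 2")
  structure(list(n_estimators_grid = as.integer(n_estimators_grid),
                 max_depth_grid = as.integer(max_depth_grid),
                 learning_rate_grid = as.numeric(learning_rate_grid),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Stratified fold assignment
#'
#' Splits observations into k folds so that per-fold class counts differ
#' by at most one from an equal division; e.g. 153 positives and 387
#' negatives over 3 folds give exactly 51 positives and 129 negatives
#' per fold. Reproducible for a given seed.
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..k), one per observation.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  folds <- integer(length(labels))
  set.seed(seed)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      cw_stop("coherwalk_stratification_error",
              "class %d has %d members, fewer than k = %d folds",
              cls, length(idx), k)
    }
    idx <- sample(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Classification metrics from labels and predictions
#'
#' Confusion counts plus per-class precision (PPV = TP/(TP+FP)) and
#' recall (TPR = TP/(TP+FN)); both classes are reported because the
#' pair dataset is imbalanced (most pairs fail to coordinate).
#'
#' @param labels true 0/1 labels.
#' @param preds predicted 0/1 labels.
#' @return An object of class `class_metrics` with `accuracy`,
#'   `confusion` (TP, FP, FN, TN, with class 1 as positive) and a
#'   `per_class` data frame of precision/recall.
#' @export
class_metrics <- function(labels, preds) {
  labels <- as.integer(labels); preds <- as.integer(preds)
  tp <- sum(labels == 1L & preds == 1L)
  fp <- sum(labels == 0L & preds == 1L)
  fn <- sum(labels == 1L & preds == 0L)
  tn <- sum(labels == 0L & preds == 0L)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  per_class <- data.frame(
    class = c(1L, 0L),
    precision = c(safe_div(tp, tp + fp), safe_div(tn, tn + fn)),
    recall = c(safe_div(tp, tp + fn), safe_div(tn, tn + fp))
  )
  structure(list(accuracy = (tp + tn) / length(labels),
                 confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 per_class = per_class),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics> accuracy %.4f | TP %d FP %d FN %d TN %d\n",
              x$accuracy, x$confusion["TP"], x$confusion["FP"],
              x$confusion["FN"], x$confusion["TN"]))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

fit_xgb <- function(x, y, n_estimators, max_depth, learning_rate) {
  dtrain <- xgboost::xgb.DMatrix(data = x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = learning_rate, nthread = 1,
                  tree_method = "exact"),  # small data; midpoint splits
    data = dtrain, nrounds = n_estimators, verbose = 0
  )
}

predict_xgb <- function(model, x) {
  as.integer(predict(model, xgboost::xgb.DMatrix(data = x, nthread = 1)) >= 0.5)
}

cv_config_accuracy <- function(x, y, folds, cfg_row) {
  k <- max(folds)
  preds <- integer(length(y))
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- fit_xgb(x[tr, , drop = FALSE], y[tr],
                     cfg_row$n_estimators, cfg_row$max_depth,
                     cfg_row$learning_rate)
    p <- predict_xgb(model, x[!tr, , drop = FALSE])
    preds[!tr] <- p
    accs[f] <- mean(p == y[!tr])
  }
  list(mean_accuracy = mean(accs), oof_preds = preds)
}

#' Grid-searched cross-validated training and evaluation
#'
#' For every point of the hyperparameter grid, trains on k-1 stratified
#' folds and tests on the held-out fold; the configuration with the
#' highest mean fold accuracy is selected and its pooled out-of-fold
#' predictions are summarized into [class_metrics()].
#'
#' Two protocols are available. `"pooled"` (default) selects
#' hyperparameters on the same folds it reports, which mildly
#' optimistically biases the reported accuracy; `"nested"` re-runs the
#' grid search inside each training split and is the methodologically
#' safer estimate.
#'
#' @param ds a [assemble_dataset()] result (`pair_dataset`).
#' @param cfg a [classifier_config()].
#' @param mode `"pooled"` or `"nested"` (see Details).
#' @return A list: `best` (data frame row of selected hyperparameters;
#'   for nested mode, the per-fold selections), `mean_accuracy`,
#'   `metrics` ([class_metrics()]), `folds`, `grid` (per-configuration
#'   mean accuracies, pooled mode only).
#' @export
grid_search_cv <- function(ds, cfg = classifier_config(),
                           mode = c("pooled", "nested")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "pair_dataset"))
  y <- ds$meta$label
  if (length(unique(y)) < 2L) {
    cw_stop("coherwalk_training_error",
            "dataset has a single class; cannot train a classifier")
  }
  x <- ds$features
  folds <- stratified_folds(y, cfg$n_folds, cfg$seed)
  grid <- expand.grid(n_estimators = cfg$n_estimators_grid,
                      max_depth = cfg$max_depth_grid,
                      learning_rate = cfg$learning_rate_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (mode == "pooled") {
    results <- lapply(seq_len(nrow(grid)), function(i) {
      cv_config_accuracy(x, y, folds, grid[i, ])
    })
    grid$mean_accuracy <- vapply(results, `[[`, numeric(1), "mean_accuracy")
    best_i <- which.max(grid$mean_accuracy)
    oof <- results[[best_i]]$oof_preds
    list(best = grid[best_i, c("n_estimators", "max_depth", "learning_rate")],
         mean_accuracy = grid$mean_accuracy[best_i],
         metrics = class_metrics(y, oof), folds = folds, grid = grid)
  } else {
    preds <- integer(length(y))
    chosen <- list()
    for (f in seq_len(cfg$n_folds)) {
      tr <- folds != f
      inner_folds <- stratified_folds(y[tr], max(2L, cfg$n_folds - 1L),
                                      cfg$seed + f)
      inner_acc <- vapply(seq_len(nrow(grid)), function(i) {
        cv_config_accuracy(x[tr, , drop = FALSE], y[tr], inner_folds,
                           grid[i, ])$mean_accuracy
      }, numeric(1))
      bi <- which.max(inner_acc)
      chosen[[f]] <- grid[bi, ]
      model <- fit_xgb(x[tr, , drop = FALSE], y[tr], grid$n_estimators[bi],
                       grid$max_depth[bi], grid$learning_rate[bi])
      preds[!tr] <- predict_xgb(model, x[!tr, , drop = FALSE])
    }
    acc_by_fold <- vapply(seq_len(cfg$n_folds), function(f) {
      mean(preds[folds == f] == y[folds == f])
    }, numeric(1))
    list(best = do.call(rbind, chosen), mean_accuracy = mean(acc_by_fold),
         metrics = class_metrics(y, preds), folds = folds, grid = NULL)
  }
}

#' Accuracy under permuted labels (chance reference)
#'
#' Repeats the cross-validated evaluation with class labels randomly
#' permuted, destroying any feature-label association; the resulting
#' accuracies estimate the null distribution an informative classifier
#' must beat (approximately the majority-class rate).
#'
#' @param ds a `pair_dataset`.
#' @param cfg a [classifier_config()] (a small grid keeps this cheap).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return Numeric vector of mean CV accuracies, one per permutation.
#' @export
permuted_label_accuracy <- function(ds, cfg = classifier_config(
                                      n_estimators_grid = 100L,
                                      max_depth_grid = 3L,
                                      learning_rate_grid = 0.1),
                                    n_perm = 20L, seed = 1L) {
  set.seed(seed)
  perm_seeds <- sample.int(1e6, n_perm)
  vapply(seq_len(n_perm), function(i) {
    ds_p <- ds
    set.seed(perm_seeds[i])
    ds_p$meta$label <- sample(ds$meta$label)
    ds_p$n_positive <- sum(ds_p$meta$label == 1L)
    ds_p$n_negative <- sum(ds_p$meta$label == 0L)
    cfg_i <- cfg; cfg_i$seed <- perm_seeds[i]
    grid_search_cv(ds_p, cfg_i)$mean_accuracy
  }, numeric(1))
}

#' Embed a collection of graphs
#'
#' Computes one anonymous-walk embedding per graph, keyed like the input
#' list (`"<player>::<game>"`). For sampled embeddings each graph gets
#' its own deterministic seed derived from `base_seed`.
#'
#' @param graphs named list of [electrode_graph()]s.
#' @param l walk length.
#' @param method `"sample"` (Monte-Carlo, the operational estimator) or
#'   `"exact"` (brute-force distribution).
#' @param plan [sampling_plan()] for the sampled method.
#' @param base_seed integer; graph i uses seed `base_seed + i`.
#' @return Named list of `walk_embedding`s.
#' @export
embed_graphs <- function(graphs, l, method = c("sample", "exact"),
                         plan = sampling_plan(l), base_seed = 1L) {
  method <- match.arg(method)
  out <- vector("list", length(graphs))
  names(out) <- names(graphs)
  for (i in seq_along(graphs)) {
    out[[i]] <- switch(method,
      sample = sample_embedding(graphs[[i]], l, plan, seed = base_seed + i),
      exact = exact_embedding(graphs[[i]], l))
  }
  out
}

#' Plateau rule for choosing the walk length
#'
#' Returns the smallest walk length whose successor improves mean CV
#' accuracy by less than `plateau` (accuracy fraction; default 0.01 = 1
#' percentage point); if every successive gain exceeds the threshold,
#' the largest length is returned. Longer walks inflate the vocabulary
#' steeply, so marginal gains do not justify them.
#'
#' @param l_range increasing vector of walk lengths.
#' @param accuracies mean CV accuracy (fraction) per length.
#' @param plateau improvement threshold, accuracy fraction.
#' @return The selected walk length.
#' @export
select_walk_length <- function(l_range, accuracies, plateau = 0.01) {
  if (length(l_range) == 0L) cw_stop("coherwalk_domain_error", "empty l_range")
  stopifnot(length(l_range) == length(accuracies))
  for (i in seq_len(length(l_range) - 1L)) {
    if (accuracies[i + 1L] - accuracies[i] < plateau) return(l_range[i])
  }
  l_range[length(l_range)]
}

#' Walk-length sweep
#'
#' For each walk length in `l_range`, embeds every graph, assembles the
#' pair dataset, runs the grid-searched cross-validation, and records
#' the accuracy curve; the reported `selected_l` follows the plateau
#' rule of [select_walk_length()].
#'
#' @param graphs named list of [electrode_graph()]s keyed
#'   `"<player>::<game>"`.
#' @param choices a [choice_table()].
#' @param l_range increasing vector of walk lengths to evaluate.
#' @param cfg a [classifier_config()].
#' @param method,base_seed passed to [embed_graphs()]; sampling plans are
#'   rebuilt per length with `epsilon`, `delta`.
#' @param epsilon,delta sample-size bound parameters.
#' @param plateau plateau threshold (accuracy fraction).
#' @return An object of class `sweep_result`: data frame `curve`
#'   (l, mean_accuracy, best hyperparameters), list `metrics` per l, and
#'   `selected_l`.
#' @export
walk_length_sweep <- function(graphs, choices, l_range,
                              cfg = classifier_config(),
                              method = "sample", base_seed = 1L,
                              epsilon = 0.1, delta = 0.01, plateau = 0.01) {
  if (length(l_range) == 0L) cw_stop("coherwalk_domain_error", "empty l_range")
  l_range <- sort(as.integer(l_range))
  metrics <- vector("list", length(l_range))
  rows <- vector("list", length(l_range))
  for (i in seq_along(l_range)) {
    l <- l_range[i]
    plan <- if (method == "sample") sampling_plan(l, epsilon, delta) else NULL
    emb <- if (method == "sample") {
      embed_graphs(graphs, l, "sample", plan, base_seed)
    } else {
      embed_graphs(graphs, l, "exact")
    }
    ds <- assemble_dataset(emb, choices)
    res <- grid_search_cv(ds, cfg)
    metrics[[i]] <- res$metrics
    rows[[i]] <- cbind(data.frame(l = l, mean_accuracy = res$mean_accuracy),
                       res$best)
  }
  curve <- do.call(rbind, rows)
  structure(list(curve = curve, metrics = metrics,
                 selected_l = select_walk_length(curve$l, curve$mean_accuracy,
                                                 plateau)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  print(x$curve, row.names = FALSE)
  cat(sprintf("selected walk length: %d\n", x$selected_l))
  invisible(x)
}
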