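# build a small synthetic pair_dataset directly from feature vectors
toy_dataset <- function(x, y) {
  structure(list(features = x,
                 meta = data.frame(player_a = "A", player_b = "B",
                                   game_id = seq_along(y), label = y),
                 n_positive = sum(y == 1), n_negative = sum(y == 0)),
            class = "pair_dataset")
}

test_that("stratified folds split classes evenly and reproducibly", {
  y <- c(rep(1L, 153), rep(0L, 387))
  f <- stratified_folds(y, 3, seed = 9)
  for (k in 1:3) {
    expect_equal(sum(y == 1 & f == k), 51L)
    expect_equal(sum(y == 0 & f == k), 129L)
  }
  expect_identical(f, stratified_folds(y, 3, seed = 9))
  expect_false(identical(f, stratified_folds(y, 3, seed = 10)))

  y6 <- c(1L, 1L, 1L, 0L, 0L, 0L)
  f6 <- stratified_folds(y6, 3, seed = 1)
  for (k in 1:3) {
    expect_equal(sum(y6 == 1 & f6 == k), 1L)
    expect_equal(sum(y6 == 0 & f6 == k), 1L)
  }
  expect_error(stratified_folds(c(1L, 0L, 0L, 0L), 2, seed = 1),
               class = "coherwalk_stratification_error")
})

test_that("confusion counts give the textbook precision and recall", {
  labels <- c(rep(1, 40), rep(1, 10), rep(0, 10), rep(0, 120))
  preds <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 120))
  m <- class_metrics(labels, preds)
  expect_equal(unname(m$confusion), c(40L, 10L, 10L, 120L))
  expect_equal(m$per_class$precision[m$per_class$class == 1], 0.8)
  expect_equal(m$per_class$recall[m$per_class$class == 1], 0.8)
  expect_equal(m$accuracy, 160 / 180)
  expect_equal(sum(m$confusion), length(labels))
})

test_that("a linearly separable dataset is classified perfectly", {
  set.seed(401)
  n <- 60
  y <- rep(c(1L, 0L), each = n / 2)
  x <- rbind(matrix(abs(rnorm(n / 2 * 5, 0, 0.01)), n / 2, 5),
             matrix(abs(rnorm(n / 2 * 5, 1, 0.01)), n / 2, 5))
  ds <- toy_dataset(x, y)
  res <- grid_search_cv(ds, classifier_config(
    n_estimators_grid = 50L, max_depth_grid = 3L, learning_rate_grid = 0.3,
    seed = 3))
  expect_equal(res$mean_accuracy, 1)
  expect_equal(res$metrics$per_class$precision, c(1, 1))
  # out-of-fold predictions cover every observation exactly once
  expect_equal(sum(res$metrics$confusion), n)
})

test_that("permuted labels collapse accuracy to the majority-class rate", {
  set.seed(402)
  n <- 120
  y <- rep(c(1L, 0L), c(40, 80))
  x <- matrix(runif(n * 6), n, 6)
  ds <- toy_dataset(x, y)
  # the grid includes a weak configuration, so the grid search can fall
  # back to near-constant (majority) predictions when labels carry no signal
  cfg <- classifier_config(n_estimators_grid = 50L, max_depth_grid = 3L,
                           learning_rate_grid = c(0.01, 0.3))
  null_acc <- permuted_label_accuracy(ds, cfg, n_perm = 20, seed = 7)
  expect_lt(abs(mean(null_acc) - 80 / 120), 0.05)
})

test_that("cross-validation results are reproducible and internally consistent", {
  set.seed(403)
  n <- 90
  y <- rep(c(1L, 0L), c(30, 60))
  x <- matrix(rnorm(n * 4), n, 4) + y
  ds <- toy_dataset(x, y)
  cfg <- classifier_config(n_estimators_grid = c(25L, 50L),
                           max_depth_grid = 3L,
                           learning_rate_grid = 0.3, seed = 11)
  r1 <- grid_search_cv(ds, cfg)
  r2 <- grid_search_cv(ds, cfg)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$metrics$confusion, r2$metrics$confusion)
  expect_equal(r1$mean_accuracy, r2$mean_accuracy)
  # accuracy recomputable from the confusion counts
  cm <- r1$metrics$confusion
  expect_equal(r1$metrics$accuracy, (cm[["TP"]] + cm[["TN"]]) / n)
  # nested mode runs and reports per-fold selections
  rn <- grid_search_cv(ds, cfg, mode = "nested")
  expect_equal(nrow(rn$best), 3L)
  expect_equal(sum(rn$metrics$confusion), n)
  expect_error(grid_search_cv(toy_dataset(x, rep(1L, n)), cfg),
               class = "coherwalk_training_error")
})

test_that("the plateau rule selects the documented walk length", {
  # flat curve: smallest length wins
  expect_equal(select_walk_length(1:5, rep(0.8, 5)), 1L)
  # strictly increasing with large gains: largest length wins
  expect_equal(select_walk_length(1:4, c(0.5, 0.6, 0.7, 0.8)), 4L)
  # plateau after a jump: first length whose successor gains < threshold
  expect_equal(select_walk_length(3:7, c(0.55, 0.60, 0.85, 0.855, 0.86)), 5L)
  expect_error(select_walk_length(integer(0), numeric(0)),
               class = "coherwalk_domain_error")
})

test_that("the walk-length sweep tracks discriminative structure", {
  # positives share a template, negatives use an independent one; a
  # miniature scenario keeps the grid small and the test fast
  cfg <- scenario_config(n_players = 6, n_games = 4, seed = 5)
  ch <- generate_choices(cfg)
  gs <- generate_scenario_graphs(cfg, ch)
  sw <- walk_length_sweep(gs, ch, l_range = c(2, 4),
                          cfg = classifier_config(
                            n_estimators_grid = 50L, max_depth_grid = 3L,
                            learning_rate_grid = 0.3, seed = 2),
                          method = "exact")
  expect_equal(sw$curve$l, c(2L, 4L))
  expect_true(all(sw$curve$mean_accuracy >= 0 &
                    sw$curve$mean_accuracy <= 1))
  expect_true(sw$selected_l %in% c(2L, 4L))
})
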