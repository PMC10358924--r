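toy_embedding <- function(p, l = 2L) {
  idx <- enumerate_walks(l)
  stopifnot(length(p) == idx$size)
  coherwalk:::new_walk_embedding(p, idx)
}

test_that("difference vectors follow |e1 - e2| and its symmetries", {
  e1 <- toy_embedding(c(0.7, 0.3), 2L)
  e2 <- toy_embedding(c(0.4, 0.6), 2L)
  expect_equal(unname(difference_vector(e1, e2)), c(0.3, 0.3))
  expect_equal(difference_vector(e1, e1), setNames(c(0, 0), names(e1$probabilities)))
  for (seed in 1:5) {
    set.seed(seed)
    a <- runif(5); b <- runif(5)
    expect_identical(difference_vector(a, b), difference_vector(b, a))
    expect_true(all(difference_vector(a, b) >= 0))
  }
  expect_error(difference_vector(runif(5), runif(3)),
               class = "coherwalk_dimension_error")
})

test_that("pair labels equal 1 exactly when both players chose the same word", {
  ch <- choice_table(data.frame(
    player_id = c("P1", "P2", "P3"), game_id = "G1",
    option = c("Water", "Water", "Beer")))
  expect_identical(label_pair(ch, "P1", "P2", "G1"), 1L)
  expect_identical(label_pair(ch, "P1", "P3", "G1"), 0L)
  expect_identical(label_pair(ch, "P2", "P1", "G1"),
                   label_pair(ch, "P1", "P2", "G1"))
  expect_error(label_pair(ch, "P1", "P1", "G1"),
               class = "coherwalk_domain_error")
  expect_error(label_pair(ch, "P1", "P9", "G1"),
               class = "coherwalk_incomplete_data_error")
})

test_that("dataset size is choose(P,2) x G with correct class counts", {
  make_inputs <- function(P, G) {
    players <- sprintf("P%02d", 1:P); games <- sprintf("G%02d", 1:G)
    ch <- expand.grid(player_id = players, game_id = games,
                      stringsAsFactors = FALSE)
    set.seed(17)
    ch$option <- sample(c("A", "B"), nrow(ch), replace = TRUE)
    emb <- list()
    for (i in seq_len(nrow(ch))) {
      set.seed(i)
      p <- runif(2); p <- p / sum(p)
      emb[[paste(ch$player_id[i], ch$game_id[i], sep = "::")]] <-
        toy_embedding(p, 2L)
    }
    list(choices = choice_table(ch), embeddings = emb)
  }
  for (case in list(c(2, 1, 1), c(4, 3, 18), c(10, 12, 540))) {
    inp <- make_inputs(case[1], case[2])
    ds <- assemble_dataset(inp$embeddings, inp$choices)
    expect_equal(nrow(ds$features), case[3])
    expect_equal(ds$n_positive + ds$n_negative, case[3])
    expect_true(all(ds$meta$player_a < ds$meta$player_b))
    expect_identical(anyDuplicated(ds$meta[c("player_a", "player_b",
                                             "game_id")]), 0L)
  }
})

test_that("missing embeddings either abort or drop only the affected pairs", {
  ch <- choice_table(data.frame(player_id = rep(c("P1", "P2", "P3"), 2),
                                game_id = rep(c("G1", "G2"), each = 3),
                                option = "A"))
  emb <- list()
  for (k in c("P1::G1", "P2::G1", "P3::G1", "P1::G2", "P2::G2", "P3::G2")) {
    emb[[k]] <- toy_embedding(c(0.5, 0.5), 2L)
  }
  emb[["P3::G2"]] <- NULL
  expect_error(assemble_dataset(emb, ch),
               class = "coherwalk_incomplete_data_error")
  expect_warning(ds <- assemble_dataset(emb, ch, on_missing = "drop"),
                 "dropped")
  expect_equal(nrow(ds$features), 4L)  # 3 pairs in G1, 1 surviving in G2
})

test_that("bag-of-node-degree is the normalized degree histogram", {
  h <- bag_of_node_degree(complete_graph(16))
  expect_equal(unname(h["15"]), 1)
  expect_equal(sum(h), 1)
  h0 <- bag_of_node_degree(electrode_graph(matrix(0, 16, 16), montage_16()))
  expect_equal(unname(h0["0"]), 1)
  star <- matrix(0, 16, 16)
  star[1, 2:16] <- star[2:16, 1] <- 1
  hs <- bag_of_node_degree(electrode_graph(star, montage_16()))
  expect_equal(unname(hs["1"]), 15 / 16)
  expect_equal(unname(hs["15"]), 1 / 16)
  for (seed in 1:5) {
    h <- bag_of_node_degree(random_graph(16, 0.4, seed))
    expect_true(all(h >= 0))
    expect_equal(sum(h), 1)
  }
})
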