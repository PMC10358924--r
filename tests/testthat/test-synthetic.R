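test_that("choices follow the salience distribution", {
  # degenerate focal point: everyone coordinates
  cfg1 <- scenario_config(salience = c(1, 0, 0, 0), seed = 3)
  ch1 <- generate_choices(cfg1)
  expect_true(all(ch1$option == "opt1"))

  # uniform salience: empirical match rate near 1/4 over many games
  cfgU <- scenario_config(n_players = 2, n_games = 500,
                          salience = rep(0.25, 4), seed = 8)
  chU <- generate_choices(cfgU)
  match_rate <- mean(vapply(unique(chU$game_id), function(g) {
    opts <- chU$option[chU$game_id == g]
    as.integer(opts[1] == opts[2])
  }, integer(1)))
  expect_lt(abs(match_rate - 0.25), 0.03)

  # marginal frequencies track a skewed salience (chi-square sanity check)
  cfgS <- scenario_config(n_players = 10, n_games = 200, seed = 9)
  chS <- generate_choices(cfgS)
  tab <- table(factor(chS$option, levels = paste0("opt", 1:4)))
  p <- chisq.test(tab, p = c(0.40, 0.25, 0.20, 0.15))$p.value
  expect_gt(p, 1e-4)
})

test_that("scenario generation is fully deterministic in the seed", {
  cfg <- scenario_config(n_players = 4, n_games = 2, seed = 21)
  expect_identical(generate_choices(cfg), generate_choices(cfg))
  ch <- generate_choices(cfg)
  g1 <- generate_scenario_graphs(cfg, ch)
  g2 <- generate_scenario_graphs(cfg, ch)
  expect_identical(g1, g2)
  ep1 <- generate_epoch_signals(g1[[1]], cfg, seed = 4)
  ep2 <- generate_epoch_signals(g1[[1]], cfg, seed = 4)
  expect_identical(ep1$data, ep2$data)
})

test_that("noiseless players sharing an option have identical graphs and zero z", {
  cfg <- scenario_config(n_players = 4, n_games = 2, flip_prob_same = 0,
                         salience = c(1, 0, 0, 0), seed = 6)
  ch <- generate_choices(cfg)
  gs <- generate_scenario_graphs(cfg, ch)
  expect_identical(gs[["P01::G01"]]$adjacency, gs[["P02::G01"]]$adjacency)
  e1 <- exact_embedding(gs[["P01::G01"]], 3)
  e2 <- exact_embedding(gs[["P02::G01"]], 3)
  expect_equal(max(difference_vector(e1, e2)), 0)
})

test_that("same-option players overlap more than different-option players", {
  cfg <- scenario_config(seed = 13)
  overlap <- function(a, b) {
    up <- upper.tri(a)
    mean(a[up] == b[up])
  }
  same <- c(); diff <- c()
  for (g in 1:4) {
    ga <- generate_graph_for_choice(cfg, g, 1, 1)
    gb <- generate_graph_for_choice(cfg, g, 1, 2)
    gc <- generate_graph_for_choice(cfg, g, 2, 3)
    same <- c(same, overlap(ga$adjacency, gb$adjacency))
    diff <- c(diff, overlap(ga$adjacency, gc$adjacency))
  }
  expect_gt(mean(same), mean(diff))
  expect_gt(mean(same), 0.85)  # ~ (1 - 2 p (1 - p)) at p = 0.05
})

test_that("degenerate template settings behave as documented", {
  # full density, no noise: the complete 120-edge graph for everyone
  cfg <- scenario_config(n_players = 2, n_games = 1, flip_prob_same = 0,
                         template_density = 1, density_spread = 0,
                         seed = 2)
  g <- generate_graph_for_choice(cfg, 1, 1, 1)
  expect_equal(n_edges(g), 120L)
  # flip probability 0.5 destroys template information: two players on
  # the same template agree no more than chance
  cfg5 <- scenario_config(flip_prob_same = 0.5, seed = 4)
  ov <- vapply(1:6, function(g) {
    a <- generate_graph_for_choice(cfg5, g, 1, 1)$adjacency
    b <- generate_graph_for_choice(cfg5, g, 1, 2)$adjacency
    up <- upper.tri(a)
    mean(a[up] == b[up])
  }, numeric(1))
  expect_lt(abs(mean(ov) - 0.5), 0.08)
})

test_that("synthesized signals realize the target connectivity", {
  cfg <- scenario_config(seed = 31)
  pp <- preprocess_config(epoch_length = 10)
  # a single strong edge is recovered above threshold
  g1 <- single_edge_graph()
  ep <- generate_epoch_signals(g1, cfg, seed = 11, epoch_length = 10)
  expect_equal(dim(ep$data), c(16L, 5120L))
  C <- coherence_matrix(preprocess_epoch(ep, pp), graph_config())
  expect_gt(C$values["Fp1", "Fp2"], 0.5)
  # an empty graph yields almost no spurious edges in long-epoch mode
  g0 <- electrode_graph(matrix(0, 16, 16), montage_16())
  spurious <- vapply(1:3, function(s) {
    ep0 <- generate_epoch_signals(g0, cfg, seed = s, epoch_length = 10)
    n_edges(build_graph(coherence_matrix(preprocess_epoch(ep0, pp)),
                        graph_config())) / 120
  }, numeric(1))
  expect_lte(mean(spurious), 0.05)
  # 1-s epochs at 512 Hz condense to 64 samples downstream
  epshort <- generate_epoch_signals(g1, cfg, seed = 12)
  expect_equal(ncol(epshort$data), 512L)
  expect_equal(ncol(preprocess_epoch(epshort, preprocess_config())$data), 64L)
})
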