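test_that("node walks canonicalize by order of first appearance", {
  expect_identical(canonicalize_walk(c("Fp1", "F3", "Fp1", "C3")),
                   c(1L, 2L, 1L, 3L))
  # different electrodes, same revisit structure, same encoding
  expect_identical(canonicalize_walk(c("Cz", "Pz", "Cz")),
                   canonicalize_walk(c("O1", "T3", "O1")))
  expect_identical(canonicalize_walk("Fz"), 1L)
  expect_error(canonicalize_walk(c("Cz", "Cz")),
               class = "coherwalk_domain_error")
  expect_error(canonicalize_walk(character(0)),
               class = "coherwalk_domain_error")
})

test_that("enumeration matches the closed recursion and known vocabulary sizes", {
  expect_identical(enumerate_walks(1)$patterns, list(c(1L, 2L)))
  expect_identical(
    enumerate_walks(3)$keys,
    c("1-2-1-2", "1-2-1-3", "1-2-3-1", "1-2-3-2", "1-2-3-4")
  )
  for (l in 1:8) {
    idx <- enumerate_walks(l)
    expect_identical(idx$size, as.integer(walk_count_recursion(l)))
    expect_identical(anyDuplicated(idx$keys), 0L)
    expect_false(is.unsorted(idx$keys))  # deterministic lexicographic order
    # every pattern is valid: starts at 1, steps bounded, no repeats
    for (p in idx$patterns[c(1L, idx$size)]) {
      expect_identical(p[1L], 1L)
      expect_true(all(diff(p) != 0))
      expect_true(all(p <= cummax(c(1L, head(p, -1L) + 1L))))
    }
  }
  expect_identical(sapply(1:7, function(l) enumerate_walks(l)$size),
                   c(1L, 2L, 5L, 15L, 52L, 203L, 877L))
  expect_error(enumerate_walks(0), class = "coherwalk_domain_error")
})

test_that("embedding vocabulary grows strictly with walk length", {
  sizes <- sapply(1:8, function(l) enumerate_walks(l)$size)
  expect_true(all(diff(sizes) > 0))
})

test_that("the sample-size bound reproduces its analytic values", {
  expect_identical(required_walk_count(52, 0.1, 0.01), 8130L)
  expect_identical(required_walk_count(2, 0.1, 0.01), 1060L)
  expect_error(required_walk_count(1, 0.1, 0.01),
               class = "coherwalk_domain_error")
  # stable for a vocabulary far beyond double precision of 2^N
  expect_gt(required_walk_count(877, 0.1, 0.01), 100000L)
})

test_that("exact embeddings match hand-derived and brute-force distributions", {
  e <- exact_embedding(path3_graph(), 2)
  expect_equal(unname(e$probabilities),
               c(2 / 3, 1 / 3))  # patterns 1-2-1, 1-2-3
  e3 <- exact_embedding(complete_graph(3), 2)
  expect_equal(unname(e3$probabilities), c(0.5, 0.5))

  for (seed in c(7, 8)) {
    g <- random_graph(6, 0.4, seed)
    for (l in c(2, 3)) {
      mine <- exact_embedding(g, l)
      ref <- exact_embedding_bruteforce(g$adjacency, l)
      expect_equal(sum(mine$probabilities), 1, tolerance = 1e-9)
      got <- mine$probabilities[names(ref)]
      expect_equal(unname(got), unname(ref), tolerance = 1e-12)
      # patterns the oracle never saw must carry zero mass
      expect_equal(sum(mine$probabilities[setdiff(names(mine$probabilities),
                                                  names(ref))]), 0)
    }
  }
})

test_that("exact embeddings are invariant under node relabeling", {
  for (seed in 1:10) {
    g <- random_graph(16, 0.3, seed)
    set.seed(seed + 1000)
    perm <- sample(16)
    gp <- electrode_graph(g$adjacency[perm, perm], g$node_labels[perm])
    # agreement to float summation order (the DFS visits walks differently)
    expect_equal(exact_embedding(g, 4)$probabilities,
                 exact_embedding(gp, 4)$probabilities, tolerance = 1e-13)
  }
})

test_that("sampled embeddings are deterministic, normalized and near the exact law", {
  g <- path3_graph()
  plan <- sampling_plan(2)
  expect_identical(plan$m, 1060L)  # N = 2 at l = 2
  e1 <- sample_embedding(g, 2, plan, seed = 42)
  e2 <- sample_embedding(g, 2, plan, seed = 42)
  expect_identical(e1$probabilities, e2$probabilities)
  expect_equal(sum(e1$probabilities), 1)
  expect_true(all(e1$probabilities * plan$m ==
                    round(e1$probabilities * plan$m)))
  expect_lt(sum(abs(e1$probabilities - exact_embedding(g, 2)$probabilities)),
            0.1)
})

test_that("a single-edge graph forces the alternating pattern", {
  g <- single_edge_graph()
  for (l in c(2, 4)) {
    e <- sample_embedding(g, l, sampling_plan(l, m = 200), seed = 5)
    key <- paste(rep(1:2, length.out = l + 1), collapse = "-")
    expect_equal(unname(e$probabilities[key]), 1)
  }
})

test_that("the Monte-Carlo bound holds empirically on the 3-node path", {
  g <- path3_graph()
  exact <- exact_embedding(g, 2)$probabilities
  plan <- sampling_plan(2)  # epsilon 0.1, delta 0.01 -> m = 1060
  l1 <- vapply(1:20, function(s) {
    sum(abs(sample_embedding(g, 2, plan, seed = s)$probabilities - exact))
  }, numeric(1))
  # failure probability delta = 1%; allow a generous 10% of 20 runs
  expect_lte(mean(l1 > plan$epsilon), 0.10)
})

test_that("edgeless graphs cannot be embedded", {
  g0 <- electrode_graph(matrix(0, 4, 4), paste0("n", 1:4))
  expect_error(exact_embedding(g0, 2), class = "coherwalk_no_walk_error")
  expect_error(sample_embedding(g0, 2, sampling_plan(2)),
               class = "coherwalk_no_walk_error")
})
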