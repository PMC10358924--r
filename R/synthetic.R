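#' Standard 16-channel 10-20 electrode montage
#' @return Character vector of 16 electrode names.
#' @export
montage_16 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "F4", "F8", "T3", "C3",
    "C4", "T4", "T5", "P3", "P4", "T6", "O1", "O2")
}

# deterministic sub-seed derivation so every synthetic object depends
# only on (scenario seed, indices), never on call order
derive_seed <- function(seed, a = 0L, b = 0L, c = 0L) {
  ((as.numeric(seed) %% 97777) * 1009 + a * 131071 + b * 8191 + c * 127 + 17) %%
    2147483629
}

#' Synthetic-scenario configuration
#'
#' Emulates the behavioral design (10 players, 12 tacit coordination
#' games with 4 candidate words each) and provides controllable
#' inter-player graph similarity: each (game, option) has a fixed random
#' template graph, and a player's graph is that template with
#' independent edge flips. Players choosing the same option therefore
#' share a template (similar graphs); different options have templates
#' that were themselves perturbed from a per-game base, so their graphs
#' differ more.
#'
#' @param n_players,n_games,n_options scenario dimensions (defaults
#'   10, 12, 4, giving choose(10,2)*12 = 540 pair observations).
#' @param salience probability over the options of a game (focal-point
#'   strength); either one vector recycled across games or a
#'   `n_games x n_options` matrix. The default (0.40, 0.25, 0.20, 0.15)
#'   encodes a strong focal point with an expected coordination rate of
#'   about 28.5%, near the roughly 28% positive fraction such tasks show.
#' @param flip_prob_same edge-flip probability applied to a player's
#'   copy of their option template (within-solution noise; in \[0, 0.5\];
#'   0.5 destroys all template information).
#' @param flip_prob_diff between-solution dissimilarity knob: 0.5 (the
#'   default) draws every (game, option) template independently at
#'   `template_density`; smaller values derive the option templates from
#'   a common per-game base by edge flips at this rate (0 makes all
#'   options of a game identical, removing the class signal).
#' @param template_density expected edge fraction of templates. Each
#'   template's realized density is drawn uniformly from
#'   `template_density` +/- `density_spread`, emulating the wide
#'   variation in overall synchronization between brain states; edge
#'   probabilities are additionally weighted by random per-node hub
#'   strengths, giving templates the heterogeneous degree structure
#'   coherence networks show. Both features make different templates
#'   distinguishable in walk space.
#' @param density_spread half-width of the per-template density range
#'   (set 0 for fixed-density Erdos-Renyi-style templates).
#' @param snr signal power ratio of shared sources to channel noise in
#'   signal-level synthesis.
#' @param fs,epoch_length sampling rate (Hz) and epoch duration (s) for
#'   signal-level synthesis.
#' @param signal_band band (Hz) of the shared broadband sources.
#' @param channel_labels electrode names (defaults to [montage_16()]).
#' @param seed master seed; all generated objects are deterministic
#'   functions of it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_players = 10L, n_games = 12L, n_options = 4L,
                            salience = c(0.40, 0.25, 0.20, 0.15),
                            flip_prob_same = 0.05, flip_prob_diff = 0.5,
                            template_density = 0.35, density_spread = 0.15,
                            snr = 9,
                            fs = 512, epoch_length = 1,
                            signal_band = c(1, 31),
                            channel_labels = montage_16(), seed = 1L) {
  if (is.matrix(salience)) {
    if (ncol(salience) != n_options || nrow(salience) != n_games) {
      cw_stop("coherwalk_config_error",
              "salience matrix must be n_games x n_options")
    }
  } else {
    if (length(salience) != n_options) {
      cw_stop("coherwalk_config_error",
              "salience must have one probability per option")
    }
    salience <- matrix(salience, n_games, n_options, byrow = TRUE)
  }
  if (any(abs(rowSums(salience) - 1) > 1e-8) || any(salience < 0)) {
    cw_stop("coherwalk_config_error", "salience rows must be probability vectors")
  }
  if (flip_prob_same < 0 || flip_prob_same > 0.5 ||
      flip_prob_diff < 0 || flip_prob_diff > 0.5) {
    cw_stop("coherwalk_config_error", "flip probabilities must be in [0, 0.5]")
  }
  if (template_density <= 0 || template_density > 1) {
    cw_stop("coherwalk_config_error", "template_density must be in (0, 1]")
  }
  if (density_spread < 0) {
    cw_stop("coherwalk_config_error", "density_spread must be >= 0")
  }
  structure(list(n_players = as.integer(n_players),
                 n_games = as.integer(n_games),
                 n_options = as.integer(n_options), salience = salience,
                 flip_prob_same = flip_prob_same,
                 flip_prob_diff = flip_prob_diff,
                 template_density = template_density,
                 density_spread = density_spread, snr = snr, fs = fs,
                 epoch_length = epoch_length, signal_band = signal_band,
                 channel_labels = channel_labels, seed = as.integer(seed)),
            class = "scenario_config")
}

player_ids <- function(cfg) sprintf("P%02d", seq_len(cfg$n_players))
game_ids <- function(cfg) sprintf("G%02d", seq_len(cfg$n_games))
option_ids <- function(cfg) sprintf("opt%d", seq_len(cfg$n_options))

#' Generate behavioral choices
#'
#' Each player's choice in each game is drawn independently from that
#' game's salience distribution over the options.
#'
#' @param cfg a [scenario_config()].
#' @return A [choice_table()].
#' @export
generate_choices <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  players <- player_ids(cfg); games <- game_ids(cfg); opts <- option_ids(cfg)
  rows <- expand.grid(player_id = players, game_id = games,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(derive_seed(cfg$seed, 1L))
  rows$option <- vapply(seq_len(nrow(rows)), function(i) {
    gi <- match(rows$game_id[i], games)
    sample(opts, 1L, prob = cfg$salience[gi, ])
  }, character(1))
  choice_table(rows)
}

rand_template <- function(n, density, spread, seed, labels) {
  if (density >= 1) {               # saturated synchronization: complete graph
    A <- matrix(1, n, n) - diag(n)
    dimnames(A) <- list(labels, labels)
    return(A)
  }
  set.seed(seed)
  lo <- max(0.02, density - spread)
  hi <- min(0.98, density + spread)
  if (hi < lo) lo <- hi <- min(max(density, 0.02), 0.98)
  d <- stats::runif(1, lo, hi)
  w <- stats::runif(n)^2
  w <- w / mean(w)                       # hub strengths, mean 1
  P <- pmin(d * outer(w, w, `+`) / 2, 1) # expected density ~ d
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(stats::runif(sum(up)) < P[up])
  A <- A + t(A)
  dimnames(A) <- list(labels, labels)
  A
}

flip_edges <- function(A, p, seed) {
  set.seed(seed)
  up <- upper.tri(A)
  flip <- stats::runif(sum(up)) < p
  v <- A[up]
  v[flip] <- 1 - v[flip]
  A[up] <- v
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

#' Template graph of a (game, option) cell
#'
#' With the default `flip_prob_diff = 0.5` every (game, option) template
#' is an independent Erdos-Renyi-style draw at `template_density`; with
#' `flip_prob_diff < 0.5` the option templates of a game are correlated
#' copies of a per-game base (edge flips at that rate). Deterministic in
#' (seed, game, option).
#'
#' @param cfg a [scenario_config()].
#' @param game,option indices (1-based) or ids.
#' @return An [electrode_graph()].
#' @export
option_template <- function(cfg, game, option) {
  gi <- if (is.character(game)) match(game, game_ids(cfg)) else game
  oi <- if (is.character(option)) match(option, option_ids(cfg)) else option
  n <- length(cfg$channel_labels)
  if (cfg$flip_prob_diff >= 0.5) {
    A <- rand_template(n, cfg$template_density, cfg$density_spread,
                       derive_seed(cfg$seed, 3L, gi, oi), cfg$channel_labels)
  } else {
    base <- rand_template(n, cfg$template_density, cfg$density_spread,
                          derive_seed(cfg$seed, 2L, gi), cfg$channel_labels)
    A <- flip_edges(base, cfg$flip_prob_diff, derive_seed(cfg$seed, 3L, gi, oi))
  }
  electrode_graph(A, cfg$channel_labels)
}

#' Generate one player's graph for a chosen option
#'
#' The player's graph is the (game, option) template with every edge
#' indicator independently flipped with probability `flip_prob_same`
#' (symmetric flips keep expected density stable). Players who chose the
#' same option thus share a template and differ only by noise.
#'
#' @param cfg a [scenario_config()].
#' @param game,option,player indices (1-based) or ids.
#' @return An [electrode_graph()].
#' @export
generate_graph_for_choice <- function(cfg, game, option, player) {
  gi <- if (is.character(game)) match(game, game_ids(cfg)) else game
  pi <- if (is.character(player)) match(player, player_ids(cfg)) else player
  tmpl <- option_template(cfg, game, option)
  A <- flip_edges(tmpl$adjacency, cfg$flip_prob_same,
                  derive_seed(cfg$seed, 4L, gi, pi))
  electrode_graph(A, cfg$channel_labels)
}

#' Generate all per-(player, game) graphs of a scenario
#'
#' @param cfg a [scenario_config()].
#' @param choices a [choice_table()]; defaults to
#'   [generate_choices()] on `cfg`.
#' @return Named list of [electrode_graph()]s keyed `"<player>::<game>"`.
#' @export
generate_scenario_graphs <- function(cfg, choices = generate_choices(cfg)) {
  out <- list()
  for (g in game_ids(cfg)) {
    for (p in player_ids(cfg)) {
      opt <- choice_lookup(choices, p, g)
      out[[embedding_key(p, g)]] <- generate_graph_for_choice(cfg, g, opt, p)
    }
  }
  out
}

#' Synthesize EEG-like signals realizing a connectivity graph
#'
#' Every edge of `g` is assigned an independent broadband source inside
#' `signal_band`; the two channels it joins both receive that source
#' (scaled so total shared-source power is `snr` times the independent
#' channel noise), so connected channels are coherent while unconnected
#' ones are not. Because a channel's power is split across its incident
#' edges, pairwise coherence falls with node degree: recovery by
#' coherence thresholding is faithful for sparse graphs and degrades for
#' dense ones. No volume conduction, 1/f background or artifacts are
#' modeled.
#'
#' @param g an [electrode_graph()].
#' @param cfg a [scenario_config()] (uses `fs`, `epoch_length`, `snr`,
#'   `signal_band`).
#' @param seed integer seed.
#' @param epoch_length override of `cfg$epoch_length`, e.g. for
#'   long-epoch validation runs where the Welch estimate has many
#'   segments and little bias.
#' @return An [eeg_epoch()] at `cfg$fs`.
#' @export
generate_epoch_signals <- function(g, cfg, seed = cfg$seed,
                                   epoch_length = cfg$epoch_length) {
  stopifnot(inherits(g, "electrode_graph"), inherits(cfg, "scenario_config"))
  n <- nrow(g$adjacency)
  ns <- as.integer(round(cfg$fs * epoch_length))
  set.seed(derive_seed(seed, 5L))
  bf <- signal::butter(4, cfg$signal_band / (cfg$fs / 2), type = "pass")
  band_noise <- function() {
    v <- signal::filtfilt(bf, stats::rnorm(ns))
    v / stats::sd(v)  # unit power so snr is a true power ratio
  }
  x <- matrix(0, n, ns)
  deg <- rowSums(g$adjacency)
  edges <- which(upper.tri(g$adjacency) & g$adjacency == 1, arr.ind = TRUE)
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      s <- band_noise()
      i <- edges[e, 1L]; j <- edges[e, 2L]
      x[i, ] <- x[i, ] + s / sqrt(deg[i])
      x[j, ] <- x[j, ] + s / sqrt(deg[j])
    }
  }
  noise <- t(vapply(seq_len(n), function(i) band_noise(), numeric(ns)))
  scale_src <- sqrt(cfg$snr)
  x <- scale_src * sweep(x, 1L, apply_sd_guard(x), "/") + noise
  eeg_epoch(x, cfg$fs, g$node_labels)
}

# normalize rows with any signal to unit sd so snr is a power ratio;
# rows without sources stay zero
apply_sd_guard <- function(x) {
  s <- apply(x, 1L, stats::sd)
  s[s == 0] <- 1
  s
}
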