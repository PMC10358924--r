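#' Behavioral choice table
#'
#' One row per (player, game): which of the game's options (e.g. one of
#' four words such as "Water", "Beer", "Wine", "Whisky") the player
#' picked. Coordination labels are derived from it pairwise.
#'
#' @param df data frame with columns `player_id`, `game_id`, `option`.
#' @return An object of class `choice_table` (a validated data frame).
#' @export
choice_table <- function(df) {
  need <- c("player_id", "game_id", "option")
  if (!all(need %in% names(df))) {
    cw_stop("coherwalk_data_error", "choice table needs columns: %s",
            paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  df$player_id <- as.character(df$player_id)
  df$game_id <- as.character(df$game_id)
  df$option <- as.character(df$option)
  if (anyDuplicated(df[c("player_id", "game_id")])) {
    cw_stop("coherwalk_data_error",
            "duplicate (player_id, game_id) entries in choice table")
  }
  class(df) <- c("choice_table", "data.frame")
  df
}

choice_lookup <- function(choices, player, game) {
  hit <- choices$player_id == player & choices$game_id == game
  if (!any(hit)) {
    cw_stop("coherwalk_incomplete_data_error",
            "no choice recorded for player '%s' in game '%s'", player, game)
  }
  choices$option[which(hit)[1L]]
}

#' Coordination label for a player pair in one game
#'
#' @param choices a [choice_table()].
#' @param a,b distinct player identifiers.
#' @param game game identifier.
#' @return 1 if both players chose the same option (coordination),
#'   else 0.
#' @export
label_pair <- function(choices, a, b, game) {
  if (a == b) {
    cw_stop("coherwalk_domain_error",
            "a pair must consist of two distinct players (got '%s' twice)", a)
  }
  as.integer(choice_lookup(choices, a, game) == choice_lookup(choices, b, game))
}

#' Absolute difference of two embeddings
#'
#' The feature vector for a player pair: z = |e1 - e2|, element-wise.
#' Symmetric in its arguments, zero iff the embeddings coincide.
#'
#' @param e1,e2 `walk_embedding`s (or plain probability vectors) of equal
#'   length, computed at the same walk length.
#' @return Numeric vector of non-negative differences.
#' @export
difference_vector <- function(e1, e2) {
  v1 <- if (inherits(e1, "walk_embedding")) e1$probabilities else e1
  v2 <- if (inherits(e2, "walk_embedding")) e2$probabilities else e2
  if (length(v1) != length(v2)) {
    cw_stop("coherwalk_dimension_error",
            "embedding lengths differ: %d vs %d", length(v1), length(v2))
  }
  if (inherits(e1, "walk_embedding") && inherits(e2, "walk_embedding") &&
      e1$length != e2$length) {
    cw_stop("coherwalk_dimension_error",
            "embeddings come from different walk lengths: %d vs %d",
            e1$length, e2$length)
  }
  abs(v1 - v2)
}

embedding_key <- function(player, game) paste(player, game, sep = "::")

#' Assemble the labeled pair dataset
#'
#' One observation per unordered pair of distinct players per game:
#' features z = |e_a - e_b| and the coordination label from the choice
#' table. Players are ordered by identifier so each pair appears once
#' (the absolute difference makes orientation irrelevant anyway). Ten
#' players and twelve games yield choose(10,2) * 12 = 540 observations.
#'
#' @param embeddings named list of `walk_embedding`s keyed
#'   `"<player>::<game>"` (see [embed_graphs()]).
#' @param choices a [choice_table()].
#' @param on_missing `"error"` (default) to fail on any missing
#'   embedding, or `"drop"` to exclude only the affected pairs with a
#'   warning.
#' @return An object of class `pair_dataset`: `features` (matrix, one
#'   row per observation), `meta` (player_a, player_b, game_id, label),
#'   `n_positive`, `n_negative`.
#' @export
assemble_dataset <- function(embeddings, choices,
                             on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  players <- sort(unique(choices$player_id))
  games <- unique(choices$game_id)
  if (length(players) < 2L) {
    cw_stop("coherwalk_data_error", "need at least two players")
  }
  pairs <- utils::combn(players, 2L)
  rows <- list(); meta <- list(); dropped <- 0L
  for (g in games) {
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      ka <- embedding_key(a, g); kb <- embedding_key(b, g)
      if (is.null(embeddings[[ka]]) || is.null(embeddings[[kb]])) {
        if (on_missing == "error") {
          miss <- if (is.null(embeddings[[ka]])) ka else kb
          cw_stop("coherwalk_incomplete_data_error",
                  "missing embedding for %s", miss)
        }
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        difference_vector(embeddings[[ka]], embeddings[[kb]])
      meta[[length(meta) + 1L]] <-
        data.frame(player_a = a, player_b = b, game_id = g,
                   label = label_pair(choices, a, b, g),
                   stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d pair observations with missing embeddings",
                    dropped))
  }
  if (length(rows) == 0L) cw_stop("coherwalk_data_error", "no observations")
  features <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  structure(list(features = features, meta = meta,
                 n_positive = sum(meta$label == 1L),
                 n_negative = sum(meta$label == 0L)),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset> %d observations (%d positive, %d negative), %d features\n",
              nrow(x$features), x$n_positive, x$n_negative, ncol(x$features)))
  invisible(x)
}

#' Bag-of-Node-Degree graph embedding (baseline)
#'
#' Projects a graph onto the normalized histogram of its node degrees:
#' entry d (d = 0 .. n-1) is the fraction of nodes with degree d. A much
#' coarser, cheaper fingerprint than the anonymous-walk distribution,
#' used as the comparison baseline.
#'
#' @param g an [electrode_graph()].
#' @return Numeric vector of length n summing to 1, named by degree.
#' @export
bag_of_node_degree <- function(g) {
  stopifnot(inherits(g, "electrode_graph"))
  n <- nrow(g$adjacency)
  deg <- rowSums(g$adjacency)
  h <- tabulate(deg + 1L, nbins = n) / n
  names(h) <- as.character(seq_len(n) - 1L)
  h
}
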