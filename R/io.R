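parse_error <- function(path, line, msg, ...) {
  cw_stop("coherwalk_parse_error", "%s:%s: %s", path, line, sprintf(msg, ...))
}

#' Write / read an electrode graph
#'
#' Two plain-text formats: an edge list (`labelA<TAB>labelB` per line,
#' preceded by a `# nodes:` header line so isolated nodes survive the
#' round trip) and a labeled square 0/1 adjacency CSV. Readers validate
#' the simple-graph invariants (binary, symmetric, zero diagonal) and
#' reject violations with the offending location.
#'
#' @param g an [electrode_graph()].
#' @param path output file.
#' @param format `"adjacency"` (CSV) or `"edgelist"` (TSV).
#' @return `write_graph`: the path, invisibly. `read_graph`: an
#'   [electrode_graph()].
#' @export
write_graph <- function(g, path, format = c("adjacency", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "electrode_graph"))
  if (format == "adjacency") {
    utils::write.csv(g$adjacency, path, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# nodes: ", paste(g$node_labels, collapse = ",")), con)
    idx <- which(upper.tri(g$adjacency) & g$adjacency == 1, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      writeLines(paste(g$node_labels[idx[, 1L]], g$node_labels[idx[, 2L]],
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path, format = c("adjacency", "edgelist")) {
  format <- match.arg(format)
  if (format == "adjacency") {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    A <- as.matrix(df)
    if (nrow(A) != ncol(A)) parse_error(path, "-", "adjacency not square")
    if (!all(A %in% c(0, 1))) parse_error(path, "-", "adjacency not binary")
    if (any(diag(A) != 0)) parse_error(path, "-", "nonzero diagonal (self-loop)")
    if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
      parse_error(path, "-", "adjacency not symmetric")
    }
    electrode_graph(A, rownames(A))
  } else {
    lines <- readLines(path)
    if (length(lines) == 0L || !startsWith(lines[1L], "# nodes:")) {
      parse_error(path, 1L, "missing '# nodes:' header")
    }
    labels <- trimws(strsplit(sub("^# nodes:\\s*", "", lines[1L]), ",")[[1L]])
    A <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (ln in seq_along(lines)[-1L]) {
      if (!nzchar(trimws(lines[ln]))) next
      parts <- strsplit(lines[ln], "\t")[[1L]]
      if (length(parts) != 2L) parse_error(path, ln, "expected two fields")
      i <- match(parts[1L], labels); j <- match(parts[2L], labels)
      if (is.na(i) || is.na(j)) parse_error(path, ln, "unknown node label")
      if (i == j) parse_error(path, ln, "self-loop not allowed")
      A[i, j] <- A[j, i] <- 1
    }
    electrode_graph(A, labels)
  }
}

#' Write / read anonymous-walk embeddings
#'
#' Long-format TSV with header `player_id  game_id  l  pattern
#' probability`; pattern strings look like `1-2-1-3`. A single embedding
#' can be written by wrapping it in a one-element named list
#' (`list("P01::G01" = e)`).
#'
#' @param embeddings named list of `walk_embedding`s keyed
#'   `"<player>::<game>"`.
#' @param path file path.
#' @return `write_embeddings`: the path, invisibly; `read_embeddings`:
#'   a named list of `walk_embedding`s.
#' @export
write_embeddings <- function(embeddings, path) {
  rows <- lapply(names(embeddings), function(k) {
    e <- embeddings[[k]]
    pg <- strsplit(k, "::", fixed = TRUE)[[1L]]
    data.frame(player_id = pg[1L], game_id = pg[2L], l = e$length,
               pattern = names(e$probabilities),
               probability = unname(e$probabilities),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pattern = "character"))
  need <- c("player_id", "game_id", "l", "pattern", "probability")
  if (!all(need %in% names(df))) parse_error(path, 1L, "bad embeddings header")
  out <- list()
  for (key in unique(embedding_key(df$player_id, df$game_id))) {
    pg <- strsplit(key, "::", fixed = TRUE)[[1L]]
    sub <- df[df$player_id == pg[1L] & df$game_id == pg[2L], ]
    l <- unique(sub$l)
    if (length(l) != 1L) parse_error(path, "-", "mixed walk lengths for %s", key)
    index <- enumerate_walks(l)
    pos <- match(index$keys, sub$pattern)
    if (anyNA(pos)) parse_error(path, "-", "missing pattern rows for %s", key)
    out[[key]] <- new_walk_embedding(sub$probability[pos], index)
  }
  out
}

#' Write / read a behavioral choice table
#'
#' TSV with columns `player_id`, `game_id`, `option`.
#'
#' @param choices a [choice_table()].
#' @param path file path.
#' @return `write_choices`: the path, invisibly; `read_choices`: a
#'   [choice_table()].
#' @export
write_choices <- function(choices, path) {
  utils::write.table(as.data.frame(choices), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  choice_table(df)
}

#' Write / read the labeled pair dataset
#'
#' TSV with one row per observation: `player_a`, `player_b`, `game_id`,
#' `label`, then the feature columns `z1..zN`.
#'
#' @param ds a `pair_dataset`.
#' @param path file path.
#' @return `write_dataset`: the path, invisibly; `read_dataset`: a
#'   `pair_dataset`.
#' @export
write_dataset <- function(ds, path) {
  z <- ds$features
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  utils::write.table(cbind(ds$meta, z), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta_cols <- c("player_a", "player_b", "game_id", "label")
  if (!all(meta_cols %in% names(df))) parse_error(path, 1L, "bad dataset header")
  zcols <- grep("^z[0-9]+$", names(df), value = TRUE)
  features <- as.matrix(df[zcols])
  colnames(features) <- NULL
  meta <- df[meta_cols]
  structure(list(features = features, meta = meta,
                 n_positive = sum(meta$label == 1L),
                 n_negative = sum(meta$label == 0L)),
            class = "pair_dataset")
}

#' Read / write a channels x samples matrix as delimited text
#'
#' On disk the matrix is stored samples-in-rows with a header row of
#' channel labels (a natural spreadsheet layout); in memory it is the
#' channels x samples [eeg_epoch()].
#'
#' @param path file path.
#' @param fs sampling rate in Hz of the stored signals.
#' @param player_id,game_id identifiers attached to the epoch.
#' @param epoch an [eeg_epoch()] (for the writer).
#' @param sep field separator (default tab).
#' @return `read_epoch_matrix`: an [eeg_epoch()]; `write_epoch_matrix`:
#'   the path, invisibly.
#' @export
read_epoch_matrix <- function(path, fs, player_id = NA_character_,
                              game_id = NA_character_, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    parse_error(path, "-", "non-numeric sample values")
  }
  eeg_epoch(t(as.matrix(df)), fs, names(df), player_id, game_id)
}

#' @rdname read_epoch_matrix
#' @export
write_epoch_matrix <- function(epoch, path, sep = "\t") {
  m <- t(epoch$data)
  colnames(m) <- epoch$channel_labels
  utils::write.table(m, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal European Data Format (EDF) reader
#'
#' Parses the fixed-width ASCII header and 16-bit little-endian sample
#' records of an EDF file and rescales digital values to physical units.
#' All signals must share one sampling rate (true for the single-amp
#' recordings this package targets); annotations channels are not
#' supported.
#'
#' @param path EDF file.
#' @param player_id,game_id identifiers attached to the epoch.
#' @return An [eeg_epoch()] spanning the whole recording.
#' @export
read_edf <- function(path, player_id = NA_character_, game_id = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_chr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr_chr(8)                                    # version
  hdr_chr(80); hdr_chr(80)                      # patient, recording ids
  hdr_chr(8); hdr_chr(8)                        # start date, time
  header_bytes <- as.integer(hdr_chr(8))
  hdr_chr(44)                                   # reserved
  n_rec <- as.integer(hdr_chr(8))
  rec_dur <- as.numeric(hdr_chr(8))
  ns <- as.integer(hdr_chr(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr_chr(w), character(1))
  labels <- field(16)
  field(80); field(8)                           # transducer, dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)                                     # prefiltering
  spr <- as.integer(field(8))                   # samples per record
  field(32)                                     # reserved
  if (length(unique(spr)) != 1L) {
    parse_error(path, "-", "signals have differing sampling rates")
  }
  if (n_rec < 0) parse_error(path, "-", "unknown record count (-1) unsupported")
  seek(con, header_bytes)
  x <- matrix(0, ns, n_rec * spr[1L])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[1L], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) < spr[1L]) parse_error(path, "-", "truncated data record")
      cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
      x[s, cols] <- phys_min[s] + gain[s] * (d - dig_min[s])
    }
  }
  eeg_epoch(x, spr[1L] / rec_dur, labels, player_id, game_id)
}
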