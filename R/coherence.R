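#' Graph-construction configuration
#'
#' Controls the Welch cross-spectral coherence estimate and the edge
#' threshold. The per-pair scalar is the mean coherence over frequency
#' bins inside `band`. With the default 64-sample epoch the Welch
#' estimate uses 3 half-overlapping Hann segments; so few segments bias
#' the estimate upward, which is why `segment_length` and
#' `segment_overlap` are exposed (longer epochs give more segments and
#' less bias).
#'
#' @param threshold coherence value at or above which an edge is drawn
#'   (inclusive), in (0, 1].
#' @param estimator `"magnitude_coherency"` (|Sxy| / sqrt(Sxx Syy),
#'   already in \[0,1\]) or `"magnitude_squared"` (its square).
#' @param segment_length,segment_overlap Welch segment size and overlap,
#'   in samples.
#' @param band two-element numeric, frequency band in Hz over which
#'   per-bin coherence is averaged (DC bin excluded).
#' @return An object of class `graph_config`.
#' @export
graph_config <- function(threshold = 0.5,
                         estimator = c("magnitude_coherency", "magnitude_squared"),
                         segment_length = 32, segment_overlap = 16,
                         band = c(1, 32)) {
  estimator <- match.arg(estimator)
  if (!(threshold > 0 && threshold <= 1)) {
    cw_stop("coherwalk_config_error", "threshold must be in (0, 1]")
  }
  if (segment_overlap >= segment_length) {
    cw_stop("coherwalk_config_error", "segment_overlap must be < segment_length")
  }
  structure(list(threshold = threshold, estimator = estimator,
                 segment_length = as.integer(segment_length),
                 segment_overlap = as.integer(segment_overlap),
                 band = as.numeric(band)),
            class = "graph_config")
}

# Welch averaged (cross-)periodograms for all channel pairs at once.
# Returns list(freq, S) where S[i, j, k] is the cross-spectrum of
# channels i, j at frequency bin k (i == j gives the auto-spectrum).
welch_cross_spectra <- function(x, fs, seg_len, overlap) {
  n <- ncol(x)
  if (seg_len > n) {
    cw_stop("coherwalk_config_error",
            "segment_length %d exceeds epoch length %d samples", seg_len, n)
  }
  step <- seg_len - overlap
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0L, seg_len - 1L) / seg_len)  # Hann
  nch <- nrow(x)
  nfreq <- seg_len %/% 2L + 1L
  S <- array(complex(real = 0), dim = c(nch, nch, nfreq))
  for (s in starts) {
    seg <- x[, s:(s + seg_len - 1L), drop = FALSE]
    seg <- sweep(seg, 1L, rowMeans(seg))          # detrend (mean) per segment
    F <- t(apply(sweep(seg, 2L, win, `*`), 1L, stats::fft))[, seq_len(nfreq), drop = FALSE]
    for (k in seq_len(nfreq)) {
      S[, , k] <- S[, , k] + tcrossprod(F[, k], Conj(F[, k]))
    }
  }
  S <- S / length(starts)
  list(freq = (seq_len(nfreq) - 1L) * fs / seg_len, S = S)
}

#' Pairwise coherence matrix of an epoch
#'
#' Estimates the coherence spectrum of every electrode pair with a Welch
#' cross-spectral estimate (Hann window, overlapping segments) and
#' averages it over the frequency bins inside `cfg$band`, yielding one
#' scalar per pair. Coherence of a channel with itself is exactly 1.
#'
#' @param epoch a conditioned [eeg_epoch()] (see [preprocess_epoch()]).
#' @param cfg a [graph_config()].
#' @return An object of class `coherence_matrix`: a symmetric matrix with
#'   unit diagonal and entries in \[0, 1\], plus channel labels.
#' @export
coherence_matrix <- function(epoch, cfg = graph_config()) {
  stopifnot(inherits(epoch, "eeg_epoch"), inherits(cfg, "graph_config"))
  x <- epoch$data
  if (nrow(x) < 2L) {
    cw_stop("coherwalk_config_error", "need at least 2 channels for coherence")
  }
  flat <- apply(x, 1L, function(ch) isTRUE(all.equal(stats::var(ch), 0)))
  if (any(flat)) {
    cw_stop("coherwalk_data_error",
            "coherence undefined for zero-variance channel(s): %s",
            paste(epoch$channel_labels[flat], collapse = ", "))
  }
  ws <- welch_cross_spectra(x, epoch$fs, cfg$segment_length, cfg$segment_overlap)
  in_band <- ws$freq >= cfg$band[1] & ws$freq <= cfg$band[2] & ws$freq > 0
  if (!any(in_band)) {
    cw_stop("coherwalk_config_error", "no frequency bins inside band [%g, %g] Hz",
            cfg$band[1], cfg$band[2])
  }
  nch <- nrow(x)
  C <- matrix(0, nch, nch, dimnames = list(epoch$channel_labels,
                                           epoch$channel_labels))
  bins <- which(in_band)
  for (i in seq_len(nch)) {
    for (j in seq_len(nch)) {
      if (j <= i) next
      coh <- vapply(bins, function(k) {
        Mod(ws$S[i, j, k]) / sqrt(Re(ws$S[i, i, k]) * Re(ws$S[j, j, k]))
      }, numeric(1))
      if (cfg$estimator == "magnitude_squared") coh <- coh^2
      C[i, j] <- C[j, i] <- mean(coh)
    }
  }
  diag(C) <- 1
  C <- pmin(pmax(C, 0), 1)  # guard against roundoff just outside [0, 1]
  structure(list(values = C, channel_labels = epoch$channel_labels),
            class = "coherence_matrix")
}

#' Electrode graph container
#'
#' An undirected simple graph on labeled electrode nodes stored as a
#' binary adjacency matrix: symmetric, zero diagonal. For 16 electrodes
#' the edge count is at most 120 = 16*15/2 and every degree at most 15.
#'
#' @param adjacency square 0/1 matrix (symmetric, zero diagonal).
#' @param node_labels node names; defaults to the matrix dimnames.
#' @return An object of class `electrode_graph`.
#' @export
electrode_graph <- function(adjacency, node_labels = rownames(adjacency)) {
  A <- as.matrix(adjacency)
  storage.mode(A) <- "double"
  if (nrow(A) != ncol(A)) cw_stop("coherwalk_data_error", "adjacency not square")
  if (!all(A %in% c(0, 1))) cw_stop("coherwalk_data_error", "adjacency not binary")
  if (!isTRUE(all.equal(A, t(A)))) {
    cw_stop("coherwalk_data_error", "adjacency not symmetric")
  }
  if (any(diag(A) != 0)) cw_stop("coherwalk_data_error", "self-loops not allowed")
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(nrow(A)))
  dimnames(A) <- list(node_labels, node_labels)
  structure(list(adjacency = A, node_labels = as.character(node_labels)),
            class = "electrode_graph")
}

#' @export
print.electrode_graph <- function(x, ...) {
  cat(sprintf("<electrode_graph> %d nodes, %d edges\n",
              nrow(x$adjacency), n_edges(x)))
  invisible(x)
}

#' Number of edges of an electrode graph
#' @param g an [electrode_graph()].
#' @return Integer edge count.
#' @export
n_edges <- function(g) as.integer(sum(g$adjacency) / 2)

#' Convert to an igraph object
#' @param g an [electrode_graph()].
#' @return An [igraph::graph] (undirected, labeled).
#' @export
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Threshold a coherence matrix into a binary synchronization graph
#'
#' Draws an edge between two electrodes when their band-averaged
#' coherence is at or above the threshold (inclusive >=; default 0.5).
#' The diagonal is ignored: a signal is always fully coherent with
#' itself, so self-loops carry no information.
#'
#' @param C a [coherence_matrix()].
#' @param cfg a [graph_config()]; only `threshold` is used.
#' @return An [electrode_graph()]. An empty graph is legal output.
#' @export
build_graph <- function(C, cfg = graph_config()) {
  stopifnot(inherits(C, "coherence_matrix"))
  A <- (C$values >= cfg$threshold) * 1
  diag(A) <- 0
  electrode_graph(A, C$channel_labels)
}
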