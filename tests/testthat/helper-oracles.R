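# Independent oracles and fixture builders used across tests.

# number of anonymous walks of length l via the closed recursion
# a(t+1, k) = a(t, k) (k - 1) + a(t, k - 1); independent of the
# package's exhaustive enumerator.
walk_count_recursion <- function(l) {
  a <- c(1, rep(0, l + 1))           # a[k+...]: index k = number of labels
  for (t in seq_len(l)) {
    b <- rep(0, l + 2)
    for (k in seq_len(t + 1)) {
      b[k] <- a[k] * (k - 1) + if (k > 1) a[k - 1] else 0
    }
    a <- b
  }
  sum(a)
}

# brute-force anonymous-walk distribution in plain R: enumerate every
# node walk recursively and accumulate its probability by pattern key.
exact_embedding_bruteforce <- function(adj, l) {
  n <- nrow(adj)
  dimnames(adj) <- NULL
  deg <- rowSums(adj)
  starts <- which(deg >= 1)
  acc <- new.env()
  walk <- function(seq_nodes, prob) {
    if (length(seq_nodes) == l + 1) {
      key <- paste(canonicalize_walk(seq_nodes), collapse = "-")
      old <- mget(key, envir = acc, ifnotfound = 0)[[1]]
      assign(key, old + prob, envir = acc)
      return(invisible())
    }
    u <- seq_nodes[length(seq_nodes)]
    for (v in which(adj[u, ] == 1)) walk(c(seq_nodes, v), prob / deg[u])
  }
  for (s in starts) walk(s, 1 / length(starts))
  unlist(as.list(acc))
}

# small named graphs
path3_graph <- function() {
  electrode_graph(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3),
                  c("A", "B", "C"))
}

complete_graph <- function(n, labels = paste0("n", seq_len(n))) {
  electrode_graph(matrix(1, n, n) - diag(n), labels)
}

single_edge_graph <- function(n = 16, labels = montage_16()) {
  A <- matrix(0, n, n)
  A[1, 2] <- A[2, 1] <- 1
  electrode_graph(A, labels)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(runif(sum(up)) < p)
  A <- A + t(A)
  if (sum(A) == 0) A[1, 2] <- A[2, 1] <- 1
  electrode_graph(A, paste0("n", seq_len(n)))
}

# write a minimal single-record EDF file byte by byte, straight from the
# format definition (fixed-width ASCII header, int16 little-endian data)
write_edf_fixture <- function(path, data, fs, labels,
                              phys_min = -200, phys_max = 200) {
  ns <- nrow(data)
  n_samp <- ncol(data)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44)
  wr(1, 8)                       # one data record
  wr(1, 8)                       # of one second
  wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)      # transducer
  for (i in seq_len(ns)) wr("uV", 8)     # dimension
  for (i in seq_len(ns)) wr(phys_min, 8)
  for (i in seq_len(ns)) wr(phys_max, 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)      # prefiltering
  for (i in seq_len(ns)) wr(n_samp, 8)   # samples per record (= fs * 1 s)
  for (i in seq_len(ns)) wr("", 32)
  gain <- (phys_max - phys_min) / (32767 - (-32768))
  for (i in seq_len(ns)) {
    dig <- round((data[i, ] - phys_min) / gain) - 32768
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
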