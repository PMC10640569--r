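# Small graph fixtures built in code.

adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  A
}

path_graph <- function(n) adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
star_graph <- function(n) adj_from_edges(n, lapply(2:n, function(i) c(1, i)))
cycle_graph <- function(n) adj_from_edges(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1)), list(c(n, 1))))
complete_graph <- function(n) matrix(1L, n, n) - diag(1L, n)

# Independent component-trace oracle: exhaustive component enumeration of
# each induced subgraph via igraph.
trace_oracle <- function(A, ord) {
  N <- nrow(A)
  t(vapply(seq_len(N), function(k) {
    keep <- setdiff(seq_len(N), ord[seq_len(k)])
    if (length(keep) == 0) return(c(0, 0))
    g <- igraph::graph_from_adjacency_matrix(A[keep, keep, drop = FALSE],
                                             mode = "undirected")
    sizes <- sort(igraph::components(g)$csize, decreasing = TRUE)
    c(sizes[1], if (length(sizes) > 1) sizes[2] else 0)
  }, numeric(2)))
}

# Direct transcription of the wPLI formula with explicit loops.
wpli_oracle <- function(coefs) {
  n_bins <- dim(coefs)[1]; n_nodes <- dim(coefs)[2]; n_obs <- dim(coefs)[3]
  out <- array(0, dim = c(n_bins, n_nodes, n_nodes))
  for (f in seq_len(n_bins)) {
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        if (i == j) next
        ims <- numeric(n_obs)
        for (o in seq_len(n_obs))
          ims[o] <- Im(coefs[f, i, o] * Conj(coefs[f, j, o]))
        den <- mean(abs(ims))
        out[f, i, j] <- if (den > 0) abs(mean(ims)) / den else 0
      }
    }
  }
  out
}

cross_spectra_from_coefs <- function(coefs, freqs = seq_len(dim(coefs)[1])) {
  structure(list(coef = coefs, freqs = freqs, fs = 2 * max(freqs) + 1,
                 n_trials = dim(coefs)[3], n_tapers = 1,
                 node_coords = NULL, subject_id = "fixture"),
            class = "cross_spectra")
}
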