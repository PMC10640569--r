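#' Attack configuration
#'
#' @param strategy one of "random", "eigenvector", "betweenness".
#' @param densities strictly increasing grid of proportional-threshold
#'   densities in (0, 1]; default 0.25% to 100% in 0.25% steps (400 values).
#' @param n_iter attack iterations per density (default 100); for targeted
#'   strategies the iterations re-randomize centrality ties only.
#' @param seed integer seed for the whole attack run.
#' @param recompute_centrality if TRUE, recompute centralities after each
#'   removal instead of ranking once on the intact thresholded graph
#'   (default FALSE: a fixed ordering).
#' @return object of class `attack_config`.
#' @export
attack_config <- function(strategy = c("random", "eigenvector", "betweenness"),
                          densities = seq(0.0025, 1, by = 0.0025),
                          n_iter = 100L, seed = 1L,
                          recompute_centrality = FALSE) {
  strategy <- match.arg(strategy)
  if (any(diff(densities) <= 0)) stop_config("densities must be strictly increasing")
  if (any(densities <= 0 | densities > 1)) stop_config("densities must lie in (0, 1]")
  if (n_iter < 1) stop_config("n_iter must be >= 1")
  structure(list(strategy = strategy, densities = densities,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 recompute_centrality = recompute_centrality),
            class = "attack_config")
}

#' Proportional thresholding of a weighted connectome
#'
#' Keeps the `m = round(density * N(N-1)/2)` largest-weight edges (rounding
#' half away from zero), with ties broken by lexicographic node-pair order,
#' and returns an unweighted graph on all N nodes (isolates allowed) as a
#' binary adjacency matrix. Zero-weight pairs are not part of the weighted
#' support and never become edges, so at density 1 the full nonzero support
#' is retained (the complete graph only when all weights are positive).
#'
#' @param conn a [connectome()] or symmetric weight matrix.
#' @param density fraction of all possible edges to retain, in (0, 1].
#' @return binary (0/1) symmetric adjacency matrix.
#' @export
proportional_threshold <- function(conn, density) {
  W <- if (inherits(conn, "connectome")) conn$W else as.matrix(conn)
  N <- nrow(W)
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  n_pairs <- N * (N - 1) / 2
  m <- round_half_away(density * n_pairs)
  if (m < 1) stop("density too low for graph size")
  iu <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[iu]
  m <- min(m, sum(w > 0))
  if (m < 1) stop("density too low for graph size")
  keep <- order(-w, iu[, 1], iu[, 2])[seq_len(m)]
  A <- matrix(0L, N, N)
  A[iu[keep, , drop = FALSE]] <- 1L
  A + t(A)
}

# Leading-eigenvector centrality of the adjacency by power iteration
# (on A + I, which shares the leading eigenvector and converges on
# bipartite graphs); absolute values; nodes off the dominant component
# decay to ~0 and fall to the end of the ranking.
eigen_centrality_power <- function(A, tol = 1e-10, max_iter = 10000L) {
  N <- nrow(A)
  if (all(A == 0)) return(rep(0, N))
  x <- rep(1 / sqrt(N), N)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    ny <- sqrt(sum(y^2))
    y <- y / ny
    if (max(abs(y - x)) < tol) { x <- y; break }
    x <- y
  }
  abs(x)
}

#' Node removal order under an attack strategy
#'
#' Random strategy: a uniform random permutation. Centrality strategies:
#' nodes ordered by centrality computed once on the intact thresholded
#' graph, descending, with ties permuted uniformly at random (centralities
#' are rounded to 8 significant digits before tie detection so that
#' symmetric nodes tie exactly). Betweenness is unweighted shortest-path
#' betweenness; eigenvector is the leading eigenvector of the adjacency
#' (absolute values, power iteration).
#'
#' Uses the current RNG stream; seed outside for reproducibility.
#'
#' @param A binary adjacency matrix from [proportional_threshold()].
#' @param strategy "random", "eigenvector" or "betweenness".
#' @return integer permutation of `1:N` (removal order).
#' @export
rank_nodes <- function(A, strategy = c("random", "eigenvector", "betweenness")) {
  strategy <- match.arg(strategy)
  N <- nrow(A)
  if (N < 1) stop("graph must have at least one node")
  if (strategy == "random") return(sample.int(N))
  cent <- node_centrality(A, strategy)
  order(-cent, runif(N))
}

# Centrality vector used for ranking, tie-rounded.
node_centrality <- function(A, strategy) {
  cent <- if (strategy == "betweenness") {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    igraph::betweenness(g, directed = FALSE)
  } else {
    eigen_centrality_power(A)
  }
  signif(cent, 8)
}

#' Component sizes along a removal order
#'
#' After removing the first `k` nodes of `order`, records the sizes of the
#' largest (`S1`) and second-largest (`S2`) connected components of the
#' induced subgraph, for `k = 1..N`; `S2 = 0` when fewer than two
#' components remain.
#'
#' @param A binary adjacency matrix.
#' @param order integer permutation of `1:N`.
#' @return data.frame with columns `k`, `S1`, `S2`.
#' @export
component_trace <- function(A, order) {
  N <- nrow(A)
  if (length(order) != N || !setequal(order, seq_len(N)))
    stop("order must be a permutation of the graph's nodes")
  nbrs <- adjacency_list(A)
  tr <- trace_components_cpp(nbrs, as.integer(order))
  data.frame(k = seq_len(N), S1 = tr[, 1], S2 = tr[, 2])
}

adjacency_list <- function(A) {
  lapply(seq_len(nrow(A)), function(v) which(A[v, ] != 0))
}

#' Percolation point of a component trace
#'
#' The smallest removal step `k*` at which the second-largest component
#' attains its maximum size, as a fraction of nodes removed (`k*/N`). An
#' all-zero `S2` trace (a graph that never fragments into two components)
#' degenerates to `1/N`.
#'
#' @param trace data.frame from [component_trace()] (needs column `S2`).
#' @return percolation point in `{1/N, ..., 1}`.
#' @export
percolation_point <- function(trace) {
  S2 <- trace$S2
  N <- length(S2)
  if (N < 1) stop("trace must have length >= 1")
  which.max(S2) / N
}

#' Iterated attacks across a density grid
#'
#' For each density: threshold once, then run `n_iter` independent
#' rank/trace/percolation iterations, recording the mean percolation point
#' and, per iteration, the set of nodes removed strictly before the
#' percolation step ("prior to failure"). Targeted strategies with no
#' centrality ties are deterministic, so a single iteration is run and
#' reused. Densities whose edge count rounds to zero are recorded as `NA`.
#'
#' @param conn a [connectome()].
#' @param cfg an [attack_config()].
#' @return object of class `percolation_function`: `subject_id`, `strategy`,
#'   `densities`, `p` (mean percolation point per density), `prefail_frac`
#'   (densities x nodes matrix: fraction of iterations each node was removed
#'   before failure), `n_iter`.
#' @export
run_attacks <- function(conn, cfg) {
  stopifnot(inherits(cfg, "attack_config"))
  W <- if (inherits(conn, "connectome")) conn$W else as.matrix(conn)
  N <- nrow(W)
  D <- length(cfg$densities)
  p <- rep(NA_real_, D)
  prefail <- matrix(NA_real_, D, N)
  with_seed(cfg$seed, {
    for (di in seq_len(D)) {
      A <- tryCatch(proportional_threshold(W, cfg$densities[di]),
                    error = function(e) NULL)
      if (is.null(A)) next
      nbrs <- adjacency_list(A)
      if (cfg$strategy == "random") {
        orders <- replicate(cfg$n_iter, sample.int(N))
      } else if (cfg$recompute_centrality) {
        orders <- replicate(cfg$n_iter, rank_nodes_recompute(A, cfg$strategy))
      } else {
        cent <- node_centrality(A, cfg$strategy)
        n_eff <- if (anyDuplicated(cent)) cfg$n_iter else 1L
        orders <- vapply(seq_len(n_eff),
                         function(i) order(-cent, runif(N)),
                         integer(N))
      }
      orders <- matrix(as.integer(orders), nrow = N)
      res <- attack_batch_cpp(nbrs, orders)
      p[di] <- mean(res$perc)
      prefail[di, ] <- res$prefail / ncol(orders)
    }
  })
  structure(list(subject_id = if (inherits(conn, "connectome")) conn$subject_id else "s1",
                 strategy = cfg$strategy, densities = cfg$densities,
                 p = p, prefail_frac = prefail, n_iter = cfg$n_iter),
            class = "percolation_function")
}

# Adaptive variant: re-rank on the shrinking graph after each removal.
rank_nodes_recompute <- function(A, strategy) {
  N <- nrow(A)
  alive <- seq_len(N)
  ord <- integer(N)
  for (k in seq_len(N)) {
    cent <- node_centrality(A[alive, alive, drop = FALSE], strategy)
    pick <- order(-cent, runif(length(alive)))[1]
    ord[k] <- alive[pick]
    alive <- alive[-pick]
  }
  ord
}

#' Long-format percolation results for a cohort
#'
#' @param pfs list of `percolation_function` objects (one per subject).
#' @return data.frame: subject_id, strategy, density, mean_percolation_point.
#' @export
percolation_table <- function(pfs) {
  do.call(rbind, lapply(pfs, function(pf) {
    data.frame(subject_id = pf$subject_id, strategy = pf$strategy,
               density = pf$densities, mean_percolation_point = pf$p,
               stringsAsFactors = FALSE)
  }))
}

#' Removal-frequency map across subjects
#'
#' For a given density and subject subset, the fraction of subjects for
#' which each node was removed prior to network failure in at least 50% of
#' attack iterations (majority vote across iterations).
#'
#' @param pfs list of `percolation_function` objects.
#' @param density a density present in the computed grid.
#' @param subjects character vector of subject ids to include (default all).
#' @return data.frame: node, fraction (in \[0, 1\]).
#' @export
removal_frequency_map <- function(pfs, density, subjects = NULL) {
  ids <- vapply(pfs, function(pf) pf$subject_id, character(1))
  if (is.null(subjects)) subjects <- ids
  sel <- which(ids %in% subjects)
  if (length(sel) == 0) stop("empty subject subset")
  di <- match(TRUE, abs(pfs[[sel[1]]]$densities - density) < 1e-9)
  if (is.na(di)) stop("density not in the computed grid")
  votes <- vapply(pfs[sel],
                  function(pf) as.numeric(pf$prefail_frac[di, ] >= 0.5),
                  numeric(ncol(pfs[[sel[1]]]$prefail_frac)))
  data.frame(node = seq_len(nrow(votes)), fraction = rowMeans(votes))
}
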