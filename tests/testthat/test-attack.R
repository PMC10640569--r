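test_that("proportional thresholding keeps the heaviest edges with exact counts", {
  # 4 nodes, distinct weights, m = 3 -> exactly the 3 heaviest pairs
  W <- matrix(0, 4, 4)
  W[1, 2] <- 10; W[1, 3] <- 8; W[1, 4] <- 1
  W[2, 3] <- 7; W[2, 4] <- 2; W[3, 4] <- 3
  W <- W + t(W)
  A <- proportional_threshold(W, 3 / 6)
  expect_equal(sum(A) / 2, 3)
  expect_true(A[1, 2] == 1 && A[1, 3] == 1 && A[2, 3] == 1)

  # counting oracle on a random 20-node matrix with positive weights
  set.seed(1)
  Wr <- matrix(0, 20, 20)
  Wr[upper.tri(Wr)] <- runif(190, 0.01, 1)
  Wr <- Wr + t(Wr)
  for (dens in c(0.05, 0.17, 0.5, 0.99)) {
    A <- proportional_threshold(Wr, dens)
    expect_equal(sum(A) / 2, round(dens * 190))
    expect_equal(A, t(A))
  }
  # density 1 keeps the full positive support (complete graph here)
  expect_equal(sum(proportional_threshold(Wr, 1)) / 2, 190)
  # zero-weight pairs never become edges
  expect_equal(sum(proportional_threshold(W, 1)) / 2, 6)
  expect_error(proportional_threshold(Wr, 1e-6), "density too low")
})

test_that("removal ranking follows centrality with uniform tie randomization", {
  withr::local_seed(1)
  # star: the hub leads under both centralities
  A <- star_graph(5)
  expect_equal(rank_nodes(A, "betweenness")[1], 1)
  expect_equal(rank_nodes(A, "eigenvector")[1], 1)

  # path a-b-c-d: b and c tie on betweenness; roughly half the draws put b first
  P <- path_graph(4)
  firsts <- replicate(1000, rank_nodes(P, "betweenness")[1])
  expect_true(all(firsts %in% c(2, 3)))
  expect_gt(mean(firsts == 2), 0.45)
  expect_lt(mean(firsts == 2), 0.55)

  # cycle: full symmetry, every node can lead
  C <- cycle_graph(5)
  f_ec <- replicate(500, rank_nodes(C, "eigenvector")[1])
  f_bc <- replicate(500, rank_nodes(C, "betweenness")[1])
  expect_setequal(unique(f_ec), 1:5)
  expect_setequal(unique(f_bc), 1:5)
  # random strategy: a uniform permutation
  expect_setequal(rank_nodes(C, "random"), 1:5)
})

test_that("component traces match hand enumeration and the igraph oracle", {
  # path a-b-c-d removed in order b, c, a, d
  tr <- component_trace(path_graph(4), c(2, 3, 1, 4))
  expect_equal(tr$S1, c(2, 1, 1, 0))
  expect_equal(tr$S2, c(1, 1, 0, 0))

  # complete graphs never fragment
  trk <- component_trace(complete_graph(5), 1:5)
  expect_true(all(trk$S2 == 0))
  expect_equal(trk$S1, 4:0)

  # random graphs and orders against exhaustive component enumeration
  set.seed(2)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < 0.4)
    A <- A + t(A)
    ord <- sample(n)
    tr <- component_trace(A, ord)
    orc <- trace_oracle(A, ord)
    expect_equal(tr$S1, orc[, 1])
    expect_equal(tr$S2, orc[, 2])
  }
})

test_that("percolation point is the first peak of S2, with degenerate conventions", {
  expect_equal(percolation_point(component_trace(path_graph(4), c(2, 3, 1, 4))),
               0.25)
  # all-zero S2 trace degenerates to 1/N
  expect_equal(percolation_point(component_trace(complete_graph(5), 1:5)), 0.2)
  # two triangles joined by a bridge: removing a bridge endpoint first
  # immediately yields the maximal second component
  A <- adj_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                              c(4, 5), c(4, 6), c(5, 6), c(3, 4)))
  expect_equal(percolation_point(component_trace(A, c(3, 1, 2, 4, 5, 6))), 1 / 6)
  # invariant to graph isomorphism
  perm <- c(4, 1, 6, 2, 5, 3)
  Ap <- A[perm, perm]
  ordp <- match(c(3, 1, 2, 4, 5, 6), perm)
  expect_equal(percolation_point(component_trace(Ap, ordp)), 1 / 6)
})

test_that("iterated attacks are deterministic given a seed and collapse without ties", {
  # fixture with all-distinct betweenness values: iterations cannot differ
  edges <- list(c(1, 2), c(1, 5), c(1, 6), c(1, 7), c(2, 3), c(2, 4),
                c(2, 6), c(2, 7), c(3, 4), c(3, 5), c(3, 6), c(3, 7),
                c(4, 7), c(5, 6))
  A <- adj_from_edges(7, edges)
  W <- A * 1.0  # density 1 retains exactly this support
  cfg <- attack_config("betweenness", densities = 1, n_iter = 50, seed = 11)
  pf1 <- run_attacks(connectome(W), cfg)
  pf2 <- run_attacks(connectome(W), cfg)
  expect_identical(pf1, pf2)
  expect_true(all(pf1$prefail_frac %in% c(0, 1)))
  pf_single <- run_attacks(connectome(W),
                           attack_config("betweenness", densities = 1,
                                         n_iter = 1, seed = 12))
  expect_equal(pf_single$p, pf1$p)

  set.seed(3)
  Wr <- matrix(0, 12, 12)
  Wr[upper.tri(Wr)] <- runif(66, 0.5, 1)
  Wr <- Wr + t(Wr)
  cfg_r <- attack_config("random", densities = c(0.2, 0.5), n_iter = 30,
                         seed = 12)
  expect_identical(run_attacks(connectome(Wr), cfg_r),
                   run_attacks(connectome(Wr), cfg_r))
})

test_that("random-attack mean percolation points are stable across seeds", {
  set.seed(4)
  n <- 30
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < 0.3)
  W <- (A + t(A)) * 1.0
  means <- vapply(1:10, function(s) {
    cfg <- attack_config("random", densities = 1, n_iter = 100, seed = s)
    run_attacks(connectome(W), cfg)$p
  }, numeric(1))
  expect_lt(sd(means), 0.05)
})

test_that("eigenvector attacks dismantle hub-and-spoke graphs no later than random", {
  # two stars joined at their hubs: EC targets the hubs immediately
  A <- adj_from_edges(12, c(lapply(2:6, function(i) c(1, i)),
                            lapply(8:12, function(i) c(7, i)),
                            list(c(1, 7))))
  W <- A * 1.0
  p_ec <- run_attacks(connectome(W), attack_config("eigenvector", densities = 1,
                                                   n_iter = 50, seed = 5))$p
  p_rand <- run_attacks(connectome(W), attack_config("random", densities = 1,
                                                     n_iter = 50, seed = 6))$p
  expect_lte(p_ec, p_rand)
})

test_that("removal-frequency maps aggregate pre-failure sets across subjects", {
  # deterministic single subject: fractions are exactly the pre-failure set
  W <- matrix(0, 6, 6)
  W[1, 2] <- 10; W[1, 3] <- 9; W[2, 3] <- 8
  W[4, 5] <- 7; W[4, 6] <- 6; W[5, 6] <- 5
  W[3, 4] <- 11
  W <- W + t(W)
  cfg <- attack_config("betweenness", densities = 1, n_iter = 20, seed = 7)
  pf <- run_attacks(connectome(W, subject_id = "a"), cfg)
  m1 <- removal_frequency_map(list(pf), 1)
  expect_true(all(m1$fraction %in% c(0, 1)))

  pfb <- pf
  pfb$subject_id <- "b"
  pfb$prefail_frac <- 1 - pf$prefail_frac  # disjoint pre-failure set
  m2 <- removal_frequency_map(list(pf, pfb), 1)
  expect_true(all(m2$fraction == 0.5))
  expect_error(removal_frequency_map(list(pf), 1, subjects = "zzz"), "empty")
})
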