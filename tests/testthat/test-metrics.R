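test_that("worked small-graph values match hand evaluation of the formulas", {
  # triangle with a pendant node: 2t = 6 triples closed of 10
  tri_pend <- binarize_full(mat_from_edges(
    4, list(c(1, 2), c(1, 3), c(2, 3), c(3, 4))
  ))
  expect_equal(graph_transitivity(tri_pend), 0.6)

  p3 <- binarize_full(path_graph(3))
  expect_equal(global_efficiency(p3), 5 / 6)
  expect_equal(as.numeric(characteristic_path_length(p3)), 4 / 3)

  p4 <- binarize_full(path_graph(4))
  expect_equal(graph_assortativity(p4), -0.5)

  two_k3 <- mat_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                   c(4, 5), c(4, 6), c(5, 6)))
  expect_equal(modularity_of_partition(binarize_full(two_k3), c(1, 1, 1, 2, 2, 2)),
               0.5)

  cyc4 <- binarize_full(mat_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(1, 4))))
  expect_equal(as.numeric(characteristic_path_length(cyc4)), 4 / 3)
})

test_that("density is the fraction of possible connections", {
  expect_equal(graph_density(graph_from_matrix(complete_graph(4))), 1)
  expect_equal(graph_density(graph_from_matrix(connectivity_matrix(matrix(0, 5, 5)))), 0)
  set.seed(1)
  m <- matrix(0, 84, 84)
  m[sample(which(upper.tri(m)), 2440)] <- 1
  m <- m + t(m)
  expect_equal(graph_density(graph_from_matrix(connectivity_matrix(m))),
               2440 / 3486)
})

test_that("assortativity is undefined on degree-regular graphs", {
  cyc5 <- binarize_full(mat_from_edges(5, list(c(1, 2), c(2, 3), c(3, 4),
                                               c(4, 5), c(1, 5))))
  expect_warning(r <- graph_assortativity(cyc5), "undefined")
  expect_true(is.na(r))
  two_k3 <- binarize_full(mat_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3),
                                                 c(4, 5), c(4, 6), c(5, 6))))
  expect_warning(expect_true(is.na(graph_assortativity(two_k3))))
  empty <- binarize_full(connectivity_matrix(matrix(0, 3, 3)))
  expect_warning(expect_true(is.na(graph_assortativity(empty))), "empty")
})

test_that("transitivity and efficiency hit their boundary cases", {
  k4 <- binarize_full(complete_graph(4))
  expect_equal(graph_transitivity(k4), 1)
  star <- binarize_full(mat_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))))
  expect_equal(graph_transitivity(star), 0)
  expect_equal(global_efficiency(binarize_full(complete_graph(6))), 1)
  expect_equal(global_efficiency(binarize_full(connectivity_matrix(matrix(0, 4, 4)))), 0)
})

test_that("CPL averages over reachable pairs only and flags exclusions", {
  k3_iso <- binarize_full(mat_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3))))
  expect_warning(cpl <- characteristic_path_length(k3_iso), "unreachable")
  expect_equal(as.numeric(cpl), 1)
  expect_equal(attr(cpl, "n_unreachable"), 3)
  expect_equal(as.numeric(characteristic_path_length(binarize_full(complete_graph(5)))), 1)
})

test_that("partition modularity obeys its contract", {
  g <- binarize_full(two_block_matrix())
  expect_equal(modularity_of_partition(g, rep(1, g$q)), 0)
  expect_error(modularity_of_partition(g, c(1, 2)),
               class = "connectoms_invalid_partition")
  # agrees with igraph on arbitrary partitions
  set.seed(9)
  ig <- igraph::graph_from_adjacency_matrix(adj_of(g), mode = "undirected")
  for (k in 1:10) {
    mem <- sample(3, g$q, replace = TRUE)
    expect_equal(modularity_of_partition(g, mem),
                 igraph::modularity(ig, mem), tolerance = 1e-12)
  }
})

test_that("best-partition modularity recovers planted structure", {
  two_k5 <- connectivity_matrix({
    m <- matrix(0, 10, 10)
    m[1:5, 1:5] <- 1
    m[6:10, 6:10] <- 1
    diag(m) <- 0
    m
  })
  res <- graph_modularity(binarize_full(two_k5), exact_max_q = 0)
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$membership)), 2)
  expect_equal(res$membership[1:5], rep(res$membership[1], 5))

  # complete graph has no modular structure
  k6 <- graph_modularity(binarize_full(complete_graph(6)))
  expect_lte(k6$Q, 1e-10)
  expect_gte(k6$Q, 0)

  # q = 84 planted 4-block graph: found Q within 0.05 of the planted Q or higher
  set.seed(31)
  q <- 84
  block <- sort(rep_len(1:4, q))
  m <- matrix(0, q, q)
  for (i in 1:(q - 1)) for (j in (i + 1):q) {
    p <- if (block[i] == block[j]) 0.7 else 0.05
    if (runif(1) < p) m[i, j] <- m[j, i] <- 1
  }
  b <- binarize_full(connectivity_matrix(m))
  planted_q <- modularity_of_partition(b, block)
  found <- graph_modularity(b)
  expect_gte(found$Q, planted_q - 0.05)
})

test_that("all six metrics agree with brute-force oracles on random small graphs", {
  # deeper 200-graph sweep lives in the acceptance suite
  set.seed(123)
  for (s in 1:50) {
    q <- sample(4:8, 1)
    b <- binarize_full(random_connectivity(q, p = runif(1, 0.3, 0.8),
                                           seed = 5000 + s))
    if (nrow(b$edges) == 0) next
    expect_equal(graph_transitivity(b), oracle_transitivity(b), tolerance = 1e-10)
    expect_equal(global_efficiency(b), oracle_efficiency(b), tolerance = 1e-10)
    r <- suppressWarnings(graph_assortativity(b))
    ro <- oracle_assortativity(b)
    if (!is.na(r) && !is.na(ro)) expect_equal(r, ro, tolerance = 1e-10)
    expect_equal(graph_modularity(b)$Q, max(0, oracle_best_modularity(b)),
                 tolerance = 1e-10)
  }
})

test_that("efficiency dominates inverse path length on connected graphs", {
  for (s in 1:30) {
    b <- binarize_full(random_connectivity(10, 0.6, seed = 700 + s))
    d <- shortest_path_lengths(b)
    if (any(!is.finite(d))) next
    expect_gte(global_efficiency(b),
               1 / as.numeric(characteristic_path_length(b)) - 1e-12)
  }
})

test_that("adding an edge never lowers density nor lengthens any path", {
  for (s in 1:15) {
    m <- random_connectivity(9, 0.3, seed = 800 + s)
    g <- graph_from_matrix(m)
    zero_pairs <- which(upper.tri(m) & m == 0, arr.ind = TRUE)
    if (nrow(zero_pairs) == 0) next
    pick <- zero_pairs[1, ]
    m2 <- unclass(m)
    m2[pick[1], pick[2]] <- m2[pick[2], pick[1]] <- 1
    g2 <- graph_from_matrix(connectivity_matrix(m2))
    expect_gte(graph_density(g2), graph_density(g))
    d1 <- shortest_path_lengths(proportional_threshold(g, 1))
    d2 <- shortest_path_lengths(proportional_threshold(g2, 1))
    expect_true(all(d2 <= d1 + 1e-12))
  }
})

test_that("compute_metrics composes the per-metric operations faithfully", {
  k84 <- complete_graph(84)
  v <- suppressWarnings(compute_metrics(k84, tau = 1))
  expect_equal(v$D, 1)
  expect_equal(v$T, 1)
  expect_equal(v$Eg, 1)
  expect_equal(v$CPL, 1)
  expect_lte(v$Q, 1e-10)
  expect_true(is.na(v$r)) # regular graph

  zeros <- connectivity_matrix(matrix(0, 10, 10))
  vz <- suppressWarnings(compute_metrics(zeros, tau = 0.5))
  expect_equal(vz$D, 0)
  expect_equal(vz$T, 0)
  expect_equal(vz$Eg, 0)
  expect_true(is.na(vz$r) && is.na(vz$Q) && is.na(vz$CPL))

  m <- two_block_matrix()
  v2 <- compute_metrics(m, tau = 0.35, seed = 4L)
  g <- graph_from_matrix(m)
  b <- proportional_threshold(g, 0.35)
  expect_equal(v2$D, graph_density(g))
  expect_equal(v2$r, graph_assortativity(b))
  expect_equal(v2$T, graph_transitivity(b))
  expect_equal(v2$Eg, global_efficiency(b))
  expect_equal(v2$Q, graph_modularity(b, seed = 4L)$Q)
  expect_equal(v2$CPL, as.numeric(characteristic_path_length(b)))
})
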