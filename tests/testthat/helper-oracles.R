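# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately share no code with the package internals:
# distances by hand-rolled BFS / Floyd-Warshall, triangles by triple
# enumeration, modularity from the spectral-form definition over exhaustive
# partitions.

mat_from_edges <- function(q, edges, weights = NULL) {
  m <- matrix(0, q, q)
  if (length(edges) > 0) {
    if (is.null(weights)) weights <- rep(1, length(edges))
    for (k in seq_along(edges)) {
      e <- edges[[k]]
      m[e[1], e[2]] <- weights[k]
      m[e[2], e[1]] <- weights[k]
    }
  }
  connectivity_matrix(m)
}

path_graph <- function(n) {
  mat_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

complete_graph <- function(n) {
  m <- matrix(1, n, n)
  diag(m) <- 0
  connectivity_matrix(m)
}

binarize_full <- function(m) proportional_threshold(graph_from_matrix(m), 1)

random_connectivity <- function(q, p = 0.4, seed = 1, max_w = 9) {
  set.seed(seed)
  m <- matrix(0, q, q)
  ut <- upper.tri(m)
  on <- runif(sum(ut)) < p
  w <- ifelse(on, sample(max_w, sum(ut), replace = TRUE), 0)
  m[ut] <- w
  m <- m + t(m)
  connectivity_matrix(m)
}

adj_of <- function(g) {
  A <- matrix(0, g$q, g$q)
  if (nrow(g$edges) > 0) {
    A[cbind(g$edges$i, g$edges$j)] <- 1
    A[cbind(g$edges$j, g$edges$i)] <- 1
  }
  A
}

# Breadth-first search from one source; Inf for unreachable nodes.
oracle_bfs <- function(A, src) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] > 0 & !is.finite(dist))
      dist[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

oracle_distances_bfs <- function(g) {
  A <- adj_of(g)
  t(vapply(seq_len(g$q), function(s) oracle_bfs(A, s), numeric(g$q)))
}

oracle_distances_floyd <- function(g) {
  A <- adj_of(g)
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Triangles and triples by exhaustive triple enumeration.
oracle_triangle_total <- function(g) {
  A <- adj_of(g)
  n <- nrow(A)
  if (n < 3) return(0)
  tri <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (A[i, j] && A[j, k] && A[i, k]) tri <- tri + 1
  }
  tri
}

oracle_transitivity <- function(g) {
  A <- adj_of(g)
  k <- rowSums(A)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  6 * oracle_triangle_total(g) / denom
}

oracle_efficiency <- function(g) {
  d <- oracle_distances_bfs(g)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (g$q * (g$q - 1))
}

oracle_cpl_connected <- function(g) {
  d <- oracle_distances_bfs(g)
  diag(d) <- NA
  mean(rowMeans(d, na.rm = TRUE))
}

# Assortativity as the Pearson correlation of endpoint degrees over the
# edge list traversed in both directions (equivalent closed form).
oracle_assortativity <- function(g) {
  k <- rowSums(adj_of(g))
  e <- g$edges
  x <- c(k[e$i], k[e$j])
  y <- c(k[e$j], k[e$i])
  suppressWarnings(stats::cor(x, y))
}

# Modularity from the adjacency form Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m)
# delta(c_i, c_j); exhaustive maximum over all set partitions.
oracle_partition_q <- function(g, mem) {
  A <- adj_of(g)
  k <- rowSums(A)
  two_m <- sum(k)
  same <- outer(mem, mem, "==")
  sum((A - outer(k, k) / two_m) * same) / two_m
}

oracle_all_partitions <- function(n) {
  out <- list()
  grow <- function(a) {
    k <- length(a) + 1
    if (k > n) {
      out[[length(out) + 1]] <<- a
      return()
    }
    for (v in seq_len(max(a, 0) + 1)) grow(c(a, v))
  }
  grow(integer(0))
  out
}

oracle_best_modularity <- function(g) {
  parts <- oracle_all_partitions(g$q)
  max(vapply(parts, function(p) oracle_partition_q(g, p), numeric(1)))
}

# A deterministic two-block planted matrix for self-consistency checks.
two_block_matrix <- function(q = 20, seed = 5) {
  set.seed(seed)
  block <- rep(1:2, each = q / 2)
  m <- matrix(0, q, q)
  for (i in 1:(q - 1)) for (j in (i + 1):q) {
    p <- if (block[i] == block[j]) 0.8 else 0.2
    if (runif(1) < p) m[i, j] <- m[j, i] <- sample(20, 1)
  }
  connectivity_matrix(m)
}
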