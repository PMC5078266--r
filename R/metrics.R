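#' Graph density of a weighted connectome graph
#'
#' Ratio of effective connections to possible connections,
#' `D = l / ((q^2 - q)/2)`. Density is the one metric computed on the
#' pre-threshold weighted graph: thresholding fixes the binary edge count, so
#' only the weighted support carries between-subject density information.
#'
#' @param g A `weighted_graph` (a `binary_graph` is also accepted, giving the
#'   binarized density).
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(g) {
  stopifnot(inherits(g, c("weighted_graph", "binary_graph")))
  nrow(g$edges) / ((g$q^2 - g$q) / 2)
}

#' Degree assortativity of a binary graph
#'
#' Newman's correlation coefficient between the degrees at the two ends of
#' an edge, each edge counted once:
#' \deqn{r = \frac{l^{-1}\sum_e k_i k_j - [l^{-1}\sum_e \frac12(k_i+k_j)]^2}
#'            {l^{-1}\sum_e \frac12(k_i^2+k_j^2) - [l^{-1}\sum_e \frac12(k_i+k_j)]^2}}
#' Degree-regular graphs (zero denominator) have no defined value and return
#' `NA` with a warning; negative values mean hubs preferentially attach to
#' low-degree nodes, the signature of biological networks.
#'
#' @param g A `binary_graph`.
#' @return Assortativity in `[-1, 1]`, or `NA` when undefined.
#' @export
graph_assortativity <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  e <- g$edges
  l <- nrow(e)
  if (l == 0) {
    warn("Assortativity undefined on an empty graph.")
    return(NA_real_)
  }
  k <- degrees(g)
  ki <- k[e$i]; kj <- k[e$j]
  m1 <- mean((ki + kj) / 2)
  num <- mean(ki * kj) - m1^2
  den <- mean((ki^2 + kj^2) / 2) - m1^2
  if (abs(den) < 1e-12) {
    warn("Assortativity undefined: zero degree variance over edge endpoints.")
    return(NA_real_)
  }
  num / den
}

#' Transitivity of a binary graph
#'
#' Ratio of (closed) triangles to connected triples,
#' `T = sum(2 t_i) / sum(k_i (k_i - 1))`. Graphs with no node of degree
#' `>= 2` have no triples; `0` is returned.
#'
#' @param g A `binary_graph`.
#' @return Transitivity in `[0, 1]`.
#' @export
graph_transitivity <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  k <- degrees(g)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  sum(2 * triangle_counts(g)) / denom
}

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest path length,
#' `Eg = (1/q) sum_i [ sum_{j != i} 1/d_ij ] / (q - 1)`; disconnected pairs
#' contribute `1/Inf = 0`, so efficiency is always finite.
#'
#' @param g A `binary_graph`.
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  mean(rowSums(inv) / (g$q - 1))
}

#' Characteristic path length of a binary graph
#'
#' Mean shortest path length, `CPL = (1/q) sum_i L_i` with `L_i` the average
#' distance from node `i` to the other nodes. On disconnected graphs,
#' unreachable pairs are excluded from each `L_i` (the average runs over
#' reachable nodes only), isolated nodes are excluded from the outer mean,
#' and the count of excluded pairs is attached as the `n_unreachable`
#' attribute with a warning. A graph with no finite off-diagonal distance
#' returns `NA`.
#'
#' @param g A `binary_graph`.
#' @return CPL (`>= 1` on a non-empty graph), with attribute
#'   `n_unreachable` = number of unordered unreachable pairs.
#' @export
characteristic_path_length <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  d <- shortest_path_lengths(g)
  diag(d) <- NA
  finite <- is.finite(d)
  n_unreach <- sum(!finite & !is.na(d)) / 2
  Li <- vapply(seq_len(g$q), function(i) {
    di <- d[i, ][finite[i, ]]
    if (length(di) == 0) NA_real_ else mean(di)
  }, numeric(1))
  if (all(is.na(Li))) {
    warn("CPL undefined: graph has no connected pair.")
    return(structure(NA_real_, n_unreachable = n_unreach))
  }
  if (n_unreach > 0) {
    warn(sprintf("CPL computed over reachable pairs only (%d unreachable pairs excluded).",
                 n_unreach))
  }
  structure(mean(Li, na.rm = TRUE), n_unreachable = n_unreach)
}

#' Modularity of a given partition
#'
#' Newman--Girvan modularity `Q = sum_u [ e_uu - a_u^2 ]`, where `e_uu` is
#' the fraction of edges inside module `u` and `a_u` the fraction of edge
#' endpoints in `u` (edges crossing between two modules contribute half to
#' each module's row of the symmetric `e` matrix).
#'
#' @param g A `binary_graph`.
#' @param membership Integer/character vector assigning each node to exactly
#'   one module.
#' @return Modularity `Q <= 1`.
#' @export
modularity_of_partition <- function(g, membership) {
  stopifnot(inherits(g, "binary_graph"))
  if (length(membership) != g$q || anyNA(membership)) {
    abort("`membership` must assign every node to a module.",
          class = "connectoms_invalid_partition")
  }
  mem <- as.integer(factor(membership))
  e <- g$edges
  m <- nrow(e)
  if (m == 0) {
    warn("Modularity undefined on an empty graph.")
    return(NA_real_)
  }
  k <- degrees(g)
  e_within <- tapply(mem[e$i] == mem[e$j], mem[e$i], sum)
  e_uu <- rep(0, max(mem))
  e_uu[as.integer(names(e_within))] <- e_within / m
  a_u <- tapply(k, mem, sum) / (2 * m)
  sum(e_uu - a_u^2)
}

# Run code with the RNG set to `seed`, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# All set partitions of n items as membership vectors (restricted growth
# strings); Bell(8) = 4140, so exhaustive search is cheap for q <= 8.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(a, k) {
    if (k > n) {
      out[[length(out) + 1]] <<- a
      return()
    }
    top <- if (k == 1) 0L else max(a[seq_len(k - 1)])
    for (v in seq_len(top + 1L)) {
      a[k] <- v
      recurse(a, k + 1L)
    }
  }
  recurse(integer(n), 1L)
  out
}

#' Best-partition modularity of a binary graph
#'
#' Finds a node partition maximizing Newman--Girvan modularity and returns
#' its `Q` (evaluated by [modularity_of_partition()]). For `q <=
#' exact_max_q` the optimum is found by exhaustive search over all set
#' partitions; beyond that, greedy multi-level (Louvain) optimization is run
#' `n_restarts` times from seeded random states and the best partition kept.
#' The result never falls below the trivial single-module partition
#' (`Q = 0`).
#'
#' @param g A `binary_graph` with at least one edge.
#' @param n_restarts Louvain restarts (default 10).
#' @param exact_max_q Largest `q` for which the search is exhaustive
#'   (default 8).
#' @param seed Seed for the restart streams; the caller's RNG state is
#'   preserved.
#' @return List with `Q` and `membership` (integer module labels). Empty
#'   graph: `Q = NA` with a warning.
#' @export
graph_modularity <- function(g, n_restarts = 10, exact_max_q = 8, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"))
  if (nrow(g$edges) == 0) {
    warn("Modularity undefined on an empty graph.")
    return(list(Q = NA_real_, membership = rep(1L, g$q)))
  }
  if (g$q <= exact_max_q) {
    parts <- enumerate_partitions(g$q)
    qs <- vapply(parts, function(p) modularity_of_partition(g, p), numeric(1))
    best <- which.max(qs)
    Q <- qs[best]
    mem <- parts[[best]]
  } else {
    ig <- as_igraph(g)
    Q <- -Inf
    mem <- rep(1L, g$q)
    for (r in seq_len(n_restarts)) {
      cl <- with_local_seed(seed + r, igraph::cluster_louvain(ig))
      cand <- as.integer(igraph::membership(cl))
      qc <- modularity_of_partition(g, cand)
      if (qc > Q) {
        Q <- qc
        mem <- cand
      }
    }
  }
  if (Q < 0) { # never worse than the trivial single-module partition
    Q <- 0
    mem <- rep(1L, g$q)
  }
  list(Q = Q, membership = mem)
}

#' Compute the six global metrics for one subject
#'
#' Density is measured on the weighted graph; assortativity, transitivity,
#' global efficiency, modularity and characteristic path length on the
#' binarized graph obtained by [proportional_threshold()] at `tau`.
#'
#' @param m A [connectivity_matrix()].
#' @param tau Proportional threshold in `[0, 1]` (default 0.35).
#' @param n_restarts,seed Passed to [graph_modularity()].
#' @return One-row tibble with columns `D`, `r`, `T`, `Eg`, `Q`, `CPL`
#'   (undefined values as `NA`).
#' @export
compute_metrics <- function(m, tau = 0.35, n_restarts = 10, seed = 1L) {
  g <- graph_from_matrix(m)
  b <- proportional_threshold(g, tau)
  empty <- nrow(b$edges) == 0
  cpl <- if (empty) NA_real_ else characteristic_path_length(b)
  tibble(
    D = graph_density(g),
    r = if (empty) NA_real_ else graph_assortativity(b),
    T = graph_transitivity(b),
    Eg = global_efficiency(b),
    Q = if (empty) NA_real_ else graph_modularity(b, n_restarts = n_restarts,
                                                  seed = seed)$Q,
    CPL = as.numeric(cpl)
  )
}

#' Compute the metric table for a whole cohort
#'
#' @param cohort Cohort tibble (`subject_id`, `group`, `matrix` list-column)
#'   as produced by [sample_cohort()] or [read_cohort_manifest()].
#' @param tau Proportional threshold (default 0.35).
#' @param n_restarts,seed Passed to [graph_modularity()].
#' @return Tidy metric table: `subject_id`, `group`, `D`, `r`, `T`, `Eg`,
#'   `Q`, `CPL`.
#' @export
#'
#' @examples
#' cohort <- sample_cohort(cohort_config(
#'   q = 30, f = 20000, n_per_group = c(HC = 3, SP = 3), seed = 7
#' ))
#' connectome_metrics(cohort, tau = 0.35)
connectome_metrics <- function(cohort, tau = 0.35, n_restarts = 10, seed = 1L) {
  stopifnot(all(c("subject_id", "group", "matrix") %in% names(cohort)))
  rows <- purrr::map(cohort$matrix, compute_metrics, tau = tau,
                     n_restarts = n_restarts, seed = seed)
  dplyr::bind_cols(
    cohort[, c("subject_id", "group")],
    dplyr::bind_rows(rows)
  )
}

#' Write a cohort metric table as CSV
#'
#' Fixed column order `subject_id, group, D, r, T, Eg, Q, CPL`; undefined
#' values are written as the literal token `NA`.
#'
#' @param metrics Metric table from [connectome_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metrics, path) {
  readr::write_csv(metrics[, c("subject_id", "group", METRIC_COLS)], path,
                   na = "NA")
  invisible(path)
}
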