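#' Build a weighted undirected graph from a connectivity matrix
#'
#' One edge per strictly positive off-diagonal pair (counted once); the edge
#' weight is the streamline count. Node indices are 1-based and kept in the
#' graph's edge table with `i < j`.
#'
#' @param m A [connectivity_matrix()] (or a plain matrix, validated on entry).
#' @return A `weighted_graph`: list with `q`, `labels`, and an `edges` tibble
#'   (`i`, `j`, `weight`).
#' @export
graph_from_matrix <- function(m) {
  if (!inherits(m, "connectivity_matrix")) m <- connectivity_matrix(m)
  q <- nrow(m)
  ut <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  edges <- tibble(
    i = as.integer(ut[, 1]),
    j = as.integer(ut[, 2]),
    weight = m[ut]
  )
  structure(
    list(q = q, labels = rownames(m), edges = edges[order(edges$i, edges$j), ]),
    class = "weighted_graph"
  )
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> q = %d, l = %d edges\n", x$q, nrow(x$edges)))
  invisible(x)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> q = %d, l' = %d edges\n", x$q, nrow(x$edges)))
  invisible(x)
}

#' Number of edges retained by a proportional threshold
#'
#' For a graph on `q` nodes, a proportional threshold `tau` keeps the
#' `T = floor((q^2 - q) * tau / 2)` strongest connections. The floor makes
#' the rule conservative: at most a fraction `tau` of all possible pairs is
#' ever retained.
#'
#' @param q Node count (>= 2).
#' @param tau Threshold in `[0, 1]`.
#' @return Integer retained-edge count.
#' @export
#'
#' @examples
#' retained_edge_count(84, 0.35) # 1220
retained_edge_count <- function(q, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0 || tau > 1) {
    abort("`tau` must be a single value in [0, 1].", class = "connectoms_range_error")
  }
  if (!is.numeric(q) || q < 2) {
    abort("`q` must be >= 2.", class = "connectoms_range_error")
  }
  as.integer(floor((q^2 - q) * tau / 2))
}

#' Proportional thresholding: binarize a weighted graph
#'
#' Keeps the `T = floor((q^2 - q) * tau / 2)` largest-weight edges of `g`
#' (all edges when fewer exist) and drops the weights, yielding the
#' unweighted graph on which all metrics but density are computed. Ties at
#' the cutoff weight are broken deterministically by ascending `(i, j)` node
#' index, which also makes the retained edge set monotone (nested) in `tau`.
#'
#' @param g A `weighted_graph` from [graph_from_matrix()].
#' @param tau Threshold in `[0, 1]`: the fraction of possible connections to
#'   conserve, strongest first.
#' @return A `binary_graph`: list with `q`, `labels`, and an `edges` tibble
#'   (`i`, `j`).
#' @export
proportional_threshold <- function(g, tau) {
  stopifnot(inherits(g, "weighted_graph"))
  T_keep <- retained_edge_count(g$q, tau)
  e <- g$edges
  ord <- order(-e$weight, e$i, e$j)
  keep <- e[ord, c("i", "j")][seq_len(min(T_keep, nrow(e))), ]
  keep <- keep[order(keep$i, keep$j), ]
  structure(list(q = g$q, labels = g$labels, edges = keep),
            class = "binary_graph")
}

# Dense 0/1 adjacency of a binary graph (internal workhorse for the metrics).
adjacency_of <- function(g) {
  A <- matrix(0L, g$q, g$q)
  if (nrow(g$edges) > 0) {
    idx <- cbind(g$edges$i, g$edges$j)
    A[idx] <- 1L
    A[idx[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(adjacency_of(g), mode = "undirected")
}

#' Node degrees of a binary graph
#'
#' @param g A `binary_graph`.
#' @return Integer vector `k` of length `q`; `sum(k)` equals twice the edge
#'   count.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  as.integer(tabulate(c(g$edges$i, g$edges$j), nbins = g$q))
}

#' All-pairs shortest path lengths (hop counts)
#'
#' @param g A `binary_graph`.
#' @return A `q x q` matrix of minimum hop counts, `0` on the diagonal and
#'   `Inf` for disconnected pairs.
#' @export
shortest_path_lengths <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  igraph::distances(as_igraph(g), algorithm = "unweighted")
}

#' Per-node triangle counts
#'
#' `t[i]` is the number of unordered neighbor pairs of node `i` that are
#' themselves connected (closed triples through `i`). The total over nodes is
#' three times the number of triangles in the graph.
#'
#' @param g A `binary_graph`.
#' @return Integer vector of length `q`.
#' @export
triangle_counts <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  A <- adjacency_of(g)
  as.integer(round(diag(A %*% A %*% A) / 2))
}

#' Write a binarized adjacency matrix as 0/1 delimited text
#'
#' @param g A `binary_graph`.
#' @param path Output path.
#' @param labels Write node labels as a header row?
#' @return `path`, invisibly.
#' @export
write_binary_adjacency <- function(g, path, labels = TRUE) {
  A <- adjacency_of(g)
  if (!is.null(g$labels)) colnames(A) <- g$labels
  utils::write.table(A, path, sep = "\t", row.names = FALSE,
                     col.names = labels && !is.null(g$labels), quote = FALSE)
  invisible(path)
}
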