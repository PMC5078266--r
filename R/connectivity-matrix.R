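#' Construct and validate a subject-level connectivity matrix
#'
#' A connectivity matrix holds streamline counts between every pair of
#' gray-matter parcels: a `q x q` symmetric, non-negative matrix with a zero
#' diagonal. It is the atomic input of the whole pipeline.
#'
#' @param values Square numeric matrix of non-negative weights (streamline
#'   counts between parcel pairs).
#' @param node_labels Optional character vector of `q` parcel names; defaults
#'   to existing dimnames or `"n1" ... "nq"`.
#'
#' @return A `connectivity_matrix`: the validated matrix with node labels as
#'   dimnames.
#' @export
#'
#' @examples
#' m <- connectivity_matrix(matrix(c(0, 5, 0, 5, 0, 2, 0, 2, 0), 3, 3))
#' graph_from_matrix(m)
connectivity_matrix <- function(values, node_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "connectoms_invalid_input")
  }
  q <- nrow(values)
  if (q != ncol(values) || q < 2) {
    abort(sprintf("`values` must be square with q >= 2 nodes, got %d x %d.",
                  nrow(values), ncol(values)),
          class = "connectoms_invalid_input")
  }
  if (anyNA(values)) {
    abort("`values` contains missing entries.", class = "connectoms_invalid_input")
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("Negative weight at (%d, %d).", neg[1, 1], neg[1, 2]),
          class = "connectoms_invalid_input")
  }
  asym <- which(abs(values - t(values)) > 1e-8, arr.ind = TRUE)
  if (nrow(asym) > 0) {
    abort(sprintf("Matrix is not symmetric at (%d, %d): %g != %g.",
                  asym[1, 1], asym[1, 2],
                  values[asym[1, 1], asym[1, 2]], values[asym[1, 2], asym[1, 1]]),
          class = "connectoms_invalid_input")
  }
  if (any(diag(values) != 0)) {
    i <- which(diag(values) != 0)[1]
    abort(sprintf("Diagonal must be zero; entry (%d, %d) is %g.",
                  i, i, values[i, i]),
          class = "connectoms_invalid_input")
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(values) %||% paste0("n", seq_len(q))
  }
  if (length(node_labels) != q) {
    abort(sprintf("Expected %d node labels, got %d.", q, length(node_labels)),
          class = "connectoms_invalid_input")
  }
  dimnames(values) <- list(node_labels, node_labels)
  structure(values, class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d nodes, %d positive pairs, total weight %g\n",
              nrow(x), sum(x[upper.tri(x)] > 0), sum(x[upper.tri(x)])))
  invisible(x)
}

#' Read a connectivity matrix from delimited text or MatrixMarket format
#'
#' Delimited files may carry an optional header row of node labels; square
#' numeric content is required. MatrixMarket coordinate files (`.mtx`) are
#' read with [Matrix::readMM()] and symmetrized if stored as one triangle.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"delim"` or `"mtx"`.
#' @return A [connectivity_matrix()].
#' @export
read_connectivity_matrix <- function(path, format = c("auto", "delim", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "delim"
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (!isSymmetric(unname(m))) m <- m + t(m) # one stored triangle
    diag(m) <- 0
    return(connectivity_matrix(m))
  }
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  toks <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks)))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  labels <- if (has_header) colnames(df) else NULL
  rownames(m) <- NULL
  connectivity_matrix(unname(m), node_labels = labels)
}

#' Write a connectivity matrix as tab-delimited text
#'
#' @param m A [connectivity_matrix()].
#' @param path Output path.
#' @param labels Write the node labels as a header row?
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(m, path, labels = TRUE) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = labels, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest and its subject matrices
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `path` (paths
#' relative to the manifest's directory or absolute). Group labels must come
#' from the closed set HC/CIS/RR/SP/PP.
#'
#' @param path Manifest CSV path.
#' @return A cohort tibble: `subject_id`, `group` (factor), and a `matrix`
#'   list-column of [connectivity_matrix()] objects.
#' @export
read_cohort_manifest <- function(path) {
  man <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(man))) {
    abort(sprintf("Manifest must have columns %s.", paste(need, collapse = ", ")),
          class = "connectoms_invalid_input")
  }
  bad <- setdiff(unique(man$group), GROUP_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("Unknown group label(s): %s. Valid: %s.",
                  paste(bad, collapse = ", "), paste(GROUP_LEVELS, collapse = ", ")),
          class = "connectoms_invalid_input")
  }
  base <- dirname(path)
  files <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    abort(sprintf("Missing matrix file(s): %s.", paste(missing, collapse = ", ")),
          class = "connectoms_invalid_input")
  }
  tibble(
    subject_id = as.character(man$subject_id),
    group = factor(man$group, levels = GROUP_LEVELS),
    matrix = purrr::map(files, read_connectivity_matrix)
  )
}
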