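#' Read a graph from an edge list or adjacency CSV
#'
#' Edge lists are whitespace/tab-separated files with one `u v` pair per line
#' (`#` comments allowed); adjacency files are square CSV matrices. Directed,
#' weighted or self-loop content is rejected unless the corresponding repair
#' flag is set, in which case it is symmetrized/binarized with a warning.
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.csv` is adjacency), `"edgelist"`,
#'   or `"adjacency_csv"`.
#' @param index_base Node indexing of an edge list: 0 (default) or 1.
#' @param n_nodes Optional node count for edge lists (defaults to the largest
#'   node index seen).
#' @param symmetrize Accept asymmetric adjacency by taking the elementwise
#'   maximum with its transpose.
#' @param binarize Accept weights by thresholding nonzero entries to 1.
#' @return A [ser_graph].
#' @export
read_graph <- function(path, format = c("auto", "edgelist", "adjacency_csv"),
                       index_base = 0, n_nodes = NULL,
                       symmetrize = FALSE, binarize = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "adjacency_csv"
              else "edgelist"
  }
  if (format == "adjacency_csv") {
    A <- as.matrix(utils::read.csv(path, header = FALSE))
    if (is.character(A)) stop("failed to parse ", path, " as a numeric matrix",
                              call. = FALSE)
    dimnames(A) <- NULL
  } else {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    if (length(lines)) {
      parts <- strsplit(lines, "[[:space:],]+")
      bad <- vapply(parts, length, integer(1)) != 2L
      if (any(bad)) stop("edge list lines must contain exactly two node ids",
                         call. = FALSE)
      uv <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
      if (anyNA(uv)) stop("failed to parse node ids in ", path, call. = FALSE)
      uv <- uv - as.integer(index_base) + 1L
      if (any(uv < 1L)) stop("node ids below index_base in ", path, call. = FALSE)
    } else {
      uv <- matrix(integer(0), 0, 2)
    }
    n <- if (is.null(n_nodes)) max(uv, 0L) else as.integer(n_nodes)
    if (any(uv[, 1] == uv[, 2])) stop("self-loops are not allowed", call. = FALSE)
    A <- edges_to_adjacency(n, uv[, 1], uv[, 2])
  }
  if (binarize && any(!A %in% c(0, 1))) {
    warning("non-binary weights thresholded to 0/1")
    A <- (A != 0) * 1L
  }
  if (symmetrize && !isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    warning("asymmetric adjacency symmetrized (elementwise maximum)")
    A <- pmax(A, t(A))
  }
  ser_graph(A)
}

#' Write a graph to an edge list or adjacency CSV
#'
#' @param graph A [ser_graph].
#' @param path Output file.
#' @param format `"edgelist"` or `"adjacency_csv"`.
#' @param index_base Node indexing for edge lists (0 or 1).
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("edgelist", "adjacency_csv"),
                        index_base = 0) {
  g <- as_ser_graph(graph)
  format <- match.arg(format)
  if (format == "adjacency_csv") {
    utils::write.table(g$adjacency, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    e <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
    e <- e - 1L + as.integer(index_base)
    writeLines(paste(e[, 1], e[, 2]), path)
  }
  invisible(path)
}

#' Write module membership of a modular graph
#'
#' Two-column CSV (`node`, `module`), 1-based node ids.
#'
#' @param graph A [ser_graph] carrying a `membership` vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_membership <- function(graph, path) {
  g <- as_ser_graph(graph)
  if (is.null(g$membership)) stop("graph has no membership vector", call. = FALSE)
  utils::write.csv(
    data.frame(node = seq_len(g$n_nodes), module = g$membership),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write a coactivation or prediction matrix as square CSV
#'
#' A header row of node ids is included; values are written with 10
#' significant digits.
#'
#' @param x A `ser_coactivation`, `ser_prediction`, or matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  m <- values_of(x)
  m <- signif(m, 10)
  colnames(m) <- paste0("n", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Read a square matrix written by [write_matrix_csv()]
#' @param path File path.
#' @return A numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = TRUE))
  dimnames(m) <- NULL
  m
}

#' Export a trajectory as CSV
#'
#' Rows are nodes, columns time points (`t0` is the initial condition), cells
#' the state letters.
#'
#' @param traj A `ser_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(unclass(traj)), path, row.names = FALSE)
  invisible(path)
}
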