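#' Read and write graphs
#'
#' Three plain-text formats are supported. `"edgelist"` is a TSV with two
#' integer columns of 0-based node labels and an optional `# nodes=N`
#' header line so isolated nodes survive a round trip. `"adjacency"` is a
#' headerless CSV of 0/1 entries; the matrix must be square, symmetric and
#' zero on the diagonal (relationship matrices are symmetric by
#' construction). `"graphml"` is standard GraphML, delegated to igraph.
#'
#' @param path File path.
#' @param format One of `"edgelist"`, `"adjacency"`, `"graphml"`.
#' @return `read_graph_file()` returns a simple undirected igraph graph;
#'   `write_graph_file()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_graph_file(igraph::make_ring(5), f, "edgelist")
#' g <- read_graph_file(f, "edgelist")
#' @export
read_graph_file <- function(path, format = c("edgelist", "adjacency", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_bad_arg("file not found: ", path)
  switch(format,
    edgelist = read_edgelist(path),
    adjacency = read_adjacency(path),
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      g <- igraph::as_undirected(g, mode = "collapse")
      check_school_graph(g)
      g
    })
}

#' @rdname read_graph_file
#' @param g A simple undirected igraph graph.
#' @export
write_graph_file <- function(g, path, format = c("edgelist", "adjacency", "graphml")) {
  format <- match.arg(format)
  check_school_graph(g)
  switch(format,
    edgelist = {
      el <- igraph::as_edgelist(g, names = FALSE) - 1L
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(sprintf("# nodes=%d", igraph::vcount(g)), con)
      if (nrow(el))
        writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
    },
    adjacency = {
      a <- as.matrix(igraph::as_adjacency_matrix(g))
      utils::write.table(a, path, sep = ",", row.names = FALSE,
                         col.names = FALSE)
    },
    graphml = igraph::write_graph(g, path, format = "graphml"))
  invisible(path)
}

read_edgelist <- function(path) {
  lines <- readLines(path)
  n_declared <- NA_integer_
  if (length(lines) && grepl("^#\\s*nodes\\s*=", lines[1])) {
    n_declared <- as.integer(sub("^#\\s*nodes\\s*=\\s*", "", lines[1]))
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    if (is.na(n_declared)) n_declared <- 0L
    return(igraph::make_empty_graph(n_declared, directed = FALSE))
  }
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop_bad_arg("malformed edge list at line ", bad[1] +
                 (!is.na(n_declared)), ": expected two columns")
  u <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  v <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(u) | is.na(v))
  if (length(bad))
    stop_bad_arg("malformed edge list at line ", bad[1] +
                 (!is.na(n_declared)), ": non-integer node label")
  n <- max(u, v) + 1L
  if (!is.na(n_declared)) {
    if (n_declared < n)
      stop_bad_arg("declared node count ", n_declared,
                   " smaller than largest label ", n - 1L)
    n <- n_declared
  }
  g <- igraph::make_graph(rbind(u, v) + 1L, n = n, directed = FALSE)
  check_school_graph(g)
  g
}

read_adjacency <- function(path) {
  a <- as.matrix(utils::read.csv(path, header = FALSE))
  if (nrow(a) != ncol(a))
    stop_bad_arg("adjacency matrix must be square; got ",
                 nrow(a), "x", ncol(a))
  if (!all(a %in% c(0, 1)))
    stop_bad_arg("adjacency matrix entries must be 0/1")
  asym <- which(a != t(a), arr.ind = TRUE)
  if (nrow(asym))
    stop_bad_arg("asymmetric adjacency matrix at cell [",
                 asym[1, 1], ",", asym[1, 2], "]")
  if (any(diag(a) != 0))
    stop_bad_arg("adjacency matrix has a non-zero diagonal")
  dimnames(a) <- NULL
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}
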