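#' Validate a graph for use with schoolnet
#'
#' All schoolnet functions operate on simple undirected [igraph] graphs:
#' no self-loops, no multi-edges, no edge directions. Nodes are identified
#' by their 1-based igraph index internally; file I/O uses 0-based integer
#' labels (see [read_graph_file()]).
#'
#' @param g An igraph object.
#' @return `g`, invisibly, after validation.
#' @export
check_school_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop_bad_arg("`g` must be an igraph object")
  if (igraph::is_directed(g)) stop_bad_arg("`g` must be undirected")
  if (any(igraph::which_loop(g))) stop_bad_arg("`g` must have no self-loops")
  if (any(igraph::which_multiple(g)))
    stop_bad_arg("`g` must have no duplicate edges")
  invisible(g)
}

#' Empirical degree distribution of a graph
#'
#' Returns the fraction of nodes having each degree k, including a k = 0
#' bin whenever isolated nodes are present.
#'
#' @param g A simple undirected igraph graph with at least one node.
#' @return An object of class `"degree_distribution"`: a list with `k`
#'   (integer degrees with non-zero frequency), `p` (their empirical
#'   frequencies, summing to 1) and `sample_size` (number of nodes).
#' @examples
#' dd <- degree_dist(igraph::make_full_graph(3))
#' dd$p   # a single 1 at degree 2
#' @export
degree_dist <- function(g) {
  check_school_graph(g)
  n <- igraph::vcount(g)
  if (n == 0L)
    stop_bad_arg("degree distribution of an empty graph is undefined")
  deg <- igraph::degree(g)
  tab <- tabulate(deg + 1L, nbins = max(deg) + 1L)
  k <- which(tab > 0L) - 1L
  structure(list(k = k, p = tab[k + 1L] / n, sample_size = n),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat("Degree distribution over", x$sample_size, "nodes\n")
  print(data.frame(k = x$k, p = signif(x$p, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
mean.degree_distribution <- function(x, ...) sum(x$k * x$p)

#' Expand a degree distribution back to a degree sequence
#'
#' @param x A `"degree_distribution"`.
#' @return Integer vector of length `sample_size`.
#' @export
as_degree_sequence <- function(x) {
  stopifnot(inherits(x, "degree_distribution"))
  rep(x$k, round(x$p * x$sample_size))
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component (the principal
#' component). Ties between equally large components are broken in favour
#' of the component containing the smallest node index.
#'
#' @param g A simple undirected igraph graph with at least one node.
#' @return An igraph graph.
#' @export
principal_component <- function(g) {
  check_school_graph(g)
  if (igraph::vcount(g) == 0L) stop_bad_arg("graph has no nodes")
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    # smallest minimum member index wins
    first_member <- vapply(big, function(cid) min(which(comp$membership == cid)),
                           numeric(1))
    big <- big[which.min(first_member)]
  }
  igraph::induced_subgraph(g, which(comp$membership == big))
}

#' The nine standard network measurements
#'
#' Computes order, size, mean degree, diameter, density, average local
#' clustering, mean geodesic distance, mean normalized betweenness and
#' mean closeness, with node-level quantities averaged over the whole
#' network.
#'
#' Conventions: local clustering of nodes with degree < 2 is 0. For a
#' connected graph, geodesic is the mean shortest-path length over
#' unordered node pairs and closeness is the average of
#' \eqn{(n-1)/\sum_j d(i,j)}. For a disconnected graph the diameter and
#' betweenness are computed on the principal component, closeness uses the
#' Wasserman–Faust component-scaled form
#' \eqn{\frac{n_c-1}{\sum d} \cdot \frac{n_c-1}{N-1}} (0 for isolated
#' nodes), and the geodesic is estimated as the reciprocal of the mean
#' closeness. An edgeless graph reports diameter, geodesic, betweenness
#' and closeness of 0.
#'
#' @param g A simple undirected igraph graph with at least 2 nodes.
#' @return An object of class `"school_measurements"`: a named list with
#'   elements `order`, `size`, `mean_degree`, `diameter`, `density`,
#'   `clustering`, `geodesic`, `betweenness`, `closeness`.
#' @examples
#' measure_graph(igraph::make_full_graph(4))
#' @export
measure_graph <- function(g) {
  check_school_graph(g)
  n <- igraph::vcount(g)
  if (n < 2L) stop_bad_arg("measurements require at least 2 nodes")
  m <- igraph::ecount(g)
  out <- list(
    order = n,
    size = m,
    mean_degree = 2 * m / n,
    diameter = NA_real_,
    density = 2 * m / (n * (n - 1)),
    clustering = igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"),
    geodesic = NA_real_, betweenness = NA_real_, closeness = NA_real_
  )
  if (m == 0L) {
    out$diameter <- 0; out$geodesic <- 0
    out$betweenness <- 0; out$closeness <- 0
  } else if (igraph::is_connected(g)) {
    out$diameter <- igraph::diameter(g)
    out$geodesic <- igraph::mean_distance(g)
    out$closeness <- mean(igraph::closeness(g, normalized = TRUE))
    out$betweenness <- if (n >= 3L)
      mean(igraph::betweenness(g, normalized = TRUE)) else 0
  } else {
    pc <- principal_component(g)
    out$diameter <- igraph::diameter(pc)
    out$betweenness <- if (igraph::vcount(pc) >= 3L)
      mean(igraph::betweenness(pc, normalized = TRUE)) else 0
    d <- igraph::distances(g)
    clo <- vapply(seq_len(n), function(i) {
      di <- d[i, -i]
      di <- di[is.finite(di)]
      nc <- length(di) + 1L            # component size of node i
      if (nc < 2L) return(0)
      ((nc - 1) / sum(di)) * ((nc - 1) / (n - 1))
    }, numeric(1))
    out$closeness <- mean(clo)
    out$geodesic <- if (out$closeness > 0) 1 / out$closeness else 0
  }
  structure(out, class = "school_measurements")
}

#' @export
print.school_measurements <- function(x, digits = 4, ...) {
  labs <- c(order = "Order", size = "Size", mean_degree = "<k>",
            diameter = "Diameter", density = "Density",
            clustering = "Clustering", geodesic = "Geodesic",
            betweenness = "Betweenness", closeness = "Closeness")
  cat("Network measurements\n")
  for (nm in names(labs))
    cat(sprintf("  %-12s %s\n", labs[[nm]], format(signif(x[[nm]], digits))))
  invisible(x)
}

#' @export
as.data.frame.school_measurements <- function(x, ...) {
  data.frame(measure = names(unclass(x)),
             value = unlist(x, use.names = FALSE),
             stringsAsFactors = FALSE)
}
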