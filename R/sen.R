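#' School Enmity Network (SEN) parameters
#'
#' Parameters of the enmity-network generator: `N` students over `m`
#' classrooms, a target mean number of enemies per student `k_avg`
#' (typically well below 2: enmity networks are sparse, disconnected and
#' contain many isolated students), and a shortcut probability `p` that
#' rewires links across classrooms preferentially.
#'
#' @param N Number of students.
#' @param m Number of classrooms, `1 <= m <= N`.
#' @param k_avg Target mean enemies per student, `>= 0`.
#' @param p Shortcut probability in `[0, 1]`.
#' @param attachment `"strict"` picks endpoints with probability
#'   proportional to degree (uniform among all nodes while every degree
#'   is 0); `"shifted"` uses weights `degree + 1`.
#' @return An object of class `"sen_params"`.
#' @examples
#' sen_params(N = 419, m = 12, k_avg = 1.5, p = 0.1)
#' @export
sen_params <- function(N, m, k_avg, p, attachment = c("strict", "shifted")) {
  N <- check_count(N, "N", min = 1L)
  m <- check_count(m, "m", min = 1L)
  if (m > N) stop_bad_arg("`m` must not exceed `N`")
  if (!is.numeric(k_avg) || k_avg < 0) stop_bad_arg("`k_avg` must be >= 0")
  check_probability(p)
  attachment <- match.arg(attachment)
  a_min <- min(classroom_sizes(N, m))
  if (round(max(classroom_sizes(N, m)) * k_avg / 2) >
      a_min * (a_min - 1) / 2)
    stop_bad_arg("`k_avg` too large: classroom link quota exceeds C(a, 2)")
  structure(list(N = N, m = m, k_avg = k_avg, p = p,
                 attachment = attachment),
            class = "sen_params")
}

#' @export
print.sen_params <- function(x, ...) {
  cat(sprintf("SEN parameters: N=%d, m=%d, k_avg=%g, p=%g (%s attachment)\n",
              x$N, x$m, x$k_avg, x$p, x$attachment))
  invisible(x)
}

#' Enmity link quota of a classroom
#'
#' A classroom of `a` students with target mean degree `k_avg` receives
#' `l = round(a * k_avg / 2)` links (banker's rounding).
#'
#' @param a Classroom size, `a >= 2`.
#' @param k_avg Target mean enemies per student.
#' @return Integer number of links.
#' @examples
#' links_per_classroom(35, 1.2)  # 21
#' @export
links_per_classroom <- function(a, k_avg) {
  a <- check_count(a, "a", min = 2L)
  if (!is.numeric(k_avg) || k_avg < 0) stop_bad_arg("`k_avg` must be >= 0")
  l <- as.integer(round(a * k_avg / 2))
  if (l > a * (a - 1) / 2)
    stop_bad_arg("link quota ", l, " exceeds the ", a * (a - 1) / 2,
                 " possible pairs")
  l
}

#' Degree-proportional node selection
#'
#' Picks one node index with probability proportional to its degree
#' (preferential attachment). With `attachment = "strict"` and all
#' degrees zero the choice is uniform; with `"shifted"` the weights are
#' `degree + 1` throughout.
#'
#' @param degrees Non-negative integer vector of current degrees.
#' @param attachment `"strict"` or `"shifted"`.
#' @return A single index into `degrees`.
#' @export
preferential_pick <- function(degrees, attachment = c("strict", "shifted")) {
  attachment <- match.arg(attachment)
  if (!length(degrees)) stop_bad_arg("`degrees` must be non-empty")
  if (any(degrees < 0)) stop_bad_arg("`degrees` must be non-negative")
  w <- if (attachment == "shifted") degrees + 1
       else if (sum(degrees) == 0) rep(1, length(degrees))
       else degrees
  sample.int(length(degrees), 1L, prob = w)
}

# Add `l` links to the adjacency structure `adj` (list of integer
# vectors) restricted to nodes `scope`: first endpoint preferential over
# the degrees within scope, second uniform, resampling self-loops and
# duplicates.  Mutates and returns `adj`.
pa_add_links <- function(adj, scope, l, attachment, max_retry = 10000L) {
  deg <- lengths(adj[scope])
  for (e in seq_len(l)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_retry)
        stop_bad_arg("could not place a link without duplication")
      i <- preferential_pick(deg, attachment)
      j <- sample.int(length(scope), 1L)
      u <- scope[i]; v <- scope[j]
      if (u != v && !(v %in% adj[[u]])) break
    }
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
  }
  adj
}

#' Preferential-attachment enmity block for one classroom
#'
#' Starts from `a` isolated students and adds `l` links one at a time,
#' each joining a preferentially chosen endpoint (see
#' [preferential_pick()]) to a uniformly chosen distinct endpoint,
#' resampling on self-loops and duplicates. Students that never get
#' picked stay isolated, which is the empirically observed (and, for
#' growth models like Barabasi–Albert, unreachable) feature of enmity
#' networks.
#'
#' @param a Classroom size.
#' @param l Number of links, `l <= a(a-1)/2`.
#' @param attachment `"strict"` or `"shifted"`.
#' @param seed Optional integer seed.
#' @return A simple undirected igraph graph on `a` nodes with exactly
#'   `l` edges.
#' @export
build_classroom_enmity <- function(a, l, attachment = "strict", seed = NULL) {
  a <- check_count(a, "a", min = 1L)
  l <- check_count(l, "l", min = 0L)
  if (l > a * (a - 1) / 2) stop_bad_arg("`l` exceeds the number of pairs")
  with_seed(seed, {
    adj <- rep(list(integer(0)), a)
    adj <- pa_add_links(adj, seq_len(a), l, attachment)
    adj_to_graph(adj)
  })
}

adj_to_graph <- function(adj) {
  n <- length(adj)
  el <- do.call(rbind, lapply(seq_len(n), function(u) {
    vs <- adj[[u]][adj[[u]] > u]
    if (length(vs)) cbind(u, vs) else NULL
  }))
  if (is.null(el)) return(igraph::make_empty_graph(n, directed = FALSE))
  igraph::make_graph(t(el), n = n, directed = FALSE)
}

#' Generate a School Enmity Network
#'
#' Builds one preferential-attachment enmity block per classroom
#' ([build_classroom_enmity()] with quota [links_per_classroom()]), then
#' rewires each link independently with probability `p`: the link is
#' removed and replaced by a whole-school link whose first endpoint is
#' chosen preferentially over all current degrees and whose second
#' endpoint is uniform. The total link count is conserved exactly; the
#' result is typically disconnected with isolated students.
#'
#' @param params A [sen_params()] object.
#' @param seed Optional integer seed.
#' @return A simple undirected igraph graph with `params$N` nodes.
#' @examples
#' g <- generate_sen(sen_params(419, 12, 1.5, 0.1), seed = 1)
#' igraph::ecount(g)
#' @export
generate_sen <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sen_params"))
  with_seed(seed, {
    sizes <- classroom_sizes(params$N, params$m)
    offset <- cumsum(c(0L, sizes[-params$m]))
    adj <- rep(list(integer(0)), params$N)
    for (j in seq_len(params$m)) {
      scope <- offset[j] + seq_len(sizes[j])
      l <- links_per_classroom(sizes[j], params$k_avg)
      adj <- pa_add_links(adj, scope, l, params$attachment)
    }
    g <- adj_to_graph(adj)
    sen_rewire(g, params$p, params$attachment)
  })
}

# Whole-graph preferential rewiring: each edge is, with probability p,
# deleted and replaced by an edge from a preferentially picked node to a
# uniform node, avoiding self-loops and duplicates.
sen_rewire <- function(g, p, attachment, max_retry = 10000L) {
  if (p == 0 || igraph::ecount(g) == 0L) return(g)
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  deg <- lengths(adj)
  rewired <- which(runif(nrow(el)) < p)
  for (e in rewired) {
    u0 <- el[e, 1]; v0 <- el[e, 2]
    adj[[u0]] <- adj[[u0]][-match(v0, adj[[u0]])]
    adj[[v0]] <- adj[[v0]][-match(u0, adj[[v0]])]
    deg[u0] <- deg[u0] - 1L; deg[v0] <- deg[v0] - 1L
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_retry)
        stop_bad_arg("could not place a replacement link")
      u <- preferential_pick(deg, attachment)
      v <- sample.int(n, 1L)
      if (u != v && !(v %in% adj[[u]])) break
    }
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
    deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
  }
  adj_to_graph(adj)
}
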