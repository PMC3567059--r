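#' Classic random-graph reference models
#'
#' Erdos–Renyi, Watts–Strogatz and Barabasi–Albert generators, used as
#' baselines that school friendship/enmity topologies are compared
#' against. ER and BA generation is delegated to igraph; the BA process
#' grows from a clique on `m + 1` nodes so every node has degree at least
#' `m`. WS generation is implemented directly as a ring lattice of even
#' degree `K` whose edges have their far endpoint rewired independently
#' with probability `p` (resampling to avoid self-loops and duplicate
#' edges), matching the closed-form degree law in [ws_pmf()].
#'
#' @param n Number of nodes.
#' @param p Link probability (ER) or rewiring probability (WS).
#' @param K Even initial lattice degree, `K < n` (WS).
#' @param m Number of links added by each arriving node (BA), `1 <= m < n`.
#' @param seed Optional integer seed for reproducibility.
#' @return A simple undirected igraph graph.
#' @examples
#' g <- generate_er(50, 0.1, seed = 1)
#' mean(igraph::degree(g))
#' @export
generate_er <- function(n, p, seed = NULL) {
  n <- check_count(n, "n", min = 1L)
  check_probability(p)
  with_seed(seed, igraph::sample_gnp(n, p))
}

#' @rdname generate_er
#' @export
generate_ws <- function(n, K, p, seed = NULL) {
  n <- check_count(n, "n", min = 2L)
  K <- check_count(K, "K", min = 2L)
  check_probability(p)
  if (K %% 2L != 0L) stop_bad_arg("`K` must be even")
  if (K >= n) stop_bad_arg("`K` must be smaller than `n`")
  with_seed(seed, {
    # ring lattice: node i linked to its K/2 clockwise neighbours
    from <- rep(seq_len(n), each = K %/% 2L)
    to <- from + rep(seq_len(K %/% 2L), times = n)
    to <- (to - 1L) %% n + 1L
    adj <- lapply(seq_len(n), function(i) integer(0))
    add_edge <- function(a, b) {
      adj[[a]] <<- c(adj[[a]], b); adj[[b]] <<- c(adj[[b]], a)
    }
    for (e in seq_along(from)) add_edge(from[e], to[e])
    rewire <- runif(length(from)) < p
    for (e in which(rewire)) {
      a <- from[e]; b <- to[e]
      # drop a-b, then resample the far endpoint until valid
      adj[[a]] <- adj[[a]][-match(b, adj[[a]])]
      adj[[b]] <- adj[[b]][-match(a, adj[[b]])]
      repeat {
        b2 <- sample.int(n, 1L)
        if (b2 != a && !(b2 %in% adj[[a]])) break
      }
      add_edge(a, b2); to[e] <- b2
    }
    igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  })
}

#' @rdname generate_er
#' @export
generate_ba <- function(n, m, seed = NULL) {
  n <- check_count(n, "n", min = 2L)
  m <- check_count(m, "m", min = 1L)
  if (n <= m) stop_bad_arg("`n` must exceed `m`")
  with_seed(seed,
    igraph::sample_pa(n, power = 1, m = m, directed = FALSE,
                      start.graph = igraph::make_full_graph(m + 1L)))
}

#' Closed-form degree laws of the reference models
#'
#' `er_pmf()` is the binomial degree law of an Erdos–Renyi graph,
#' `Binom(n - 1, p)` at degree `k`; `poisson_pmf()` its large-`n` Poisson
#' limit. `ws_pmf()` is the Watts–Strogatz degree law for a ring lattice
#' of degree `K` rewired with probability `p`: a node of degree
#' `k >= K/2` keeps `s` of its `K/2` outgoing lattice links (binomially)
#' and receives a Poisson(`pK/2`) number of rewired links,
#' \deqn{P(k) = \sum_{s=0}^{\min(k-K/2,\,K/2)} \binom{K/2}{s}(1-p)^s
#'   p^{K/2-s} \frac{(pK/2)^{k-K/2-s}}{(k-K/2-s)!} e^{-pK/2}.}
#' `ba_pmf()` is the stationary Barabasi–Albert law
#' \eqn{P(k) = 2m(m+1)/[k(k+1)(k+2)]} for `k >= m`, with its
#' \eqn{k^{-3}} tail.
#'
#' @param k Integer degree (vectorized).
#' @param n,p,K,m,lambda Model parameters as in [generate_er()] and
#'   friends; `lambda > 0` is the Poisson mean.
#' @return Numeric vector of probabilities.
#' @examples
#' sum(ba_pmf(2:1e5, m = 2))  # ~1
#' @export
er_pmf <- function(k, n, p) {
  n <- check_count(n, "n", min = 1L)
  check_probability(p)
  if (any(k != floor(k)) || any(k < 0)) stop_bad_arg("`k` must be integers >= 0")
  dbinom(k, n - 1L, p)
}

#' @rdname er_pmf
#' @export
poisson_pmf <- function(k, lambda) {
  if (!is.numeric(lambda) || lambda <= 0) stop_bad_arg("`lambda` must be > 0")
  if (any(k != floor(k)) || any(k < 0)) stop_bad_arg("`k` must be integers >= 0")
  dpois(k, lambda)
}

#' @rdname er_pmf
#' @export
ws_pmf <- function(k, K, p) {
  K <- check_count(K, "K", min = 2L)
  if (K %% 2L != 0L) stop_bad_arg("`K` must be even")
  check_probability(p)
  if (any(k != floor(k)) || any(k < 0)) stop_bad_arg("`k` must be integers >= 0")
  half <- K %/% 2L
  vapply(k, function(kk) {
    if (kk < half) return(0)
    s <- 0:min(kk - half, half)
    sum(dbinom(s, half, 1 - p) * dpois(kk - half - s, p * half))
  }, numeric(1))
}

#' @rdname er_pmf
#' @export
ba_pmf <- function(k, m) {
  m <- check_count(m, "m", min = 1L)
  if (any(k != floor(k)) || any(k < 0)) stop_bad_arg("`k` must be integers >= 0")
  out <- 2 * m * (m + 1) / (k * (k + 1) * (k + 2))
  out[k < m] <- 0
  out
}
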