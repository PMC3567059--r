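# Brute-force oracles, independent of the package internals (and of
# igraph): everything is computed from the raw adjacency matrix with
# breadth-first search and direct counting.

oracle_bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(A[u, ] == 1)) {
        if (is.infinite(d[v])) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
      }
    }
    frontier <- nxt
  }
  d
}

oracle_distances <- function(A) t(sapply(seq_len(nrow(A)), oracle_bfs_dist, A = A))

# number of shortest paths between every pair, by dynamic programming
# over increasing distance
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  np <- matrix(0, n, n)
  diag(np) <- 1
  maxd <- max(D[is.finite(D)])
  if (maxd >= 1) for (dd in 1:maxd) {
    idx <- which(D == dd, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      pred <- which(A[, j] == 1 & D[i, ] == dd - 1)
      np[i, j] <- sum(np[i, pred])
    }
  }
  np
}

oracle_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      comp[is.finite(oracle_bfs_dist(A, s))] <- cid
    }
  }
  comp
}

# the nine measurements, from scratch
oracle_measurements <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  m <- sum(A) / 2
  # local clustering by explicit triangle counting
  cl <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    sum(A[nb, nb]) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  D <- oracle_distances(A)
  comp <- oracle_components(A)
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(big) > 1) {
    firsts <- vapply(big, function(cc) min(which(comp == cc)), numeric(1))
    big <- big[which.min(firsts)]
  }
  pc <- which(comp == big)
  Apc <- A[pc, pc, drop = FALSE]; npc <- length(pc)
  Dpc <- D[pc, pc, drop = FALSE]
  diam <- if (m == 0) 0 else max(Dpc)
  # betweenness on the principal component
  btw <- 0
  if (npc >= 3) {
    NP <- oracle_path_counts(Apc, Dpc)
    b <- vapply(seq_len(npc), function(v) {
      tot <- 0
      for (s in seq_len(npc)) for (t in seq_len(npc)) {
        if (s < t && s != v && t != v && NP[s, t] > 0 &&
            Dpc[s, v] + Dpc[v, t] == Dpc[s, t])
          tot <- tot + NP[s, v] * NP[v, t] / NP[s, t]
      }
      tot
    }, numeric(1))
    btw <- mean(b / ((npc - 1) * (npc - 2) / 2))
  }
  connected <- max(comp) == 1
  if (m == 0) {
    geo <- 0; clo <- 0
  } else if (connected) {
    geo <- mean(D[upper.tri(D)])
    clo <- mean(vapply(seq_len(n), function(i) (n - 1) / sum(D[i, -i]),
                       numeric(1)))
  } else {
    clo_i <- vapply(seq_len(n), function(i) {
      di <- D[i, -i]; di <- di[is.finite(di)]
      nc <- length(di) + 1
      if (nc < 2) return(0)
      ((nc - 1) / sum(di)) * ((nc - 1) / (n - 1))
    }, numeric(1))
    clo <- mean(clo_i)
    geo <- if (clo > 0) 1 / clo else 0
  }
  list(order = n, size = m, mean_degree = 2 * m / n, diameter = diam,
       density = 2 * m / (n * (n - 1)), clustering = mean(cl),
       geodesic = geo, betweenness = btw, closeness = clo)
}

random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

adjacency_to_graph <- function(A)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")

# independent discrete power-law sampler: direct multinomial sampling on
# a truncated, renormalized pmf (contrast: the package uses inverse-CDF
# lookup against an exact zeta normalization)
oracle_rpowerlaw <- function(n, alpha, k_min = 1, cap = 200000) {
  ks <- k_min:cap
  w <- ks ^ (-alpha)
  sample(ks, n, replace = TRUE, prob = w / sum(w))
}
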