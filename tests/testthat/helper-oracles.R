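# Independent brute-force oracles used to validate the graph measures and
# classifier arithmetic. These deliberately avoid igraph and the package's
# own code paths.

# all-pairs shortest-path distances by breadth-first search
bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] > 0)
        new <- nb[!is.finite(d[s, nb])]
        d[s, new] <- dist
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
      frontier <- frontier[frontier != s]
    }
  }
  d
}

oracle_efficiency <- function(adj) {
  d <- bfs_distances(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- NA
  mean(inv, na.rm = TRUE)
}

oracle_cpl <- function(adj) {
  d <- bfs_distances(adj)
  du <- d[upper.tri(d)]
  mean(du[is.finite(du)])
}

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  closed <- 0; paths2 <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    paths2 <- paths2 + k * (k - 1) / 2
    if (k >= 2) {
      cmb <- utils::combn(nb, 2)
      closed <- closed + sum(adj[t(cmb)] > 0)  # connected neighbour pairs
    }
  }
  # sum over nodes of connected neighbour pairs = 3 * triangles
  if (paths2 == 0) return(0)
  closed / paths2
}

newman_q <- function(adj, membership) {
  m2 <- sum(adj)                 # 2m
  if (m2 == 0) return(NA_real_)
  deg <- rowSums(adj)
  q <- 0
  for (cl in unique(membership)) {
    idx <- membership == cl
    q <- q + sum(adj[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
  }
  q
}

# exhaustive modularity maximum over all set partitions (restricted growth
# strings); feasible up to ~8 nodes
oracle_modularity <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 9)
  best <- -Inf
  a <- integer(n)  # restricted growth string
  recurse <- function(pos, maxval) {
    if (pos > n) {
      q <- newman_q(adj, a)
      if (q > best) best <<- q
      return(invisible(NULL))
    }
    for (v in seq_len(maxval + 1L)) {
      a[pos] <<- v
      recurse(pos + 1L, max(maxval, v))
    }
  }
  recurse(1L, 0L)
  best
}

# random connected-ish weighted matrix with modular structure
random_modular_matrix <- function(n, n_modules = 2, seed = 1) {
  set.seed(seed)
  module <- rep(seq_len(n_modules), length.out = n)
  w <- matrix(stats::runif(n * n, 0.05, 0.3), n, n)
  boost <- outer(module, module, "==") * stats::runif(n * n, 0.3, 0.6)
  m <- w + boost
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
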