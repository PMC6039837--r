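#' @title Cost thresholding and global graph measures
#'
#' @description
#' Connectivity matrices are reduced to binary graphs by retaining the top
#' `cost` fraction of the strongest connections, where the analysis cost is
#' the one maximizing the global cost efficiency GCE = E_C - C (global
#' efficiency of the thresholded graph minus its cost). Three global
#' measures are computed on the binarized graph: modularity (segregation of
#' the network into communities), transitivity (normalized clustering) and
#' characteristic path length (integration).
#' @name netmeasures
NULL

check_conn_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  if (max(abs(diag(m))) > 1e-8) stop("matrix diagonal must be zero")
  invisible(TRUE)
}

#' Proportional threshold to a binary adjacency matrix
#'
#' Retains the top `ceiling(cost * m)` of the m upper-triangle edges by
#' weight (then symmetrizes). Ties at the cutoff are broken by ascending
#' (row, col) index so the edge count is exact.
#'
#' @param matrix symmetric connectivity matrix with zero diagonal.
#' @param cost fraction of edges to retain, in `(0, 1]`.
#' @return binary adjacency matrix (0/1, symmetric, zero diagonal).
#' @export
threshold_matrix <- function(matrix, cost) {
  check_conn_matrix(matrix)
  if (cost <= 0 || cost > 1) stop("cost must be in (0, 1]")
  n <- nrow(matrix)
  ut <- which(upper.tri(matrix), arr.ind = TRUE)
  w <- matrix[ut]
  k <- ceiling(cost * nrow(ut))
  ord <- order(-w, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(k)]
  adj <- matrix(0L, n, n, dimnames = dimnames(matrix))
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj + t(adj)
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Global efficiency of a binary graph
#'
#' Mean over ordered node pairs of the inverse shortest-path distance;
#' unreachable pairs contribute zero.
#'
#' @param adj binary adjacency matrix.
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  if (nrow(adj) < 2) stop("efficiency needs at least 2 nodes")
  d <- igraph::distances(adj_to_graph(adj))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0   # unreachable pairs contribute zero
  diag(inv) <- NA             # self-pairs excluded
  mean(inv, na.rm = TRUE)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all reachable unordered pairs. For a
#' disconnected graph the mean is over reachable pairs only and the fraction
#' of reachable pairs is attached as attribute `reachable_fraction`.
#'
#' @param adj binary adjacency matrix with at least one edge.
#' @return scalar (> 0) with attribute `reachable_fraction`.
#' @export
characteristic_path_length <- function(adj) {
  if (sum(adj) == 0) stop("characteristic path length undefined: no edges")
  d <- igraph::distances(adj_to_graph(adj))
  du <- d[upper.tri(d)]
  reach <- is.finite(du)
  out <- mean(du[reach])
  attr(out, "reachable_fraction") <- mean(reach)
  out
}

#' Transitivity (normalized whole-graph clustering)
#'
#' 3 x (number of triangles) / (number of paths of length 2); defined as 0
#' for graphs with no length-2 paths.
#'
#' @param adj binary adjacency matrix.
#' @return scalar in `[0, 1]`.
#' @export
graph_transitivity <- function(adj) {
  t <- igraph::transitivity(adj_to_graph(adj), type = "global")
  if (is.nan(t)) 0 else t
}

#' Modularity by multi-restart Louvain optimization
#'
#' Maximizes Newman modularity with Louvain community detection over
#' `n_restarts` seeded restarts (plus the trivial single-community
#' partition, whose modularity is exactly 0, as a floor); returns the best
#' value and its partition.
#'
#' @param adj binary adjacency matrix with at least one edge.
#' @param gamma resolution parameter (default 1).
#' @param n_restarts number of seeded restarts (default 100).
#' @param seed RNG seed.
#' @return scalar Q with attribute `membership` (community assignment).
#' @export
graph_modularity <- function(adj, gamma = 1, n_restarts = 100L, seed = 1L) {
  if (sum(adj) == 0) stop("modularity undefined: graph has no edges")
  g <- adj_to_graph(adj)
  best_q <- 0                                 # single community: Q = 0
  best_mem <- rep(1L, nrow(adj))
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, resolution = gamma)
      q <- igraph::modularity(g, igraph::membership(cl))
      if (q > best_q + 1e-12) {
        best_q <- q
        best_mem <- as.integer(igraph::membership(cl))
      }
    }
  })
  structure(best_q, membership = best_mem)
}

#' Global cost efficiency scan over a cost grid
#'
#' For each cost the matrix is thresholded, the global efficiency E_C
#' computed, and GCE = E_C - C recorded; the optimal cost is the first
#' maximum of the GCE curve.
#'
#' @param matrix symmetric connectivity matrix.
#' @param cost_grid sorted cost grid in `(0, 1)`; default 0.01..0.50 step
#'   0.01.
#' @return object of class `threshold_scan`: data.frame (`cost`,
#'   `efficiency`, `gce`) and `optimal_cost`.
#' @export
gce_scan <- function(matrix, cost_grid = seq(0.01, 0.50, by = 0.01)) {
  if (length(cost_grid) == 0L) stop("empty cost grid")
  stopifnot(all(diff(cost_grid) > 0), all(cost_grid > 0), all(cost_grid <= 1))
  eff <- vapply(cost_grid, function(cc)
    global_efficiency(threshold_matrix(matrix, cc)), numeric(1))
  gce <- eff - cost_grid
  structure(list(scan = data.frame(cost = cost_grid, efficiency = eff,
                                   gce = gce),
                 optimal_cost = cost_grid[which.max(gce)]),
            class = "threshold_scan")
}

#' Graph features of one subject and band across runs
#'
#' Thresholds each run's connectivity matrix at the fixed cost, computes
#' modularity, transitivity and characteristic path length per run, and
#' averages across runs (the per-run values are retained for the
#' reliability analysis).
#'
#' @param band_matrices_per_run list of `band_connectivity` (or plain
#'   matrices), one per run.
#' @param cost analysis cost (default 0.10, the global-cost-efficiency
#'   optimum applied to all subjects and bands).
#' @param n_restarts,seed passed to [graph_modularity()].
#' @return list of class `graph_features`: `per_run` data.frame (run, Q, T,
#'   CPL) and `mean` named vector.
#' @export
subject_features <- function(band_matrices_per_run, cost = 0.10,
                             n_restarts = 100L, seed = 1L) {
  if (length(band_matrices_per_run) < 1L) stop("need at least one run")
  mats <- lapply(band_matrices_per_run, function(x)
    if (inherits(x, "band_connectivity")) x$matrix else x)
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stop("inconsistent matrix sizes across runs")
  rows <- lapply(seq_along(mats), function(r) {
    adj <- threshold_matrix(mats[[r]], cost)
    data.frame(run = r,
               modularity = as.numeric(graph_modularity(
                 adj, n_restarts = n_restarts, seed = child_seed(seed, r))),
               transitivity = graph_transitivity(adj),
               cpl = as.numeric(characteristic_path_length(adj)))
  })
  per_run <- do.call(rbind, rows)
  structure(list(per_run = per_run,
                 mean = colMeans(per_run[, c("modularity", "transitivity",
                                             "cpl")]),
                 cost_used = cost),
            class = "graph_features")
}

#' Per-run and run-averaged feature tables for a whole cohort
#'
#' Runs the connectivity and graph stages subject by subject (runs are
#' regenerated from their recorded seeds, so memory stays flat).
#'
#' @param cohort a `vns_cohort`.
#' @param bands bands to analyse.
#' @param cost analysis cost.
#' @param epoch_len_s epoch length for PLV.
#' @param n_restarts,seed modularity optimizer settings.
#' @return list with `per_run` and `averaged` data.frames (columns
#'   subject_id, group, sedation, age, sex, band, \[run,\] modularity,
#'   transitivity, cpl, cost_used).
#' @export
cohort_features <- function(cohort, bands = c("theta", "alpha", "beta"),
                            cost = 0.10, epoch_len_s = 3.0,
                            n_restarts = 100L, seed = 1L) {
  stopifnot(inherits(cohort, "vns_cohort"))
  man <- cohort$manifest
  per_run <- list(); averaged <- list()
  for (i in seq_len(nrow(man))) {
    runs <- subject_runs(cohort, man$subject_id[i])
    for (b in bands) {
      bcs <- lapply(runs, band_plv_matrix, band = b,
                    epoch_len_s = epoch_len_s)
      gf <- subject_features(bcs, cost = cost, n_restarts = n_restarts,
                             seed = child_seed(seed, i))
      meta <- man[i, c("subject_id", "group", "sedation", "age", "sex")]
      per_run[[length(per_run) + 1L]] <-
        cbind(meta, band = b, gf$per_run, cost_used = cost,
              row.names = NULL)
      averaged[[length(averaged) + 1L]] <-
        cbind(meta, band = b, as.data.frame(as.list(gf$mean)),
              cost_used = cost, row.names = NULL)
    }
  }
  list(per_run = do.call(rbind, per_run),
       averaged = do.call(rbind, averaged))
}
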