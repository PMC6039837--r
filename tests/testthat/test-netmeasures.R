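adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1L; a[e[2], e[1]] <- 1L }
  a
}

test_that("proportional thresholding retains exactly the strongest edges", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.9, 0.1, 0.8, 0.3, 0.2, 0.7)  # 6 distinct weights
  m <- m + t(m)
  adj <- threshold_matrix(m, 1 / 3)
  expect_equal(sum(adj) / 2, 2)
  # the two largest weights are m[1,2]=0.9 and m[2,3]=0.8 (column-major fill)
  expect_equal(adj[1, 2], 1)
  expect_equal(adj[2, 3], 1)
  expect_equal(sum(adj[upper.tri(adj)] * m[upper.tri(m)]),
               0.9 + 0.8)

  expect_equal(sum(threshold_matrix(m, 1)) / 2, 6)  # complete graph

  # all-ties: exact ceiling(m/2) edges by the index tie-break
  mt <- matrix(0.5, 5, 5); diag(mt) <- 0
  adj_t <- threshold_matrix(mt, 0.5)
  expect_equal(sum(adj_t) / 2, ceiling(10 * 0.5))

  expect_error(threshold_matrix(m, 0), "cost")
  expect_error(threshold_matrix(matrix(1:9, 3, 3) * 1.0, 0.5), "symmetric")
})

test_that("edge-count density contract holds across costs and sizes", {
  for (seed in 1:3) {
    m <- random_modular_matrix(12, 3, seed)
    for (cost in c(0.05, 0.10, 0.33, 0.85)) {
      adj <- threshold_matrix(m, cost)
      expect_equal(sum(adj) / 2, ceiling(cost * choose(12, 2)))
    }
  }
})

test_that("global efficiency matches hand values and BFS oracle", {
  k4 <- matrix(1L, 4, 4); diag(k4) <- 0L
  expect_equal(global_efficiency(k4), 1.0)
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3)
  expect_equal(global_efficiency(matrix(0L, 3, 3)), 0.0)
})

test_that("characteristic path length follows the reachable-pair convention", {
  k3 <- matrix(1L, 3, 3); diag(k3) <- 0L
  expect_equal(as.numeric(characteristic_path_length(k3)), 1.0)
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(as.numeric(characteristic_path_length(path3)), 4 / 3)
  two_edges <- adj_from_edges(4, list(c(1, 2), c(3, 4)))
  cpl <- characteristic_path_length(two_edges)
  expect_equal(as.numeric(cpl), 1.0)
  expect_equal(attr(cpl, "reachable_fraction"), 2 / 6)
  expect_error(characteristic_path_length(matrix(0L, 3, 3)), "no edges")
})

test_that("transitivity matches hand values", {
  k3 <- matrix(1L, 3, 3); diag(k3) <- 0L
  expect_equal(graph_transitivity(k3), 1.0)
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(graph_transitivity(path3), 0.0)
  k4_minus <- matrix(1L, 4, 4); diag(k4_minus) <- 0L
  k4_minus[1, 2] <- k4_minus[2, 1] <- 0L
  expect_equal(graph_transitivity(k4_minus), 0.75)  # 2 triangles, 8 paths
  expect_equal(graph_transitivity(matrix(0L, 3, 3)), 0)
})

test_that("modularity: two disjoint K4s give Q = 0.5; K6 gives 0", {
  k4 <- matrix(1L, 4, 4); diag(k4) <- 0L
  two_k4 <- rbind(cbind(k4, matrix(0L, 4, 4)),
                  cbind(matrix(0L, 4, 4), k4))
  q <- graph_modularity(two_k4, seed = 5)
  expect_equal(as.numeric(q), 0.5)
  expect_equal(as.numeric(q), oracle_modularity(two_k4))
  expect_length(unique(attr(q, "membership")), 2)

  k6 <- matrix(1L, 6, 6); diag(k6) <- 0L
  q6 <- graph_modularity(k6, seed = 5)
  expect_equal(as.numeric(q6), 0)
  expect_error(graph_modularity(matrix(0L, 4, 4)), "no edges")
})

test_that("fixed seed gives identical modularity and partition", {
  m <- random_modular_matrix(16, 4, seed = 9)
  adj <- threshold_matrix(m, 0.2)
  q1 <- graph_modularity(adj, n_restarts = 10, seed = 3)
  q2 <- graph_modularity(adj, n_restarts = 10, seed = 3)
  expect_identical(as.numeric(q1), as.numeric(q2))
  expect_identical(attr(q1, "membership"), attr(q2, "membership"))
})

test_that("graph measures agree with brute-force oracles on small graphs", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:8, 1)
    repeat {
      adj <- matrix(0L, n, n)
      adj[upper.tri(adj)] <- as.integer(stats::runif(choose(n, 2)) < 0.5)
      adj <- adj + t(adj)
      if (sum(adj) > 0) break
    }
    expect_equal(global_efficiency(adj), oracle_efficiency(adj))
    expect_equal(as.numeric(characteristic_path_length(adj)),
                 oracle_cpl(adj))
    expect_equal(graph_transitivity(adj), oracle_transitivity(adj))
    expect_equal(as.numeric(graph_modularity(adj, n_restarts = 30,
                                             seed = seed)),
                 oracle_modularity(adj), tolerance = 1e-12)
  }
})

test_that("measures are invariant to node relabelling", {
  m <- random_modular_matrix(10, 2, seed = 4)
  adj <- threshold_matrix(m, 0.3)
  set.seed(1); perm <- sample(10)
  adj_p <- adj[perm, perm]
  expect_equal(global_efficiency(adj_p), global_efficiency(adj))
  expect_equal(as.numeric(characteristic_path_length(adj_p)),
               as.numeric(characteristic_path_length(adj)))
  expect_equal(graph_transitivity(adj_p), graph_transitivity(adj))
  expect_equal(as.numeric(graph_modularity(adj_p, n_restarts = 30, seed = 1)),
               as.numeric(graph_modularity(adj, n_restarts = 30, seed = 1)))
})

test_that("thresholding permutes consistently with its input", {
  m <- random_modular_matrix(9, 3, seed = 2)
  set.seed(2); perm <- sample(9)
  expect_equal(unname(threshold_matrix(m[perm, perm], 0.25)),
               unname(threshold_matrix(m, 0.25)[perm, perm]))
})

test_that("gce scan: efficiency bounds, interior maximum, brute-force argmax", {
  m <- random_modular_matrix(16, 4, seed = 7)
  scan <- gce_scan(m)
  expect_true(all(scan$scan$gce <= scan$scan$efficiency))
  expect_true(all(scan$scan$efficiency <= 1))
  expect_equal(scan$scan$gce, scan$scan$efficiency - scan$scan$cost)
  # economical modular weight matrix: positive interior maximum
  expect_gt(max(scan$scan$gce), 0)
  grid <- scan$scan$cost
  opt <- scan$optimal_cost
  expect_true(opt > min(grid) && opt < max(grid))
  # brute force recomputation without the scan object
  brute <- vapply(grid, function(cc)
    oracle_efficiency(threshold_matrix(m, cc)) - cc, numeric(1))
  expect_equal(opt, grid[which.max(brute)])
  expect_error(gce_scan(m, numeric(0)), "empty")
})

test_that("gce at cost 1 equals efficiency minus one (non-positive)", {
  m <- random_modular_matrix(8, 2, seed = 3)
  adj <- threshold_matrix(m, 1)
  expect_lte(global_efficiency(adj) - 1, 0)
})

test_that("subject features average across runs and keep per-run values", {
  m1 <- random_modular_matrix(12, 3, seed = 1)
  gf_same <- subject_features(list(m1, m1, m1), cost = 0.2, n_restarts = 20)
  expect_equal(unname(gf_same$mean["modularity"]),
               gf_same$per_run$modularity[1])
  expect_equal(nrow(gf_same$per_run), 3)

  gf_single <- subject_features(list(m1), cost = 0.2, n_restarts = 20)
  expect_equal(unname(gf_single$mean["transitivity"]),
               gf_single$per_run$transitivity[1])

  m2 <- random_modular_matrix(10, 2, seed = 2)
  expect_error(subject_features(list(m1, m2), cost = 0.2),
               "inconsistent")
})
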