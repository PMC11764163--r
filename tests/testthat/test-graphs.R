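test_that("time-averaged connectivity is mean |dPL| with unit diagonal", {
  set.seed(31)
  theta <- matrix(runif(4 * 30, -pi, pi), 4, 30)
  dpl <- compute_dpl(phase_tensor(theta))
  conn <- time_average_connectivity(dpl)
  v <- conn$values
  expect_equal(v, t(v))
  expect_equal(diag(v), rep(1, 4))
  expect_true(all(v >= 0 & v <= 1 + 1e-12))
  expect_equal(v[2, 3], mean(abs(cos(theta[2, ] - theta[3, ]))),
               tolerance = 1e-12)
})

test_that("absolute thresholding keeps strictly supra-threshold pairs", {
  conn <- diag(4) * 0 + 0.1
  conn[1, 2] <- conn[2, 1] <- 0.5
  conn[3, 4] <- conn[4, 3] <- 0.2   # exactly at the cutoff: excluded
  diag(conn) <- 1
  g <- build_graph(conn, "absolute", 0.2)
  expect_equal(igraph::ecount(g), 1)
  e <- igraph::as_data_frame(g)
  expect_identical(sort(c(e$from, e$to)), sort(ten_twenty_labels(4)[1:2]))
  expect_equal(e$weight, 0.5)
  # all vertices kept even when isolated
  expect_equal(igraph::vcount(g), 4)
  expect_error(build_graph(conn, "absolute", 1.5), "cutoff")
})

test_that("proportional thresholding keeps the documented edge count", {
  set.seed(32)
  n <- 8
  conn <- matrix(runif(n * n), n, n)
  conn <- (conn + t(conn)) / 2; diag(conn) <- 1
  g <- build_graph(conn, "proportional", 0.2)
  expect_equal(igraph::ecount(g), ceiling(0.2 * n * (n - 1) / 2))
  # the kept edges are the strongest ones
  w <- conn[upper.tri(conn)]
  kept <- sort(igraph::E(g)$weight, decreasing = TRUE)
  expect_equal(kept, sort(w, decreasing = TRUE)[seq_along(kept)])
  expect_error(build_graph(conn, "proportional", 0), "fraction")
})

test_that("clustering, path length and degree match brute-force oracles", {
  set.seed(33)
  for (i in 1:60) {
    n <- sample(3:10, 1)
    adj <- random_adjacency(n, runif(1, 0.15, 0.8))
    g <- graph_from_adjacency(adj)
    cc <- clustering_coefficient(g)
    expect_equal(unname(cc$per_node), oracle_clustering(adj),
                 tolerance = 1e-12)
    expect_equal(cc$average, mean(oracle_clustering(adj)), tolerance = 1e-12)
    expect_equal(unname(degree_stats(g)$degrees), oracle_degrees(adj))
    cpl <- characteristic_path_length(g)
    oracle <- oracle_cpl(adj)
    if (is.nan(oracle)) expect_true(is.nan(cpl))
    else expect_equal(cpl, oracle, tolerance = 1e-12)
  }
})

test_that("disconnected graphs report NaN path length and component count", {
  adj <- matrix(0, 5, 5)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[3, 4] <- adj[4, 3] <- 1
  g <- graph_from_adjacency(adj)
  expect_true(is.nan(characteristic_path_length(g)))
  rec <- graph_metrics(g)
  expect_true(is.nan(rec$char_path_length))
  expect_equal(rec$n_components, 3)
})

test_that("modularity equals the definition on the returned membership", {
  set.seed(34)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.7))
    if (sum(adj) == 0) next
    g <- graph_from_adjacency(adj)
    mod <- graph_modularity(g)
    expect_equal(mod$q, oracle_modularity_q(adj, as.integer(mod$membership)),
                 tolerance = 1e-12)
  }
  # edgeless graphs are flagged undefined rather than scored
  g0 <- graph_from_adjacency(matrix(0, 4, 4))
  expect_true(is.na(graph_modularity(g0)$q))
})

test_that("greedy modularity is near-optimal and exact on a two-clique graph", {
  # two triangles joined by one edge: optimum is the two-community split
  adj <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
  }
  g <- graph_from_adjacency(adj)
  mod <- graph_modularity(g)
  expect_equal(mod$q, oracle_best_modularity(adj), tolerance = 1e-12)
  expect_identical(mod$n_communities, 2L)
  m <- as.integer(mod$membership)
  expect_identical(length(unique(m[1:3])), 1L)
  expect_identical(length(unique(m[4:6])), 1L)
})

test_that("graph records compare across conditions with Bonferroni control", {
  mk <- function(cond, shift) {
    lapply(1:5, function(i) {
      structure(list(mean_connectivity = 0.4 + shift + i / 100,
                     avg_clustering = 0.5 + i / 50,
                     char_path_length = if (i == 1 && cond == "A") NaN
                     else 1.8 + i / 20,
                     degrees = NULL, mean_degree = 3 + i / 10,
                     modularity_q = 0.3 + i / 30,
                     n_components = 1, subject_id = sprintf("S%02d", i),
                     condition = cond), class = "leida_graph_record")
    })
  }
  out <- compare_graph_conditions(mk("A", 0), mk("B", 0.3))
  expect_identical(out$metric,
                   c("mean_connectivity", "avg_clustering", "char_path_length",
                     "mean_degree", "modularity_q"))
  row <- out[out$metric == "mean_connectivity", ]
  expect_gt(row$t, 0)                    # B above A
  expect_lt(row$p_bonferroni, 0.05)
  expect_true(all(out$p_bonferroni >= out$p_raw, na.rm = TRUE))
  # the NaN path length is excluded and counted
  cpl <- out[out$metric == "char_path_length", ]
  expect_identical(cpl$n_excluded, 1L)
  expect_identical(cpl$n_a, 4L)
  # identical groups give t near zero and p near one
  same <- compare_graph_conditions(mk("A", 0), mk("B", 0))
  expect_equal(same[same$metric == "avg_clustering", "t"], 0)
})

test_that("metrics from thresholded dPL connectivity are finite on synthetic data", {
  cfg <- synth_config(n_subjects = 1, n_channels = 6, n_samples = 400,
                      n_states = 2, seed = 12)
  d <- generate_dataset(cfg)
  dpl <- epoch_to_dpl(d$epochs[[1]], decimate = 4, edge = 25)
  conn <- time_average_connectivity(dpl)
  g <- build_graph(conn, "absolute", 0.2)
  rec <- graph_metrics(g, conn)
  expect_true(is.finite(rec$mean_connectivity))
  expect_true(is.finite(rec$avg_clustering))
  expect_true(is.finite(rec$mean_degree))
  expect_identical(rec$subject_id, "S01")
  tab <- graph_records_table(list(rec))
  expect_identical(nrow(tab), 1L)
})
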