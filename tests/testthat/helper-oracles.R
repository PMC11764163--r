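# Brute-force graph oracles, independent of igraph, for cross-checking the
# graph metrics. All take a binary symmetric adjacency matrix (zero diagonal).

oracle_degrees <- function(adj) rowSums(adj)

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        links <- links + adj[nb[a], nb[b]]
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# all-pairs shortest hop counts by breadth-first search
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (dist[w] > d) {
            dist[w] <- d
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_cpl <- function(adj) {
  D <- oracle_distances(adj)
  off <- D[upper.tri(D)]
  if (any(is.infinite(off))) return(NaN)
  mean(off)
}

# modularity of a given membership vector, straight from the definition
oracle_modularity_q <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  k <- rowSums(adj)
  same <- outer(membership, membership, "==")
  sum((adj - outer(k, k) / (2 * m)) * same) / (2 * m)
}

# all set partitions of n items as membership vectors (Bell-number growth;
# keep n small)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    g <- max(p)
    for (j in seq_len(g + 1)) out[[length(out) + 1]] <- c(p, j)
  }
  out
}

oracle_best_modularity <- function(adj) {
  best <- -Inf
  for (p in all_partitions(nrow(adj))) {
    q <- oracle_modularity_q(adj, p)
    if (q > best) best <- q
  }
  best
}

random_adjacency <- function(n, p_edge) {
  adj <- matrix(0, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(stats::runif(length(up)) < p_edge)
  adj + t(adj)
}

graph_from_adjacency <- function(adj) {
  labels <- leidar::ten_twenty_labels(nrow(adj))
  conn <- adj * 0.5
  diag(conn) <- 1
  leidar::build_graph(conn, mode = "absolute", value = 0.2)
}

# Benchmark generator settings shared by the recovery / separability tests.
# Three planted states; in the "separable" variant state 3 is almost absent in
# condition A (entry rate 0.005) and almost permanent in condition B (boosted
# self-transition), so per-time-point condition classification is possible.
separable_transitions <- function() {
  rbind(c(0.895, 0.100, 0.005),
        c(0.100, 0.895, 0.005),
        c(0.250, 0.250, 0.500))
}

separable_config <- function() {
  leidar::synth_config(
    n_subjects = 12, n_channels = 8, n_samples = 2000,
    n_states = 3, transition_matrix = separable_transitions(),
    boost_state = 3, occupancy_boost = 10000,
    phase_noise_kappa = 200, amplitude_noise_sd = 0.1, seed = 11)
}

recovery_config <- function() {
  leidar::synth_config(n_subjects = 12, n_channels = 8, n_samples = 2000,
                       n_states = 3, seed = 21)
}

# band-pass + Hilbert + dPL + leading eigenvector for one epoch
epoch_to_eigs <- function(epoch, decimate = 5, edge = 50) {
  ph <- leidar::instantaneous_phase(leidar::bandpass_filter(epoch, 1, 40))
  leidar::leading_eigenvector(
    leidar::compute_dpl(ph, decimate = decimate, edge_samples = edge))
}

epoch_to_dpl <- function(epoch, decimate = 5, edge = 50) {
  ph <- leidar::instantaneous_phase(leidar::bandpass_filter(epoch, 1, 40))
  leidar::compute_dpl(ph, decimate = decimate, edge_samples = edge)
}

# planted state label of every pooled row, via each epoch's retained sample
# indices
true_labels_for_pool <- function(pool, dataset) {
  key <- paste0(pool$index$subject, "_", pool$index$condition)
  vapply(seq_len(nrow(pool$index)), function(i) {
    dataset$true_states[[key[i]]][pool$index$time[i]]
  }, integer(1))
}

# a small random phase tensor container with arbitrary symmetric slices, for
# oracle checks of the eigenvector stage
random_symmetric_dpl <- function(n, t_len) {
  arr <- array(0, dim = c(n, n, t_len))
  for (t in seq_len(t_len)) {
    m <- matrix(stats::rnorm(n * n), n, n)
    arr[, , t] <- (m + t(m)) / 2
  }
  structure(list(dpl = arr, channel_labels = leidar::ten_twenty_labels(n),
                 time_index = seq_len(t_len), sampling_rate = 1,
                 decimate = 1, subject_id = "S01", condition = "A"),
            class = "leida_dpl")
}
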