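#' Time-averaged connectivity matrix
#'
#' Collapses a dynamic phase-locking tensor to a static pairwise
#' synchronisation matrix: entry (n, p) is the time mean of |dPL(n, p, t)|,
#' a phase-locking-value-style quantity in \[0, 1\] with unit diagonal.
#'
#' @param dpl A `leida_dpl`.
#' @return Object of class `leida_conn`: `values` (N x N symmetric matrix),
#'   `channel_labels`, `subject_id`, `condition`.
#' @export
time_average_connectivity <- function(dpl) {
  N <- dim(dpl$dpl)[1]
  m <- matrix(abs(dpl$dpl), N * N, dim(dpl$dpl)[3])
  values <- matrix(rowMeans(m), N, N)
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(list(values = values, channel_labels = dpl$channel_labels,
                 subject_id = dpl$subject_id, condition = dpl$condition),
            class = "leida_conn")
}

#' Threshold a connectivity matrix into an undirected weighted graph
#'
#' Absolute mode keeps channel pairs whose connectivity exceeds a cutoff
#' (default 0.2); proportional mode keeps the top fraction `q` of the
#' strongest pairs (default 0.20, i.e. the top 20% of connections), ties
#' broken by ascending channel-index pair order.
#'
#' @param conn A `leida_conn` (or plain symmetric matrix).
#' @param mode `"absolute"` or `"proportional"`.
#' @param value Cutoff in \[0, 1\] (absolute) or fraction in (0, 1\]
#'   (proportional).
#' @return An `igraph` undirected graph with edge attribute `weight` and
#'   graph attributes `threshold_mode`, `threshold_value`, plus the epoch
#'   metadata.
#' @export
build_graph <- function(conn, mode = c("absolute", "proportional"),
                        value = 0.2) {
  mode <- match.arg(mode)
  vals <- if (inherits(conn, "leida_conn")) conn$values else conn
  labels <- if (inherits(conn, "leida_conn")) conn$channel_labels else
    ten_twenty_labels(nrow(vals))
  N <- nrow(vals)
  ij <- which(upper.tri(vals), arr.ind = TRUE)
  w <- vals[ij]
  if (mode == "absolute") {
    if (value < 0 || value > 1) stop("parameter error: cutoff must lie in [0, 1]")
    keep <- w > value
  } else {
    if (value <= 0 || value > 1) stop("parameter error: fraction must lie in (0, 1]")
    m_edges <- ceiling(value * N * (N - 1) / 2)
    ord <- order(-w, ij[, 1], ij[, 2])
    keep <- logical(length(w))
    keep[ord[seq_len(min(m_edges, length(w)))]] <- TRUE
  }
  edges <- data.frame(from = labels[ij[keep, 1]], to = labels[ij[keep, 2]],
                      weight = w[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = labels))
  g <- igraph::set_graph_attr(g, "threshold_mode", mode)
  g <- igraph::set_graph_attr(g, "threshold_value", value)
  if (inherits(conn, "leida_conn")) {
    g <- igraph::set_graph_attr(g, "subject_id", conn$subject_id)
    g <- igraph::set_graph_attr(g, "condition", conn$condition)
  }
  g
}

#' Local clustering coefficients
#'
#' Binary (unweighted) local clustering coefficient per node — triangles
#' through the node over possible triangles among its neighbours; nodes with
#' degree < 2 score 0 — and their average.
#'
#' @param graph An `igraph` graph from [build_graph()].
#' @return List with `per_node` (named numeric) and `average`.
#' @export
clustering_coefficient <- function(graph) {
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  names(cc) <- igraph::V(graph)$name
  list(per_node = cc, average = mean(cc))
}

#' Characteristic path length
#'
#' Mean unweighted shortest-path hop count over all reachable node pairs;
#' `NaN` (undefined) when the graph is disconnected.
#'
#' @param graph An `igraph` graph.
#' @return Numeric scalar, or `NaN` for disconnected graphs.
#' @export
characteristic_path_length <- function(graph) {
  if (igraph::vcount(graph) < 2) return(NaN)
  if (igraph::components(graph)$no > 1) return(NaN)
  igraph::mean_distance(graph, directed = FALSE, weights = NA)
}

#' Node degrees and mean degree
#' @param graph An `igraph` graph.
#' @return List with `degrees` (named integer) and `mean_degree`.
#' @export
degree_stats <- function(graph) {
  d <- igraph::degree(graph)
  list(degrees = d, mean_degree = mean(d))
}

#' Greedy modularity maximisation
#'
#' Clauset-Newman-Moore style greedy agglomeration on the binarised graph;
#' the returned partition is the cut of the merge hierarchy with the highest
#' modularity, so `q` is always the modularity of `membership`. Deterministic;
#' the seed is accepted for interface symmetry with the other stages.
#'
#' @param graph An `igraph` graph with at least one edge.
#' @param seed Unused beyond determinism bookkeeping.
#' @return List with `q` (modularity of the best partition; `NA` flagged for
#'   edgeless graphs), `membership` (named integer communities),
#'   `n_communities`.
#' @export
graph_modularity <- function(graph, seed = 1) {
  if (igraph::ecount(graph) == 0) {
    return(list(q = NA_real_, membership = NULL, n_communities = NA_integer_,
                flagged = "edgeless graph: modularity undefined"))
  }
  set.seed(derive_seed(seed, "modularity"))
  gs <- igraph::simplify(graph)
  cl <- igraph::cluster_fast_greedy(gs, weights = NA)
  # walk the merge hierarchy and keep the cut with the highest (unweighted)
  # modularity; the hierarchy's own membership can disagree with its best cut
  ones <- rep(1, igraph::ecount(gs))
  best_q <- -Inf
  best_mem <- NULL
  for (no in seq_len(igraph::vcount(gs))) {
    mem <- tryCatch(suppressWarnings(igraph::cut_at(cl, no = no)),
                    error = function(e) NULL)
    # cuts below the number of components are unreachable
    if (is.null(mem) || anyNA(mem)) next
    q <- igraph::modularity(gs, mem, weights = ones)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_mem <- mem
    }
  }
  names(best_mem) <- igraph::V(gs)$name
  list(q = best_q, membership = best_mem,
       n_communities = length(unique(best_mem)))
}

#' Full graph-metric record for one epoch
#'
#' @param graph An `igraph` graph from [build_graph()].
#' @param conn The `leida_conn` the graph was built from (for
#'   `mean_connectivity`).
#' @param seed Passed to [graph_modularity()].
#' @return Object of class `leida_graph_record`: mean_connectivity,
#'   avg_clustering, char_path_length (NaN if disconnected), mean_degree,
#'   degrees, modularity_q, n_components, subject_id, condition.
#' @export
graph_metrics <- function(graph, conn = NULL, seed = 1) {
  mean_conn <- if (!is.null(conn)) {
    v <- if (inherits(conn, "leida_conn")) conn$values else conn
    mean(v[upper.tri(v)])
  } else NA_real_
  cc <- clustering_coefficient(graph)
  deg <- degree_stats(graph)
  mod <- graph_modularity(graph, seed = seed)
  structure(list(
    mean_connectivity = mean_conn,
    avg_clustering = cc$average,
    char_path_length = characteristic_path_length(graph),
    degrees = deg$degrees,
    mean_degree = deg$mean_degree,
    modularity_q = mod$q,
    n_components = igraph::components(graph)$no,
    subject_id = igraph::graph_attr(graph, "subject_id") %||% NA_character_,
    condition = igraph::graph_attr(graph, "condition") %||% NA_character_
  ), class = "leida_graph_record")
}

#' Bind graph-metric records into a tidy data frame
#' @param records List of `leida_graph_record`.
#' @return Data frame, one row per record.
#' @export
graph_records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(subject = r$subject_id, condition = r$condition,
               mean_connectivity = r$mean_connectivity,
               avg_clustering = r$avg_clustering,
               char_path_length = r$char_path_length,
               mean_degree = r$mean_degree,
               modularity_q = r$modularity_q,
               n_components = r$n_components)
  }))
}

#' Compare graph metrics between two conditions
#'
#' Welch t test per metric (mean connectivity, average clustering,
#' characteristic path length, mean degree, modularity Q) between the
#' condition-A and condition-B record sets, Bonferroni-adjusted over the
#' number of metrics actually tested. Records with undefined path length are
#' excluded from that metric and the exclusion count is reported; a metric
#' with fewer than two defined values per group is skipped.
#'
#' @param records_a,records_b Lists of `leida_graph_record` (or data frames
#'   from [graph_records_table()]).
#' @return Data frame: metric, t, p_raw, p_bonferroni, n_a, n_b, n_excluded,
#'   skipped.
#' @export
compare_graph_conditions <- function(records_a, records_b) {
  ta <- if (is.data.frame(records_a)) records_a else graph_records_table(records_a)
  tb <- if (is.data.frame(records_b)) records_b else graph_records_table(records_b)
  metrics <- c("mean_connectivity", "avg_clustering", "char_path_length",
               "mean_degree", "modularity_q")
  rows <- list()
  for (m in metrics) {
    xa <- ta[[m]]; xb <- tb[[m]]
    n_excl <- sum(!is.finite(xa)) + sum(!is.finite(xb))
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    if (length(xa) < 2 || length(xb) < 2) {
      rows[[m]] <- data.frame(metric = m, t = NA_real_, p_raw = NA_real_,
                              n_a = length(xa), n_b = length(xb),
                              n_excluded = n_excl, skipped = TRUE)
      next
    }
    t_stat <- two_sample_t(xa, xb)
    p <- if (is.finite(t_stat)) {
      if (stats::var(xa) + stats::var(xb) == 0) 1
      else stats::t.test(xb, xa)$p.value
    } else 0
    rows[[m]] <- data.frame(metric = m, t = t_stat, p_raw = p,
                            n_a = length(xa), n_b = length(xb),
                            n_excluded = n_excl, skipped = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tested <- !out$skipped
  out$p_bonferroni <- NA_real_
  if (any(tested)) out$p_bonferroni[tested] <- bonferroni_adjust(out$p_raw[tested])
  out
}

#' Write a connectivity matrix as TSV with a channel-label header
#' @param conn A `leida_conn`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_connectivity <- function(conn, path) {
  df <- as.data.frame(conn$values)
  names(df) <- conn$channel_labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
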