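#' Pool leading-eigenvector series across epochs
#'
#' Concatenates the V1(t) rows of several epochs into one matrix, in
#' deterministic (subject, condition, time) order, with a full per-row index.
#'
#' @param series List of `leida_eigs` objects sharing channel labels.
#' @return Object of class `leida_pool`: `vectors` (M x N) and `index`
#'   (data frame with columns subject, condition, time).
#' @export
pool_eigenvectors <- function(series) {
  if (inherits(series, "leida_eigs")) series <- list(series)
  stopifnot(length(series) >= 1)
  ref <- series[[1]]$channel_labels
  for (s in series) {
    if (!identical(s$channel_labels, ref)) {
      stop("input error: channel-label mismatch across epochs")
    }
  }
  idx <- do.call(rbind, lapply(series, function(s) {
    data.frame(subject = s$subject_id, condition = s$condition,
               time = s$time_index)
  }))
  vecs <- do.call(rbind, lapply(series, function(s) s$vectors))
  ord <- order(idx$subject, idx$condition, idx$time)
  structure(list(vectors = vecs[ord, , drop = FALSE],
                 index = idx[ord, , drop = FALSE],
                 channel_labels = ref),
            class = "leida_pool")
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance from the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  M <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(M, 1)
  centers[1, ] <- x[i, ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        i <- sample.int(M, 1)
      } else {
        i <- sample.int(M, 1, prob = d2)
      }
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Cluster pooled eigenvectors into phase-locking states
#'
#' Best-of-`n_init` k-means (Lloyd iterations over Euclidean distance, which
#' on unit-norm vectors is monotone in cosine distance) with k-means++
#' seeding. States are renumbered by descending total occupancy, so state 1
#' is always the most visited.
#'
#' @param pool A `leida_pool`.
#' @param k Number of states.
#' @param n_init Number of seeded restarts; the solution with the lowest
#'   within-cluster sum of squares is kept.
#' @param seed Integer seed; the run is deterministic given it.
#' @return Object of class `leida_states`: `k`, `centroids` (k x N),
#'   `labels` (per pooled row, in 1..k), `inertia`, `sizes`, `seed`,
#'   `n_redraws` (restarts redrawn after an empty cluster).
#' @export
cluster_eigenvectors <- function(pool, k, n_init = 20, seed = 1) {
  x <- pool$vectors
  M <- nrow(x)
  if (k < 1) stop("parameter error: k must be >= 1")
  if (k > M) stop("parameter error: k exceeds the number of pooled vectors")
  set.seed(derive_seed(seed, "kmeans"))
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    # degenerate pool: fewer distinct rows than clusters
    ux <- unique(x)
    labels <- apply(x, 1, function(r) {
      which.min(colSums((t(ux) - r)^2))
    })
    centroids <- rbind(ux, ux[rep(1, k - n_distinct), , drop = FALSE])
    fit <- list(cluster = labels, centers = centroids, tot.withinss = 0)
    n_redraws <- 0L
  } else {
    best <- NULL
    n_redraws <- 0L
    for (i in seq_len(n_init)) {
      fit <- NULL
      attempts <- 0L
      while (is.null(fit) && attempts < 50L) {
        attempts <- attempts + 1L
        centers <- kmeanspp_centers(x, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = 100,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit) && any(fit$size == 0)) fit <- NULL
      }
      n_redraws <- n_redraws + attempts - 1L
      if (is.null(fit)) stop("numerical error: k-means failed to find ", k,
                             " non-empty clusters")
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    fit <- best
  }
  # renumber by descending occupancy (cluster size), ties by original id
  sizes <- tabulate(fit$cluster, nbins = k)
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  structure(list(k = as.integer(k),
                 centroids = unname(fit$centers[ord, , drop = FALSE]),
                 labels = remap[fit$cluster],
                 inertia = fit$tot.withinss,
                 sizes = sizes[ord],
                 channel_labels = pool$channel_labels,
                 seed = as.integer(seed), n_init = as.integer(n_init),
                 n_redraws = n_redraws),
            class = "leida_states")
}

#' @export
print.leida_states <- function(x, ...) {
  cat(sprintf("<leida_states> k = %d, inertia = %.4g, sizes: %s\n",
              x$k, x$inertia, paste(x$sizes, collapse = " ")))
  invisible(x)
}

#' Survey clustering solutions over a range of k
#'
#' Fits one best-of-restarts k-means model per requested `k` and reports its
#' within-cluster sum of squares and mean silhouette width. No automatic
#' selection is made; k = 8 is the configured default of the headline
#' analysis.
#'
#' @param pool A `leida_pool`.
#' @param k_range Integer vector of cluster counts.
#' @param n_init,seed Passed to [cluster_eigenvectors()].
#' @param silhouette_max Silhouette width is computed on a seeded subsample of
#'   at most this many rows (a full distance matrix over large pools is
#'   avoided).
#' @return Data frame with columns `k`, `inertia`, `silhouette`.
#' @export
scan_k <- function(pool, k_range, n_init = 20, seed = 1,
                   silhouette_max = 2000) {
  if (length(k_range) < 1) stop("parameter error: empty k_range")
  M <- nrow(pool$vectors)
  set.seed(derive_seed(seed, "silhouette"))
  sub <- if (M > silhouette_max) sort(sample.int(M, silhouette_max)) else seq_len(M)
  d_sub <- stats::dist(pool$vectors[sub, , drop = FALSE])
  out <- lapply(sort(unique(as.integer(k_range))), function(k) {
    model <- cluster_eigenvectors(pool, k, n_init = n_init, seed = seed)
    sil <- NA_real_
    if (k >= 2 && length(unique(model$labels[sub])) >= 2) {
      sw <- cluster::silhouette(model$labels[sub], d_sub)
      sil <- mean(sw[, "sil_width"])
    }
    data.frame(k = k, inertia = model$inertia, silhouette = sil)
  })
  do.call(rbind, out)
}

#' Occupancy, dwell time and transition statistics per subject and condition
#'
#' Occupancy is the fraction of time points assigned to each state within a
#' subject-condition epoch; dwell time is the mean length of consecutive runs
#' of the same state (runs truncate at epoch boundaries); transitions are
#' empirical next-step frequencies within epochs (rows for unvisited states
#' are `NA`).
#'
#' @param model A `leida_states`.
#' @param pool The `leida_pool` the model was fitted on.
#' @param sampling_rate Optional sampling rate (Hz) of the underlying
#'   recording; with `decimate`, converts dwell steps to seconds.
#' @param decimate Decimation factor used when the eigenvector series was
#'   computed.
#' @return Object of class `leida_metrics`: data frames `occupancy`
#'   (subject, condition, state, occupancy), `dwell` (+ dwell_steps,
#'   dwell_seconds) and `transitions` (subject, condition, from, to, prob),
#'   plus `k`.
#' @export
compute_state_metrics <- function(model, pool, sampling_rate = NULL,
                                  decimate = 1) {
  if (length(model$labels) != nrow(pool$vectors)) {
    stop("input error: labels do not cover the pool")
  }
  k <- model$k
  idx <- pool$index
  key <- paste(idx$subject, idx$condition, sep = "\r")
  groups <- split(seq_len(nrow(idx)), key)
  occ_rows <- list(); dwell_rows <- list(); trans_rows <- list()
  for (g in names(groups)) {
    rows <- groups[[g]]
    if (length(rows) == 0) stop("input error: subject x condition with zero time points")
    rows <- rows[order(idx$time[rows])]
    lab <- model$labels[rows]
    subj <- idx$subject[rows[1]]
    cond <- idx$condition[rows[1]]
    occ <- tabulate(lab, nbins = k) / length(lab)
    occ_rows[[g]] <- data.frame(subject = subj, condition = cond,
                                state = seq_len(k), occupancy = occ)
    r <- rle(lab)
    dwell <- vapply(seq_len(k), function(s) {
      runs <- r$lengths[r$values == s]
      if (length(runs) == 0) NA_real_ else mean(runs)
    }, numeric(1))
    dwell_sec <- if (is.null(sampling_rate)) rep(NA_real_, k) else
      dwell * decimate / sampling_rate
    dwell_rows[[g]] <- data.frame(subject = subj, condition = cond,
                                  state = seq_len(k), dwell_steps = dwell,
                                  dwell_seconds = dwell_sec)
    tr <- matrix(0, k, k)
    if (length(lab) > 1) {
      for (t in seq_len(length(lab) - 1)) {
        tr[lab[t], lab[t + 1]] <- tr[lab[t], lab[t + 1]] + 1
      }
    }
    rs <- rowSums(tr)
    prob <- tr / ifelse(rs > 0, rs, NA_real_)
    trans_rows[[g]] <- data.frame(subject = subj, condition = cond,
                                  from = rep(seq_len(k), times = k),
                                  to = rep(seq_len(k), each = k),
                                  prob = as.vector(prob))
  }
  structure(list(
    occupancy = do.call(rbind, c(occ_rows, list(make.row.names = FALSE))),
    dwell = do.call(rbind, c(dwell_rows, list(make.row.names = FALSE))),
    transitions = do.call(rbind, c(trans_rows, list(make.row.names = FALSE))),
    k = k
  ), class = "leida_metrics")
}

#' Export / import a state model as JSON
#' @param model A `leida_states`.
#' @param path JSON file path.
#' @return Invisibly, `path` (writer); a `leida_states` (reader). The row
#'   labels are not serialised (they are a property of the fitted pool).
#' @export
write_state_model <- function(model, path) {
  out <- list(k = model$k, seed = model$seed, n_init = model$n_init,
              inertia = model$inertia, sizes = model$sizes,
              channel_labels = model$channel_labels,
              centroids = unname(apply(model$centroids, 1, c,
                                       simplify = FALSE)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_model
#' @export
read_state_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = x$k,
                 centroids = if (is.list(x$centroids))
                   do.call(rbind, x$centroids) else x$centroids,
                 labels = NULL, inertia = x$inertia, sizes = x$sizes,
                 channel_labels = x$channel_labels, seed = x$seed,
                 n_init = x$n_init, n_redraws = NA_integer_),
            class = "leida_states")
}

#' Assign new eigenvectors to the nearest state centroid
#' @param model A `leida_states`.
#' @param vectors T x N matrix of unit-norm eigenvectors.
#' @return Integer state labels in 1..k.
#' @export
assign_states <- function(model, vectors) {
  cross <- vectors %*% t(model$centroids)
  c2 <- rowSums(model$centroids^2)
  d2 <- outer(rowSums(vectors^2), c2, "+") - 2 * cross
  max.col(-d2, ties.method = "first")
}
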