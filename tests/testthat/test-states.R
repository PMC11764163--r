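make_blob_pool <- function(centers, n_per, sd = 0.05, seed = 1) {
  set.seed(seed)
  vecs <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    m <- matrix(rnorm(n_per * ncol(centers), sd = sd), n_per)
    sweep(m, 2, centers[i, ], "+")
  }))
  n <- nrow(vecs)
  structure(list(vectors = vecs,
                 index = data.frame(subject = "S01", condition = "A",
                                    time = seq_len(n)),
                 channel_labels = ten_twenty_labels(ncol(centers))),
            class = "leida_pool")
}

test_that("pool_eigenvectors orders rows by subject, condition, time", {
  mk <- function(subj, cond, times) {
    structure(list(vectors = matrix(times, length(times), 2),
                   eigenvalues = times, channel_labels = c("C3", "C4"),
                   time_index = times, sampling_rate = 1, decimate = 1,
                   subject_id = subj, condition = cond,
                   sign_convention = "majority-negative"),
              class = "leida_eigs")
  }
  pool <- pool_eigenvectors(list(mk("S02", "A", 1:2), mk("S01", "B", 1:2),
                                 mk("S01", "A", c(3, 1))))
  expect_identical(pool$index$subject, c("S01", "S01", "S01", "S01", "S02", "S02"))
  expect_identical(pool$index$condition, c("A", "A", "B", "B", "A", "A"))
  expect_identical(pool$index$time, c(1, 3, 1, 2, 1, 2))
  bad <- mk("S03", "A", 1:2); bad$channel_labels <- c("X", "Y")
  expect_error(pool_eigenvectors(list(mk("S01", "A", 1:2), bad)), "mismatch")
})

test_that("k-means recovers well-separated blobs and orders states by occupancy", {
  centers <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  pool <- make_blob_pool(centers, n_per = c(60), seed = 2)
  # unequal blob sizes: 60 / 40 / 20
  pool2 <- make_blob_pool(centers, 20, seed = 3)
  vecs <- rbind(pool$vectors[1:60, ], pool$vectors[61:100, ], pool2$vectors[41:60, ])
  pool$vectors <- vecs
  pool$index <- data.frame(subject = "S01", condition = "A",
                           time = seq_len(nrow(vecs)))
  model <- cluster_eigenvectors(pool, 3, n_init = 5, seed = 4)
  expect_identical(model$sizes, c(60L, 40L, 20L))
  # state 1 must be the biggest blob's
  expect_equal(model$centroids[1, ], centers[1, ], tolerance = 0.05)
  expect_equal(model$centroids[3, ], centers[3, ], tolerance = 0.05)
  # determinism given the seed
  model2 <- cluster_eigenvectors(pool, 3, n_init = 5, seed = 4)
  expect_identical(model$labels, model2$labels)
  expect_identical(model$inertia, model2$inertia)
})

test_that("clustering handles degenerate pools with fewer distinct rows than k", {
  pool <- structure(list(vectors = matrix(rep(c(1, 0), each = 5), 10, 2),
                         index = data.frame(subject = "S01", condition = "A",
                                            time = 1:10),
                         channel_labels = c("C3", "C4")),
                    class = "leida_pool")
  pool$vectors <- rbind(matrix(1, 6, 2), matrix(0, 4, 2))
  model <- cluster_eigenvectors(pool, 3, seed = 1)
  expect_identical(model$inertia, 0)
  expect_identical(length(unique(model$labels)), 2L)
  expect_error(cluster_eigenvectors(pool, 0), "k must be")
  expect_error(cluster_eigenvectors(pool, 99), "exceeds")
})

test_that("scan_k reports decreasing inertia and silhouettes", {
  centers <- rbind(c(1, 0), c(-1, 0), c(0, 1.5))
  pool <- make_blob_pool(centers, 40, seed = 5)
  tab <- scan_k(pool, 2:4, n_init = 5, seed = 6)
  expect_identical(tab$k, 2:4)
  expect_true(all(diff(tab$inertia) < 0))
  expect_true(all(tab$silhouette > 0))
  # the planted k = 3 has the best silhouette here
  expect_identical(tab$k[which.max(tab$silhouette)], 3L)
})

test_that("occupancy, dwell and transition metrics match a hand example", {
  lab <- c(1L, 1L, 2L, 2L, 2L, 1L)
  pool <- structure(list(vectors = matrix(0, 6, 2),
                         index = data.frame(subject = "S01", condition = "A",
                                            time = 1:6),
                         channel_labels = c("C3", "C4")),
                    class = "leida_pool")
  model <- structure(list(k = 3L, labels = lab), class = "leida_states")
  m <- compute_state_metrics(model, pool, sampling_rate = 100, decimate = 2)
  expect_equal(m$occupancy$occupancy, c(3 / 6, 3 / 6, 0))
  # state 1: runs of length 2 and 1 -> 1.5 steps; state 2: one run of 3
  expect_equal(m$dwell$dwell_steps, c(1.5, 3, NA))
  expect_equal(m$dwell$dwell_seconds, c(1.5, 3, NA) * 2 / 100)
  tr <- m$transitions
  expect_equal(tr$prob[tr$from == 1 & tr$to == 1], 1 / 2)
  expect_equal(tr$prob[tr$from == 1 & tr$to == 2], 1 / 2)
  expect_equal(tr$prob[tr$from == 2 & tr$to == 2], 2 / 3)
  expect_equal(tr$prob[tr$from == 2 & tr$to == 1], 1 / 3)
  # unvisited state 3 has an all-NA transition row
  expect_true(all(is.na(tr$prob[tr$from == 3])))
  # occupancies sum to one per epoch
  expect_equal(sum(m$occupancy$occupancy), 1)
})

test_that("state model round trips through JSON", {
  centers <- rbind(c(1, 0), c(0, 1))
  pool <- make_blob_pool(centers, 30, seed = 7)
  model <- cluster_eigenvectors(pool, 2, n_init = 3, seed = 8)
  path <- tempfile(fileext = ".json")
  write_state_model(model, path)
  back <- read_state_model(path)
  expect_identical(back$k, model$k)
  expect_equal(back$centroids, model$centroids, tolerance = 1e-14)
  expect_equal(back$sizes, model$sizes)
  expect_identical(back$channel_labels, model$channel_labels)
  # assignment with the reloaded model reproduces the fitted labels
  expect_identical(assign_states(back, pool$vectors), model$labels)
  unlink(path)
})
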