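#' Build a classifier feature set
#'
#' Converts epochs into per-time-point samples for condition classification:
#' * `raw` — the channel values at each retained time point (F = N);
#' * `dpl_flat` — each dPL slice flattened row by row (F = N^2);
#' * `eigenvector` — the leading eigenvector V1(t) rows (F = N).
#'
#' Values are *not* standardised here; [train_cnn()] standardises per feature
#' using training-split statistics only.
#'
#' @param kind One of `"raw"`, `"dpl_flat"`, `"eigenvector"`.
#' @param x For `raw`, a list of [signal_epoch()]; for `dpl_flat`, a list of
#'   `leida_dpl`; for `eigenvector`, a list of `leida_eigs`.
#' @param decimate,edge_samples For `raw` only: retained-sample schedule
#'   (matching the one used for the dPL path).
#' @return Object of class `leida_features`: `kind`, `x` (M x F), `y`
#'   (0 = condition A, 1 = condition B), `group` (subject per sample),
#'   `time`, `n_channels`.
#' @export
build_features <- function(kind = c("raw", "dpl_flat", "eigenvector"), x,
                           decimate = 1, edge_samples = 0) {
  kind <- match.arg(kind)
  stopifnot(is.list(x), length(x) >= 1)
  mats <- list(); ys <- list(); gs <- list(); ts <- list()
  n_ch <- NULL
  for (i in seq_along(x)) {
    e <- x[[i]]
    if (kind == "raw") {
      stopifnot(inherits(e, "leida_epoch"))
      N <- nrow(e$data)
      idx <- seq.int(edge_samples + 1, ncol(e$data) - edge_samples,
                     by = decimate)
      m <- t(e$data[, idx, drop = FALSE])
      tt <- idx
    } else if (kind == "dpl_flat") {
      stopifnot(inherits(e, "leida_dpl"))
      N <- dim(e$dpl)[1]
      Tn <- dim(e$dpl)[3]
      m <- t(vapply(seq_len(Tn),
                    function(t) as.vector(t(e$dpl[, , t])),  # row-major
                    numeric(N * N)))
      tt <- e$time_index
    } else {
      stopifnot(inherits(e, "leida_eigs"))
      N <- ncol(e$vectors)
      m <- e$vectors
      tt <- e$time_index
    }
    if (is.null(n_ch)) n_ch <- N
    if (N != n_ch) stop("input error: mixed channel counts across epochs")
    mats[[i]] <- m
    ys[[i]] <- rep(ifelse(e$condition == "B", 1L, 0L), nrow(m))
    gs[[i]] <- rep(e$subject_id, nrow(m))
    ts[[i]] <- tt
  }
  structure(list(kind = kind, x = do.call(rbind, mats),
                 y = unlist(ys), group = unlist(gs), time = unlist(ts),
                 n_channels = n_ch),
            class = "leida_features")
}

#' Train/test split of a feature set
#'
#' Default mode is group-aware: whole subjects are assigned to one side, so
#' no subject contributes samples to both train and test. The alternative
#' (`group_aware = FALSE`) is a stratified random per-sample 80/20-style
#' split. Both classes are guaranteed present on both sides (re-drawn with a
#' warning if needed).
#'
#' @param features A `leida_features`.
#' @param test_fraction Fraction of samples (or subjects) held out.
#' @param seed Integer seed; identical seeds give identical manifests.
#' @param group_aware Keep all samples of a subject on one side.
#' @return Object of class `leida_split`: `train`, `test` (row indices),
#'   `manifest` (data frame sample/subject/label/side), `seed`,
#'   `group_aware`.
#' @export
split_data <- function(features, test_fraction = 0.2, seed = 1,
                       group_aware = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- features$y
  if (length(unique(y)) < 2) stop("input error: both classes must be present")
  set.seed(derive_seed(seed, "split"))
  M <- length(y)
  ok <- FALSE
  for (attempt in 1:20) {
    if (group_aware) {
      subs <- unique(features$group)
      n_test <- max(1L, round(length(subs) * test_fraction))
      test_subs <- sample(subs, n_test)
      test_idx <- which(features$group %in% test_subs)
    } else {
      test_idx <- unlist(lapply(unique(y), function(cl) {
        rows <- which(y == cl)
        sample(rows, max(1L, round(length(rows) * test_fraction)))
      }))
    }
    train_idx <- setdiff(seq_len(M), test_idx)
    if (length(unique(y[test_idx])) == 2 &&
        length(unique(y[train_idx])) == 2) { ok <- TRUE; break }
    warning("a class was absent from one side of the split; re-drawing")
  }
  if (!ok) stop("input error: could not produce a split with both classes on both sides")
  manifest <- data.frame(sample = seq_len(M), subject = features$group,
                         label = y, side = "train")
  manifest$side[test_idx] <- "test"
  structure(list(train = sort(train_idx), test = sort(test_idx),
                 manifest = manifest, seed = as.integer(seed),
                 group_aware = group_aware),
            class = "leida_split")
}
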