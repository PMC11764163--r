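#' Construct a signal epoch
#'
#' One multichannel recording for a single subject and condition.
#'
#' @param data Numeric channels x samples matrix (signal units).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Unique channel names; defaults to a 10-20-style
#'   montage.
#' @param subject_id Subject identifier.
#' @param condition Condition label, `"A"` (non-social-like) or `"B"`
#'   (social-like).
#' @return Object of class `leida_epoch`.
#' @export
signal_epoch <- function(data, sampling_rate,
                         channel_labels = ten_twenty_labels(nrow(data)),
                         subject_id = "S01", condition = "A") {
  stopifnot(is.matrix(data))
  if (nrow(data) < 2) stop("input error: need >= 2 channels")
  if (ncol(data) < 4) stop("input error: need >= 4 samples")
  if (!all(is.finite(data))) stop("input error: non-finite values in data")
  if (anyDuplicated(channel_labels)) stop("input error: channel labels not unique")
  if (length(channel_labels) != nrow(data)) {
    stop("input error: one label per channel required")
  }
  if (!condition %in% c("A", "B")) stop("input error: condition must be A or B")
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = as.character(channel_labels),
                 subject_id = as.character(subject_id),
                 condition = condition),
            class = "leida_epoch")
}

#' @export
print.leida_epoch <- function(x, ...) {
  cat(sprintf("<leida_epoch> %s/%s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data),
              x$sampling_rate))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Removes the per-channel mean, then applies a Butterworth band-pass
#' forward and backward (zero phase distortion) to each channel.
#'
#' @param epoch A [signal_epoch()].
#' @param low,high Band edges in Hz; must satisfy
#'   `0 < low < high < sampling_rate / 2`.
#' @param order Butterworth order of the one-directional prototype.
#' @return A filtered [signal_epoch()] of the same shape.
#' @export
bandpass_filter <- function(epoch, low = 1, high = 40, order = 4) {
  fs <- epoch$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("parameter error: band edges must satisfy 0 < low < high < Nyquist")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- epoch
  for (ch in seq_len(nrow(epoch$data))) {
    x <- epoch$data[ch, ]
    out$data[ch, ] <- signal::filtfilt(bf, x - mean(x))
  }
  out
}

# FFT-based analytic signal (Hilbert transform): zero out negative
# frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase and envelope via the analytic signal
#'
#' Computes the Hilbert-transform analytic signal per channel and returns the
#' instantaneous phase theta(n, t) in (-pi, pi] and envelope A(n, t) >= 0,
#' such that `A * cos(theta)` reconstructs the (band-limited) input away from
#' the epoch edges.
#'
#' @param epoch A band-limited [signal_epoch()].
#' @return Object of class `leida_phase` (see [phase_tensor()]).
#' @export
instantaneous_phase <- function(epoch) {
  const <- which(apply(epoch$data, 1, function(x) diff(range(x)) == 0))
  if (length(const)) {
    stop("degenerate-input error: constant channel(s): ",
         paste(epoch$channel_labels[const], collapse = ", "))
  }
  N <- nrow(epoch$data)
  theta <- matrix(0, N, ncol(epoch$data))
  amp <- theta
  for (ch in seq_len(N)) {
    a <- analytic_signal(epoch$data[ch, ])
    theta[ch, ] <- Arg(a)
    amp[ch, ] <- Mod(a)
  }
  phase_tensor(theta, amp, epoch$sampling_rate, epoch$channel_labels,
               epoch$subject_id, epoch$condition)
}

#' Construct a phase tensor directly
#'
#' Container for instantaneous phase and envelope; normally produced by
#' [instantaneous_phase()], but may be built directly from known phases (for
#' analytic checks).
#'
#' @param theta Channels x samples phase matrix, radians (wrapped to
#'   (-pi, pi\]).
#' @param amplitude Channels x samples non-negative envelope; defaults to 1.
#' @param sampling_rate Hz.
#' @param channel_labels,subject_id,condition Metadata.
#' @return Object of class `leida_phase`.
#' @export
phase_tensor <- function(theta, amplitude = NULL, sampling_rate = 1,
                         channel_labels = ten_twenty_labels(nrow(theta)),
                         subject_id = "S01", condition = "A") {
  stopifnot(is.matrix(theta))
  if (is.null(amplitude)) amplitude <- matrix(1, nrow(theta), ncol(theta))
  stopifnot(all(dim(amplitude) == dim(theta)), all(amplitude >= 0))
  structure(list(theta = wrap_angle(theta), amplitude = amplitude,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels,
                 subject_id = subject_id, condition = condition),
            class = "leida_phase")
}

#' Dynamic phase-locking tensor
#'
#' At every retained time point, the N x N phase-alignment matrix
#' `dPL(n, p, t) = cos(theta(n, t) - theta(p, t))`: 1 for aligned phases,
#' 0 for orthogonal (90 degrees), -1 for opposing phases. Each slice is
#' symmetric with unit diagonal, and is positive semidefinite of rank <= 2
#' (it equals `cc' + ss'` with `c = cos(theta)`, `s = sin(theta)`).
#'
#' @param phase A `leida_phase`.
#' @param decimate Keep every `decimate`-th sample (default 1 = one slice per
#'   sample).
#' @param edge_samples Samples to discard at each epoch edge before the
#'   tensor is formed (analytic-signal edge artifacts); default 0.
#' @return Object of class `leida_dpl`: list with `dpl` (N x N x T array),
#'   `channel_labels`, `time_index` (original sample indices of the retained
#'   slices), `sampling_rate`, `decimate`, `subject_id`, `condition`.
#' @export
compute_dpl <- function(phase, decimate = 1, edge_samples = 0) {
  N <- nrow(phase$theta)
  S <- ncol(phase$theta)
  if (N < 2) stop("input error: need >= 2 channels")
  if (S - 2 * edge_samples < 1) {
    stop("parameter error: no samples left after trimming")
  }
  idx <- seq.int(edge_samples + 1, S - edge_samples, by = decimate)
  Tn <- length(idx)
  co <- cos(phase$theta[, idx, drop = FALSE])
  si <- sin(phase$theta[, idx, drop = FALSE])
  dpl <- array(0, dim = c(N, N, Tn))
  for (t in seq_len(Tn)) {
    dpl[, , t] <- tcrossprod(co[, t]) + tcrossprod(si[, t])
  }
  structure(list(dpl = dpl, channel_labels = phase$channel_labels,
                 time_index = idx, sampling_rate = phase$sampling_rate,
                 decimate = decimate, subject_id = phase$subject_id,
                 condition = phase$condition),
            class = "leida_dpl")
}

# Deterministic sign convention: flip the eigenvector so that the majority of
# its elements are negative; when positive and negative counts tie, force the
# first element non-positive. Idempotent.
apply_sign_convention <- function(v) {
  n_pos <- sum(v > 0)
  n_neg <- sum(v < 0)
  if (n_pos > n_neg) return(-v)
  if (n_pos == n_neg && v[1] > 0) return(-v)
  v
}

#' Leading eigenvectors of a dynamic phase-locking tensor
#'
#' For every time slice, the unit-norm eigenvector associated with the
#' largest-magnitude eigenvalue, with a deterministic sign convention (flip
#' so the majority of elements are negative; ties force the first element
#' non-positive).
#'
#' @param dpl A `leida_dpl` (or any array of symmetric slices in the same
#'   container).
#' @return Object of class `leida_eigs`: `vectors` (T x N; row t = V1(t)),
#'   `eigenvalues` (length T), plus the metadata carried over.
#' @export
leading_eigenvector <- function(dpl) {
  N <- dim(dpl$dpl)[1]
  Tn <- dim(dpl$dpl)[3]
  vectors <- matrix(0, Tn, N)
  values <- numeric(Tn)
  for (t in seq_len(Tn)) {
    e <- tryCatch(eigen(dpl$dpl[, , t], symmetric = TRUE),
                  error = function(err) {
                    stop("numerical error: eigen decomposition failed at time index ",
                         dpl$time_index[t], ": ", conditionMessage(err))
                  })
    i <- which.max(abs(e$values))
    v <- e$vectors[, i]
    vectors[t, ] <- apply_sign_convention(v / sqrt(sum(v^2)))
    values[t] <- e$values[i]
  }
  structure(list(vectors = vectors, eigenvalues = values,
                 channel_labels = dpl$channel_labels,
                 time_index = dpl$time_index,
                 sampling_rate = dpl$sampling_rate,
                 decimate = dpl$decimate,
                 subject_id = dpl$subject_id, condition = dpl$condition,
                 sign_convention = "majority-negative"),
            class = "leida_eigs")
}

#' Write / read a leading-eigenvector series
#'
#' Serialised as a gzipped TSV of the T x N vector matrix (first column the
#' original sample index, second the eigenvalue) plus a JSON header carrying
#' channel labels, sampling rate, decimation and sign-convention id.
#'
#' @param eigs A `leida_eigs`.
#' @param path Output path (`.tsv.gz`); the header is written alongside as
#'   `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_eigs <- function(eigs, path) {
  df <- data.frame(time = eigs$time_index, eigenvalue = eigs$eigenvalues,
                   eigs$vectors, check.names = FALSE)
  names(df)[-(1:2)] <- eigs$channel_labels
  con <- gzfile(path, "w")
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  hdr <- list(channel_labels = eigs$channel_labels,
              sampling_rate = eigs$sampling_rate, decimate = eigs$decimate,
              subject_id = eigs$subject_id, condition = eigs$condition,
              sign_convention = eigs$sign_convention)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eigs
#' @export
read_eigs <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(gzfile(path), sep = "\t", header = TRUE,
                          check.names = FALSE)
  structure(list(vectors = unname(as.matrix(df[, -(1:2), drop = FALSE])),
                 eigenvalues = df$eigenvalue,
                 channel_labels = hdr$channel_labels,
                 time_index = df$time, sampling_rate = hdr$sampling_rate,
                 decimate = hdr$decimate, subject_id = hdr$subject_id,
                 condition = hdr$condition,
                 sign_convention = hdr$sign_convention),
            class = "leida_eigs")
}
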