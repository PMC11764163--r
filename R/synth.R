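#' Standard 10-20/10-10 style channel labels
#'
#' Returns `n` EEG channel names following the extended international 10-20
#' layout (the 64-channel montage of a typical mobile EEG amplifier). For
#' `n > 64` the list is extended with generic `ChNN` names.
#'
#' @param n Number of channels.
#' @return Character vector of length `n`, unique.
#' @export
ten_twenty_labels <- function(n) {
  base <- c(
    "Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz",
    "C4", "T8", "M2", "CP5", "CP1", "CP2", "CP6", "P7",
    "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "O2",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FC3", "FCz", "FC4", "C5", "C1", "C2", "C6", "CP3",
    "CPz", "CP4", "P5", "P1", "P2", "P6", "PO5", "PO3",
    "PO4", "PO6", "FT7", "FT8", "TP7", "TP8", "PO7", "PO8"
  )
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("Ch%02d", (length(base) + 1):n))
}

#' Default state partitions
#'
#' Builds one channel partition per state: each state splits the montage into
#' two phase-aligned communities of deliberately unequal size (60/40), with
#' the community boundary rotated by a state-specific offset so that every
#' state has a distinct phase-alignment pattern. The unequal split matters:
#' two equal-size communities at orthogonal offsets would make the two
#' leading eigenvalues of the planted phase-locking matrix coincide, leaving
#' the leading eigenvector undefined; the 60/40 split keeps the spectrum
#' simple so each state has a well-defined eigenvector signature.
#'
#' @param n_channels,n_states Counts.
#' @return List of length `n_states`; element `s` is an integer vector of
#'   length `n_channels` giving the community id (1-based) of each channel
#'   under state `s`.
#' @export
default_state_partitions <- function(n_channels, n_states) {
  major <- max(2L, ceiling(n_channels * 0.6))
  if (major >= n_channels) major <- n_channels - 1L
  lapply(seq_len(n_states), function(s) {
    shift <- ((s - 1) * max(1L, floor(n_channels / n_states))) %% n_channels
    idx <- ((seq_len(n_channels) - 1 + shift) %% n_channels) + 1
    ifelse(idx <= major, 1L, 2L)
  })
}

#' Default state-transition matrix
#'
#' Row-stochastic matrix with self-transition `self` and the remaining mass
#' spread evenly over the other states; its stationary distribution is
#' uniform.
#'
#' @param n_states Number of states.
#' @param self Self-transition probability (per state step).
#' @return `n_states x n_states` row-stochastic matrix.
#' @export
default_transition_matrix <- function(n_states, self = 0.9) {
  stopifnot(n_states >= 2, self > 0, self < 1)
  P <- matrix((1 - self) / (n_states - 1), n_states, n_states)
  diag(P) <- self
  P
}

#' Configuration for the synthetic oscillatory dataset generator
#'
#' Describes a two-condition (A = non-social-like, B = social-like) multichannel
#' study in which a hidden Markov chain switches between planted phase-locking
#' states. Each state assigns channels to phase-aligned communities; community
#' phase offsets are equally spaced on \[0, pi). Condition B multiplies the
#' self-transition of one designated state by `occupancy_boost` (row then
#' renormalised), so the two conditions share the same state repertoire and
#' differ only in how much time they spend in that state — mirroring an
#' occupancy effect confined to a single state.
#'
#' Defaults emulate a 64-channel, 500 Hz recording filtered to 1-40 Hz from 47
#' participants, with 8 planted states and the boosted state being state 7.
#'
#' @param n_subjects Number of subjects (each contributes one epoch per
#'   condition).
#' @param n_channels Number of channels.
#' @param n_samples Samples per epoch (per condition).
#' @param sampling_rate Sampling rate in Hz.
#' @param carrier_freq Carrier oscillation frequency in Hz (must lie in the
#'   1-40 Hz band and below Nyquist/2).
#' @param n_states Number of planted phase-locking states (>= 2).
#' @param state_partitions List (length `n_states`) of per-channel community
#'   ids, or `NULL` for [default_state_partitions()].
#' @param transition_matrix Row-stochastic `n_states x n_states` matrix of the
#'   state chain (per state step), or `NULL` for
#'   [default_transition_matrix()].
#' @param boost_state Index of the state whose occupancy differs between
#'   conditions; `NULL` picks state 7 when there are at least 7 states and
#'   the last state otherwise.
#' @param occupancy_boost Multiplier (> 0) on `boost_state`'s self-transition
#'   in condition B; 1 means no condition effect.
#' @param state_step Samples per state step; state switches happen only at
#'   step boundaries so states persist over many carrier cycles (default 25
#'   samples = 50 ms at 500 Hz).
#' @param phase_noise_kappa von Mises concentration of per-sample,
#'   per-channel phase jitter (`Inf` = none).
#' @param amplitude_noise_sd Standard deviation of additive Gaussian
#'   amplitude noise, in signal units (carrier amplitude is 1).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return Object of class `leida_synth_config`.
#' @export
synth_config <- function(n_subjects = 47, n_channels = 64, n_samples = 5000,
                         sampling_rate = 500, carrier_freq = 10,
                         n_states = 8, state_partitions = NULL,
                         transition_matrix = NULL, boost_state = NULL,
                         occupancy_boost = 1.5, state_step = 25,
                         phase_noise_kappa = 20, amplitude_noise_sd = 0.3,
                         seed = 1) {
  if (is.null(state_partitions)) {
    state_partitions <- default_state_partitions(n_channels, n_states)
  }
  if (is.null(transition_matrix)) {
    transition_matrix <- default_transition_matrix(n_states)
  }
  # state 7 in the default 8-state repertoire; the last state otherwise
  if (is.null(boost_state)) boost_state <- min(7L, n_states)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
    n_samples = as.integer(n_samples), sampling_rate = sampling_rate,
    carrier_freq = carrier_freq, n_states = as.integer(n_states),
    state_partitions = state_partitions, transition_matrix = transition_matrix,
    boost_state = as.integer(boost_state), occupancy_boost = occupancy_boost,
    state_step = as.integer(state_step),
    phase_noise_kappa = phase_noise_kappa,
    amplitude_noise_sd = amplitude_noise_sd, seed = as.integer(seed)
  ), class = "leida_synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_states < 2) stop("configuration error: n_states must be >= 2")
    if (n_subjects < 1 || n_channels < 2 || n_samples < 4) {
      stop("configuration error: need >= 1 subject, >= 2 channels, >= 4 samples")
    }
    if (carrier_freq < 1 || carrier_freq > 40) {
      stop("configuration error: carrier_freq must lie in [1, 40] Hz")
    }
    if (sampling_rate <= 2 * carrier_freq) {
      stop("configuration error: sampling_rate must exceed 2 * carrier_freq")
    }
    if (!is.matrix(transition_matrix) ||
        any(dim(transition_matrix) != n_states) ||
        any(transition_matrix < 0) ||
        any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
      stop("configuration error: transition_matrix must be n_states x n_states row-stochastic")
    }
    if (length(state_partitions) != n_states) {
      stop("configuration error: one partition per state is required")
    }
    for (p in state_partitions) {
      if (length(p) != n_channels || anyNA(p) || any(p < 1)) {
        stop("configuration error: invalid partition (channel missing/duplicated)")
      }
    }
    if (boost_state < 1 || boost_state > n_states) {
      stop("configuration error: boost_state out of range")
    }
    if (!is.finite(occupancy_boost) || occupancy_boost <= 0) {
      stop("configuration error: occupancy_boost producing a non-stochastic row")
    }
    if (state_step < 1) stop("configuration error: state_step must be >= 1")
  })
  invisible(cfg)
}

#' Stationary distribution of a row-stochastic matrix
#' @param P Row-stochastic square matrix.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

boosted_matrix <- function(P, state, boost) {
  P[state, state] <- P[state, state] * boost
  P[state, ] <- P[state, ] / sum(P[state, ])
  P
}

simulate_chain <- function(P, n_steps, init) {
  k <- nrow(P)
  s <- integer(n_steps)
  s[1] <- sample.int(k, 1, prob = init)
  if (n_steps > 1) {
    for (t in 2:n_steps) s[t] <- sample.int(k, 1, prob = P[s[t - 1], ])
  }
  s
}

#' Generate a synthetic multichannel dataset with planted phase-locking states
#'
#' For each subject and condition a hidden state sequence is drawn from the
#' Markov chain (condition B uses the occupancy-boosted matrix), started from
#' that chain's stationary distribution. Each channel's phase advances at
#' `2 * pi * carrier_freq / sampling_rate` per sample, plus the community
#' phase offset of its group in the active state (offsets equally spaced on
#' \[0, pi)), plus von Mises jitter. The signal is `cos(phase)` with additive
#' Gaussian amplitude noise.
#'
#' @param config A [synth_config()].
#' @return Object of class `leida_dataset`: list with `epochs` (list of
#'   [signal_epoch()]), `true_states` (per-epoch integer state label per
#'   sample), `true_occupancy` (data frame subject/condition/state/occupancy)
#'   and `config`.
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  N <- config$n_channels
  S <- config$n_samples
  labels <- ten_twenty_labels(N)
  offsets <- lapply(config$state_partitions, function(part) {
    m <- max(part)
    ((seq_len(m) - 1) * pi / m)[part]
  })
  P_A <- config$transition_matrix
  P_B <- boosted_matrix(P_A, config$boost_state, config$occupancy_boost)
  init_A <- stationary_distribution(P_A)
  init_B <- stationary_distribution(P_B)
  n_steps <- ceiling(S / config$state_step)
  omega <- 2 * pi * config$carrier_freq / config$sampling_rate
  base_phase <- omega * (seq_len(S) - 1)

  epochs <- list()
  true_states <- list()
  occ_rows <- list()
  subj_ids <- sprintf("S%02d", seq_len(config$n_subjects))
  for (subj in subj_ids) {
    for (cond in c("A", "B")) {
      P <- if (cond == "A") P_A else P_B
      init <- if (cond == "A") init_A else init_B
      steps <- simulate_chain(P, n_steps, init)
      state_seq <- rep(steps, each = config$state_step)[seq_len(S)]
      off <- vapply(offsets, identity, numeric(N))   # N x n_states
      data <- matrix(0, N, S)
      for (ch in seq_len(N)) {
        jitter <- rvonmises(S, config$phase_noise_kappa)
        phase <- base_phase + off[ch, state_seq] + jitter
        data[ch, ] <- cos(phase) +
          stats::rnorm(S, sd = config$amplitude_noise_sd)
      }
      key <- paste0(subj, "_", cond)
      epochs[[key]] <- signal_epoch(data, config$sampling_rate, labels,
                                    subject_id = subj, condition = cond)
      true_states[[key]] <- state_seq
      occ <- tabulate(state_seq, nbins = config$n_states) / S
      occ_rows[[key]] <- data.frame(subject = subj, condition = cond,
                                    state = seq_len(config$n_states),
                                    occupancy = occ)
    }
  }
  structure(list(
    epochs = epochs, true_states = true_states,
    true_occupancy = do.call(rbind, c(occ_rows, list(make.row.names = FALSE))),
    config = config
  ), class = "leida_dataset")
}

#' @export
print.leida_dataset <- function(x, ...) {
  cat(sprintf(
    "<leida_dataset> %d subjects x 2 conditions, %d channels, %d samples @ %g Hz, %d planted states\n",
    x$config$n_subjects, x$config$n_channels, x$config$n_samples,
    x$config$sampling_rate, x$config$n_states))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes one file per epoch (TSV channel-by-sample matrix with channel labels
#' as row names, or 16-bit EDF), a TSV sidecar manifest listing subject,
#' condition, file and seed, a JSON dump of the generator configuration, and
#' (optionally) the planted state sequences.
#'
#' @param dataset A `leida_dataset`.
#' @param path Output directory (created if needed).
#' @param format `"tsv"` (delimited matrix; lossless) or `"edf"` (European
#'   Data Format, quantised to 16 bits).
#' @param write_truth Also write per-epoch planted state sequences
#'   (`*_states.tsv`).
#' @return Invisibly, the manifest data frame.
#' @export
write_epochs <- function(dataset, path, format = c("tsv", "edf"),
                         write_truth = TRUE) {
  format <- match.arg(format)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(path)) stop("I/O error: cannot create ", path)
  }
  rows <- list()
  for (key in names(dataset$epochs)) {
    ep <- dataset$epochs[[key]]
    file <- paste0("sub-", ep$subject_id, "_cond-", ep$condition, ".",
                   if (format == "tsv") "tsv" else "edf")
    fp <- file.path(path, file)
    if (format == "tsv") {
      # %.17g keeps the round trip bit-identical for doubles
      df <- data.frame(channel = ep$channel_labels,
                       matrix(sprintf("%.17g", ep$data), nrow(ep$data)),
                       check.names = FALSE)
      utils::write.table(df, fp, sep = "\t", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    } else {
      write_edf(ep$data, ep$sampling_rate, ep$channel_labels, fp)
    }
    if (write_truth && !is.null(dataset$true_states[[key]])) {
      utils::write.table(
        data.frame(state = dataset$true_states[[key]]),
        file.path(path, sub("\\.(tsv|edf)$", "_states.tsv", file)),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    rows[[key]] <- data.frame(subject = ep$subject_id,
                              condition = ep$condition, file = file,
                              sampling_rate = ep$sampling_rate,
                              seed = dataset$config$seed)
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(manifest, file.path(path, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- dataset$config
  cfg$transition_matrix <- unname(apply(cfg$transition_matrix, 1, c,
                                        simplify = FALSE))
  jsonlite::write_json(unclass(cfg), file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read epochs written by [write_epochs()]
#'
#' @param path Directory containing `manifest.tsv` and the epoch files.
#' @return List with `epochs` (list of [signal_epoch()]), `true_states`
#'   (planted label sequences where present, else `NULL`) and `manifest`.
#' @export
read_epochs <- function(path) {
  mf <- file.path(path, "manifest.tsv")
  if (!file.exists(mf)) stop("I/O error: no manifest.tsv under ", path)
  manifest <- utils::read.table(mf, sep = "\t", header = TRUE,
                                colClasses = c(subject = "character",
                                               condition = "character"))
  epochs <- list()
  true_states <- list()
  for (i in seq_len(nrow(manifest))) {
    fp <- file.path(path, manifest$file[i])
    if (grepl("\\.edf$", fp)) {
      e <- read_edf(fp)
      data <- e$data; labels <- e$channel_labels; fs <- e$sampling_rate
    } else {
      raw <- utils::read.table(fp, sep = "\t", header = FALSE,
                               colClasses = "character")
      labels <- raw[[1]]
      data <- as.matrix(vapply(raw[-1], as.numeric, numeric(nrow(raw))))
      dimnames(data) <- NULL
      fs <- manifest$sampling_rate[i]
    }
    key <- paste0(manifest$subject[i], "_", manifest$condition[i])
    epochs[[key]] <- signal_epoch(data, fs, labels,
                                  subject_id = manifest$subject[i],
                                  condition = manifest$condition[i])
    sf <- file.path(path, sub("\\.(tsv|edf)$", "_states.tsv", manifest$file[i]))
    if (file.exists(sf)) {
      true_states[[key]] <- utils::read.table(sf, header = TRUE)$state
    }
  }
  list(epochs = epochs,
       true_states = if (length(true_states)) true_states else NULL,
       manifest = manifest)
}
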