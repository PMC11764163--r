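#' Welch two-sample t statistic
#'
#' Unequal-variance t statistic, signed so that it is positive when
#' `mean(b) > mean(a)` (condition B above condition A). When both groups have
#' zero variance the statistic is 0 for equal means and `+/-Inf` (a flagged
#' degenerate value) for unequal means.
#'
#' @param a,b Numeric vectors, each with at least two finite values.
#' @return The t statistic (possibly infinite).
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b)))) {
    stop("input error: each group needs >= 2 finite values")
  }
  num <- mean(b) - mean(a)
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  if (se2 == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / sqrt(se2)
}

#' Build a per-state occupancy contrast from state metrics
#'
#' Pairs each subject's condition-A and condition-B occupancy per state.
#'
#' @param metrics A `leida_metrics` (from [compute_state_metrics()]) or its
#'   `occupancy` data frame (columns subject, condition, state, occupancy).
#' @return Object of class `leida_contrast`: `A` and `B` (subjects x states
#'   occupancy matrices with equal subject sets), `subjects`, `states`.
#' @export
occupancy_contrast <- function(metrics) {
  occ <- if (inherits(metrics, "leida_metrics")) metrics$occupancy else metrics
  stopifnot(all(c("subject", "condition", "state", "occupancy") %in% names(occ)))
  subs_a <- sort(unique(occ$subject[occ$condition == "A"]))
  subs_b <- sort(unique(occ$subject[occ$condition == "B"]))
  if (!identical(subs_a, subs_b)) {
    stop("input error: conditions must cover the same subjects")
  }
  states <- sort(unique(occ$state))
  grab <- function(cond) {
    m <- matrix(NA_real_, length(subs_a), length(states),
                dimnames = list(subs_a, states))
    sel <- occ[occ$condition == cond, ]
    m[cbind(match(sel$subject, subs_a), match(sel$state, states))] <- sel$occupancy
    m
  }
  A <- grab("A"); B <- grab("B")
  if (anyNA(A) || anyNA(B)) stop("input error: missing occupancy entries")
  if (any(A < 0 | A > 1 | B < 0 | B > 1)) {
    stop("input error: occupancy values must lie in [0, 1]")
  }
  structure(list(A = A, B = B, subjects = subs_a, states = states),
            class = "leida_contrast")
}

# vectorised Welch t for P permuted group pairs held in P x S matrices
welch_t_rows <- function(Ap, Bp) {
  S_a <- ncol(Ap); S_b <- ncol(Bp)
  ma <- rowMeans(Ap); mb <- rowMeans(Bp)
  va <- (rowSums(Ap^2) - S_a * ma^2) / (S_a - 1)
  vb <- (rowSums(Bp^2) - S_b * mb^2) / (S_b - 1)
  se2 <- va / S_a + vb / S_b
  t <- (mb - ma) / sqrt(se2)
  t[se2 == 0 & mb == ma] <- 0
  t[se2 == 0 & mb != ma] <- Inf * sign((mb - ma)[se2 == 0 & mb != ma])
  t
}

#' Permutation test on per-state occupancy
#'
#' For every state, compares condition B against condition A with a Welch t
#' statistic and builds a permutation null by shuffling condition labels. The
#' default scheme flips each subject's A/B pair with probability 1/2 (each
#' participant experienced both conditions); `scheme = "unpaired"` instead
#' reshuffles all values between the two groups. Two-sided p-values use the
#' add-one correction `p = (1 + #{|t_null| >= |t_obs|}) / (n_perm + 1)` and
#' are Benjamini-Hochberg adjusted across states.
#'
#' @param contrast A `leida_contrast`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (reproducible given it).
#' @param scheme `"paired"` (within-subject label swap, default) or
#'   `"unpaired"` (full reshuffle).
#' @param keep_null Retain the null t distributions (as an attribute
#'   `null_t`, a states-column matrix).
#' @return Data frame with one row per state: `state`, `t_obs`, `p_raw`,
#'   `p_fdr`, `n_perm`, `seed`, `scheme`.
#' @export
permutation_test <- function(contrast, n_perm = 10000, seed = 1,
                             scheme = c("paired", "unpaired"),
                             keep_null = FALSE) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) stop("parameter error: n_perm must be >= 100")
  A <- contrast$A; B <- contrast$B
  S <- nrow(A)
  set.seed(derive_seed(seed, paste0("perm-", scheme)))
  if (scheme == "paired") {
    flips <- matrix(stats::runif(n_perm * S) < 0.5, n_perm, S)
  } else {
    sel <- t(replicate(n_perm, sample.int(2 * S, S)))
    comp <- t(apply(sel, 1, function(i) setdiff(seq_len(2 * S), i)))
  }
  res <- list()
  nulls <- if (keep_null) matrix(NA_real_, n_perm, length(contrast$states))
  for (j in seq_along(contrast$states)) {
    a <- A[, j]; b <- B[, j]
    # computed through the same vectorised code path as the null draws so
    # that the identity permutation compares exactly equal
    t_obs <- welch_t_rows(matrix(a, 1), matrix(b, 1))
    if (scheme == "paired") {
      Ap <- matrix(rep(a, each = n_perm), n_perm, S)
      Bp <- matrix(rep(b, each = n_perm), n_perm, S)
      Ap[flips] <- rep(b, each = n_perm)[flips]
      Bp[flips] <- rep(a, each = n_perm)[flips]
    } else {
      z <- c(a, b)
      Ap <- matrix(z[sel], n_perm, S)
      Bp <- matrix(z[comp], n_perm, S)
    }
    t_null <- welch_t_rows(Ap, Bp)
    if (keep_null) nulls[, j] <- t_null
    p_raw <- (1 + sum(abs(t_null) >= abs(t_obs))) / (n_perm + 1)
    res[[j]] <- data.frame(state = contrast$states[j], t_obs = t_obs,
                           p_raw = p_raw)
  }
  out <- do.call(rbind, res)
  out$p_fdr <- fdr_adjust(out$p_raw)
  out$n_perm <- as.integer(n_perm)
  out$seed <- as.integer(seed)
  out$scheme <- scheme
  if (keep_null) attr(out, "null_t") <- nulls
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: order-preserving, each adjusted value at least
#' its raw value.
#'
#' @param p Numeric p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) stop("parameter error: empty p-value vector")
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("parameter error: p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per value, with `m = length(p)`.
#'
#' @param p Numeric p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bonferroni_adjust <- function(p) {
  if (length(p) == 0) stop("parameter error: empty p-value vector")
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("parameter error: p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "bonferroni")
}
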