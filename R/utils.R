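#' @keywords internal
"_PACKAGE"

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed is turned into per-stage seeds by hashing the stage
#' name, so that changing one stage's draw count never perturbs another
#' stage's stream. The result is always a valid 32-bit R integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"synth"`, `"cluster"`).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h * 362437) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used to score recovery of planted state sequences by clustering.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return Numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Match estimated states to planted states
#'
#' Finds the permutation of estimated labels maximising the confusion-matrix
#' trace against reference labels (exhaustive over permutations; intended for
#' small k).
#'
#' @param estimated Integer labels in `1..k`.
#' @param reference Integer labels in `1..k`.
#' @param k Number of states.
#' @return Integer vector `map` of length `k`: estimated state `s` corresponds
#'   to reference state `map[s]`.
#' @export
match_states <- function(estimated, reference, k) {
  stopifnot(k <= 8, length(estimated) == length(reference))
  tab <- matrix(0, k, k)
  idx <- cbind(estimated, reference)
  for (i in seq_len(nrow(idx))) tab[idx[i, 1], idx[i, 2]] <- tab[idx[i, 1], idx[i, 2]] + 1
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) sum(tab[cbind(seq_len(k), p)]), numeric(1))
  perms[[which.max(scores)]]
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    sub <- permutations_of(k - 1L)
    rest <- setdiff(seq_len(k), i)
    out <- c(out, lapply(sub, function(p) c(i, rest[p])))
  }
  out
}

#' Wrap angles to (-pi, pi]
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped into the principal interval.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); mean 0.
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (is.infinite(kappa)) return(numeric(n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
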