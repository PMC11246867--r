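# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed` so library calls never
#' disturb user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported rank averages use the
#' conventional half-away-from-zero rule instead.
#' @noRd
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Squared-distance based cross-distance matrix
#'
#' Euclidean distances between every row of `A` (m x p) and every row of
#' `B` (n x p), computed via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b.
#' Small negative values from cancellation are clipped to zero.
#' @noRd
cross_dist <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("cross_dist: column counts differ (", ncol(A), " vs ", ncol(B), ")")
  }
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Draw independent sub-seeds from a master seed
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Stable order of a numeric vector: ties broken by original position.
stable_order <- function(x) order(x, seq_along(x), method = "radix")
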