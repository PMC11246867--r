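#' Euclidean distance between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors have different lengths: ", length(a), " vs ", length(b))
  }
  sqrt(sum((a - b)^2))
}

#' Find the k nearest training rows to a query point
#'
#' Exact k-nearest-neighbor search by full distance computation. Ties at the
#' k-th distance are broken by the smallest row index, so results are
#' deterministic across runs and platforms. Duplicated training rows (as
#' arise in bootstrap samples) are legitimate distinct neighbors.
#'
#' @param Xtrain Numeric training matrix, n x p.
#' @param x0 Numeric query vector of length p.
#' @param k Number of neighbors, `1 <= k <= n`.
#' @return A `neighbor_set`: list with `indices` (into the rows of
#'   `Xtrain`) and `distances`, both length k, distances sorted ascending.
#' @examples
#' ns <- find_neighbors(matrix(c(0, 1, 10)), 0.4, k = 2)
#' ns$indices # 1 2
#' @export
find_neighbors <- function(Xtrain, x0, k) {
  Xtrain <- as.matrix(Xtrain)
  n <- nrow(Xtrain)
  if (length(x0) != ncol(Xtrain)) {
    stop("query has length ", length(x0), " but training data has ",
         ncol(Xtrain), " columns")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
    stop("k must be a positive integer, got ", deparse(k))
  }
  if (k > n) stop("k = ", k, " exceeds the number of training rows (", n, ")")
  d <- sqrt(rowSums(sweep(Xtrain, 2, x0, "-")^2))
  ord <- stable_order(d)[seq_len(k)]
  structure(list(indices = ord, distances = d[ord]), class = "neighbor_set")
}

#' Plain KNN prediction: mean of neighbor responses
#'
#' @param neighbor_responses Numeric vector of the k neighbors' responses.
#' @return Their arithmetic mean.
#' @examples
#' knn_predict(c(2, 4, 6)) # 4
#' @export
knn_predict <- function(neighbor_responses) {
  if (length(neighbor_responses) < 1L) {
    stop("need at least one neighbor response")
  }
  mean(neighbor_responses)
}

#' Kernel-weighted KNN prediction
#'
#' Weighted average of neighbor responses, with weights from the kernel
#' profile evaluated at each neighbor's distance. If every weight is zero
#' (all neighbors at or beyond a compact-support bandwidth) the prediction
#' falls back to the unweighted mean rather than returning NaN. The result
#' is always a convex combination of the responses, hence bounded by their
#' minimum and maximum.
#'
#' @param neighbors A `neighbor_set` from [find_neighbors()] (or any list
#'   with a `distances` element).
#' @param neighbor_responses Responses of those neighbors, same length.
#' @param family Kernel family, see [kernel_families()].
#' @param h Positive bandwidth.
#' @return The weighted (or fallback unweighted) mean response.
#' @examples
#' ns <- list(distances = c(0, 0.5, 1))
#' kernel_knn_predict(ns, c(1, 2, 3), "triangular", 1) # 4/3
#' @export
kernel_knn_predict <- function(neighbors, neighbor_responses, family, h) {
  d <- neighbors$distances
  if (length(d) != length(neighbor_responses)) {
    stop("distances (", length(d), ") and responses (",
         length(neighbor_responses), ") differ in length")
  }
  w <- kernel_weight(family, d, h)
  sw <- sum(w)
  if (sw == 0 || max(w) == min(w)) {
    # zero total weight (compact support exhausted) or constant weights
    # (uniform kernel with all neighbors inside h): the weighted average
    # IS the plain mean, so return it exactly
    return(knn_predict(neighbor_responses))
  }
  sum(w * neighbor_responses) / sw
}
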