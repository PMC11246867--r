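#' Bandwidth candidates from maximum k-NN distances
#'
#' On \[0, 1\]-scaled features all pairwise distances are bounded, so a small
#' set of data-driven bandwidths can be read off the neighbor structure: for
#' each `kappa`, take every training point's distance to its kappa-th nearest
#' other point and keep the maximum over points. Choosing the largest
#' candidate guarantees that every training point's `k` nearest neighbors
#' (for `k <= max(kappas)`) receive nonzero weight under a compact-support
#' kernel.
#'
#' @param Xtrain Scaled numeric matrix, n x p.
#' @param kappas Integer neighbor orders; default `c(2, 3, 5, 7)`. All must
#'   be below n.
#' @return Deduplicated ascending numeric vector of positive bandwidths
#'   (at most `length(kappas)` values).
#' @examples
#' X <- matrix(c(0, 0.1, 0.2, 0.3, 0.4))
#' bandwidth_candidates(X, kappas = c(2, 3)) # 0.2 0.3
#' @export
bandwidth_candidates <- function(Xtrain, kappas = c(2, 3, 5, 7)) {
  Xtrain <- as.matrix(Xtrain)
  n <- nrow(Xtrain)
  if (!is.numeric(kappas) || length(kappas) == 0L ||
      any(kappas < 1) || any(kappas != floor(kappas))) {
    stop("kappas must be positive integers")
  }
  if (any(kappas >= n)) {
    stop("every kappa must be below the number of rows (n = ", n, ")")
  }
  D <- as.matrix(stats::dist(Xtrain))
  if (max(D) == 0) {
    stop("degenerate data: all rows are identical (zero diameter)")
  }
  # row-wise sorted distances to the *other* points (self excluded);
  # column i of `sorted` holds point i's 1st..max(kappas)-th neighbor dists
  sorted <- vapply(seq_len(n), function(i) {
    sort(D[i, -i])[seq_len(max(kappas))]
  }, numeric(max(kappas)))
  sorted <- matrix(sorted, nrow = max(kappas))
  h <- vapply(kappas, function(k) max(sorted[k, ]), numeric(1))
  h <- sort(unique(h[h > 0]))
  if (length(h) == 0L) {
    stop("degenerate data: every candidate bandwidth is zero")
  }
  h
}

#' Assign rows to near-equal cross-validation folds
#'
#' Uniform random permutation, seeded; when n is not divisible by the fold
#' count the remainder rows are spread one per fold.
#' @noRd
make_folds <- function(n, folds, seed) {
  if (folds < 2L) stop("folds must be at least 2")
  if (folds > n) stop("more folds (", folds, ") than rows (", n, ")")
  sizes <- rep(n %/% folds, folds)
  if (n %% folds > 0) sizes[seq_len(n %% folds)] <- sizes[seq_len(n %% folds)] + 1L
  ids <- rep(seq_len(folds), sizes)
  perm <- with_seed(seed, sample.int(n))
  out <- integer(n)
  out[perm] <- ids
  out
}

# Shared engine for cv_error / grid_search: evaluates every (k, h) cell on
# one fixed fold partition, reusing per-fold neighbor sorts across cells.
cv_grid_engine <- function(data, k_candidates, h_candidates, family,
                           folds, seed) {
  stopifnot(inherits(data, "rk_dataset"))
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (any(k_candidates < 1)) stop("k candidates must be positive")
  plain <- identical(family, "none")
  if (!plain) {
    check_family(family)
    h_candidates <- sort(unique(as.numeric(h_candidates)))
    if (any(h_candidates <= 0)) stop("bandwidth candidates must be positive")
  } else {
    h_candidates <- NA_real_
  }
  fold_id <- make_folds(data$n, folds, seed)
  min_train <- data$n - max(tabulate(fold_id, folds))
  kmax <- max(k_candidates)
  if (kmax > min_train) {
    stop("k = ", kmax, " exceeds the smallest training-fold size (",
         min_train, ")")
  }

  # per fold: sorted neighbor distances and responses up to kmax
  fold_sq_err <- array(0, dim = c(folds, length(k_candidates),
                                  length(h_candidates)))
  for (f in seq_len(folds)) {
    val <- which(fold_id == f)
    trn <- which(fold_id != f)
    Dm <- cross_dist(data$X[val, , drop = FALSE],
                     data$X[trn, , drop = FALSE])
    m <- length(val)
    dists <- matrix(0, m, kmax)
    resp <- matrix(0, m, kmax)
    for (i in seq_len(m)) {
      ord <- stable_order(Dm[i, ])[seq_len(kmax)]
      dists[i, ] <- Dm[i, ord]
      resp[i, ] <- data$y[trn][ord]
    }
    yv <- data$y[val]
    for (ki in seq_along(k_candidates)) {
      k <- k_candidates[ki]
      rk <- resp[, seq_len(k), drop = FALSE]
      if (plain) {
        pred <- rowMeans(rk)
        fold_sq_err[f, ki, 1L] <- sqrt(mean((yv - pred)^2))
      } else {
        dk <- dists[, seq_len(k), drop = FALSE]
        fallback <- rowMeans(rk)
        for (hi in seq_along(h_candidates)) {
          w <- kernel_weight(family, as.vector(dk), h_candidates[hi])
          w <- matrix(w, nrow(dk), k)
          sw <- rowSums(w)
          pred <- ifelse(sw > 0, rowSums(w * rk) / ifelse(sw > 0, sw, 1),
                         fallback)
          fold_sq_err[f, ki, hi] <- sqrt(mean((yv - pred)^2))
        }
      }
    }
  }
  cv <- apply(fold_sq_err, c(2L, 3L), mean)
  cv_table <- expand.grid(k = k_candidates, h = h_candidates,
                          KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies k fastest; reorder k-major (k, then h) for tie rules
  cv_table$mean_rmse <- as.vector(cv)
  cv_table <- cv_table[order(cv_table$k, cv_table$h), , drop = FALSE]
  rownames(cv_table) <- NULL
  cv_table
}

#' Cross-validated error of one (k, h) configuration
#'
#' Rows are randomly partitioned (seeded) into near-equal folds; each fold
#' serves once as validation while the model predicts it from the remaining
#' folds. Returns the mean over folds of the validation RMSE of
#' kernel-weighted KNN with the given neighbor count and bandwidth. With
#' `family = "none"` the prediction is the plain neighbor mean and `h` is
#' ignored.
#'
#' @param data An [rk_dataset()] (already scaled if scaling is wanted).
#' @param k Neighbor count.
#' @param h Bandwidth (ignored for `family = "none"`).
#' @param family Kernel family or `"none"`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling the fold partition.
#' @param metric Validation metric, `"rmse"` (default) or `"mae"`.
#' @return Mean validation error across folds.
#' @export
cv_error <- function(data, k, h = NULL, family = "none", folds = 5,
                     seed = 1, metric = c("rmse", "mae")) {
  metric <- match.arg(metric)
  tab <- cv_grid_engine_metric(data, k, if (is.null(h)) NA_real_ else h,
                               family, folds, seed, metric)
  tab$mean_rmse[1L]
}

# cv_grid_engine with a selectable fold metric (RMSE default, MAE option).
cv_grid_engine_metric <- function(data, k_candidates, h_candidates, family,
                                  folds, seed, metric = "rmse") {
  if (metric == "rmse") {
    return(cv_grid_engine(data, k_candidates, h_candidates, family,
                          folds, seed))
  }
  # MAE path: same structure, absolute-error aggregation
  stopifnot(inherits(data, "rk_dataset"))
  k_candidates <- sort(unique(as.integer(k_candidates)))
  plain <- identical(family, "none")
  if (!plain) check_family(family) else h_candidates <- NA_real_
  h_candidates <- if (plain) NA_real_ else sort(unique(as.numeric(h_candidates)))
  fold_id <- make_folds(data$n, folds, seed)
  kmax <- max(k_candidates)
  min_train <- data$n - max(tabulate(fold_id, folds))
  if (kmax > min_train) {
    stop("k = ", kmax, " exceeds the smallest training-fold size (",
         min_train, ")")
  }
  err <- array(0, dim = c(folds, length(k_candidates), length(h_candidates)))
  for (f in seq_len(folds)) {
    val <- which(fold_id == f)
    trn <- which(fold_id != f)
    Dm <- cross_dist(data$X[val, , drop = FALSE], data$X[trn, , drop = FALSE])
    m <- length(val)
    dists <- matrix(0, m, kmax); resp <- matrix(0, m, kmax)
    for (i in seq_len(m)) {
      ord <- stable_order(Dm[i, ])[seq_len(kmax)]
      dists[i, ] <- Dm[i, ord]; resp[i, ] <- data$y[trn][ord]
    }
    yv <- data$y[val]
    for (ki in seq_along(k_candidates)) {
      k <- k_candidates[ki]
      rk <- resp[, seq_len(k), drop = FALSE]
      if (plain) {
        err[f, ki, 1L] <- mean(abs(yv - rowMeans(rk)))
      } else {
        dk <- dists[, seq_len(k), drop = FALSE]
        fallback <- rowMeans(rk)
        for (hi in seq_along(h_candidates)) {
          w <- matrix(kernel_weight(family, as.vector(dk), h_candidates[hi]),
                      nrow(dk), k)
          sw <- rowSums(w)
          pred <- ifelse(sw > 0, rowSums(w * rk) / ifelse(sw > 0, sw, 1),
                         fallback)
          err[f, ki, hi] <- mean(abs(yv - pred))
        }
      }
    }
  }
  cv <- apply(err, c(2L, 3L), mean)
  cv_table <- expand.grid(k = k_candidates, h = h_candidates,
                          KEEP.OUT.ATTRS = FALSE)
  cv_table$mean_rmse <- as.vector(cv)
  cv_table <- cv_table[order(cv_table$k, cv_table$h), , drop = FALSE]
  rownames(cv_table) <- NULL
  cv_table
}

#' Grid search for the optimal (k, h) pair
#'
#' Evaluates every combination of neighbor count and bandwidth by
#' cross-validation on one fixed (seeded) fold partition and returns the
#' minimizing cell. Ties are broken toward smaller k, then smaller h —
#' preferring the cheaper, smoother model.
#'
#' @param data An [rk_dataset()] (scaled).
#' @param k_candidates Ascending positive integers.
#' @param h_candidates Ascending positive bandwidths (ignored when
#'   `family = "none"`).
#' @param family Kernel family or `"none"` for plain KNN (only k tuned).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold partition.
#' @param metric Validation metric, `"rmse"` (default) or `"mae"`.
#' @return A `tune_result`: list with `k_opt`, `h_opt` (NA for plain KNN)
#'   and the full `cv_table` (columns k, h, mean_rmse).
#' @export
grid_search <- function(data, k_candidates, h_candidates = NULL,
                        family = "none", folds = 5, seed = 1,
                        metric = c("rmse", "mae")) {
  metric <- match.arg(metric)
  tab <- cv_grid_engine_metric(data, k_candidates,
                               if (is.null(h_candidates)) NA_real_ else h_candidates,
                               family, folds, seed, metric)
  best <- which(tab$mean_rmse == min(tab$mean_rmse))[1L] # rows k-major
  structure(
    list(k_opt = tab$k[best], h_opt = tab$h[best], cv_table = tab),
    class = "tune_result"
  )
}

#' @export
print.tune_result <- function(x, ...) {
  cat("tuned kernel-KNN: k_opt =", x$k_opt,
      if (!is.na(x$h_opt)) paste(" h_opt =", signif(x$h_opt, 6)), "\n")
  cat("  cv grid:", nrow(x$cv_table), "cells, best mean RMSE =",
      signif(min(x$cv_table$mean_rmse), 6), "\n")
  invisible(x)
}

#' Default neighbor-count candidates
#'
#' Odd values spanning the small-k regime KNN regression favors, capped so
#' every candidate fits in the smallest CV training fold.
#'
#' @param n Training-set size.
#' @param folds CV fold count.
#' @return Integer vector of admissible k candidates.
#' @export
default_k_candidates <- function(n, folds = 5) {
  cap <- floor(n * (folds - 1) / folds)
  k <- c(1L, 3L, 5L, 7L, 9L, 11L, 15L, 21L)
  k <- k[k >= 1 & k <= cap]
  if (length(k) == 0L) k <- 1L
  k
}
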