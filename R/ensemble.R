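#' Bootstrap row indices
#'
#' n uniform draws with replacement from the n training-row indices; the
#' classical bagging resample (on average about 63.2% of distinct rows
#' appear).
#'
#' @param n Number of training rows.
#' @param rng_seed Integer seed.
#' @return Integer vector of length n.
#' @export
bootstrap_indices <- function(n, rng_seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("n must be a positive integer")
  }
  with_seed(rng_seed, sample.int(n, n, replace = TRUE))
}

#' Random feature subset
#'
#' Uniform sample of d distinct column indices out of p, sorted ascending
#' for determinism. Induces the random-subspace diversity of the ensemble.
#'
#' @param p Total feature count.
#' @param d Subset size, `1 <= d <= p`.
#' @param rng_seed Integer seed.
#' @return Sorted integer vector of length d.
#' @export
sample_features <- function(p, d, rng_seed) {
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != floor(d)) {
    stop("d must be a positive integer")
  }
  if (d > p) stop("d = ", d, " exceeds the feature count p = ", p)
  sort(with_seed(rng_seed, sample.int(p, d)))
}

#' Ensemble configuration
#'
#' Collects every tunable of the RK-KNN fit. `kernel = "none"` yields the
#' R-KNN baseline (plain-mean members; only k is tuned).
#'
#' @param B Number of ensemble members (default 1000).
#' @param d Feature-subset size per member; `NULL` (default) means
#'   `ceiling(p/2)` at fit time. Conventional choices are `p/2`, `p/5` and
#'   `sqrt(p)` — see [d_defaults()].
#' @param kernel Kernel family (see [kernel_families()]) or `"none"`.
#' @param folds CV folds for per-member tuning (default 5).
#' @param k_candidates Neighbor-count grid; `NULL` means
#'   [default_k_candidates()] at fit time.
#' @param kappas Neighbor orders for [bandwidth_candidates()]
#'   (default `c(2, 3, 5, 7)`).
#' @param master_seed Integer seed; the entire fit is a pure function of
#'   (data, config).
#' @param tune_scope `"per-member"` (default; (k, h) re-tuned by CV inside
#'   every bootstrap member) or `"global"` (tuned once on the full training
#'   set and reused by all members — much cheaper for large B).
#' @param aggregate `"mean"` (default) or `"median"` member aggregation.
#' @param resample If `FALSE`, every member uses the identity sample
#'   instead of a bootstrap draw (diagnostic hook; default `TRUE`).
#' @param tune_metric `"rmse"` (default) or `"mae"` validation metric.
#' @return A list of class `rkknn_control`.
#' @export
rkknn_control <- function(B = 1000, d = NULL, kernel = "triangular",
                          folds = 5, k_candidates = NULL,
                          kappas = c(2, 3, 5, 7), master_seed = 1,
                          tune_scope = c("per-member", "global"),
                          aggregate = c("mean", "median"),
                          resample = TRUE,
                          tune_metric = c("rmse", "mae")) {
  if (!is.numeric(B) || B < 1 || B != floor(B)) stop("B must be a positive integer")
  if (!identical(kernel, "none")) check_family(kernel)
  structure(
    list(B = as.integer(B), d = d, kernel = kernel, folds = as.integer(folds),
         k_candidates = k_candidates, kappas = kappas,
         master_seed = as.integer(master_seed),
         tune_scope = match.arg(tune_scope),
         aggregate = match.arg(aggregate),
         resample = isTRUE(resample),
         tune_metric = match.arg(tune_metric)),
    class = "rkknn_control"
  )
}

#' Conventional feature-subset sizes
#'
#' The three customary subset sizes for random-subspace KNN ensembles:
#' half the features, a fifth of the features, and the square root of the
#' feature count (each at least 1, rounded up).
#'
#' @param p Feature count.
#' @return Named integer vector with elements `half`, `fifth`, `sqrt`.
#' @export
d_defaults <- function(p) {
  c(half = max(1L, as.integer(ceiling(p / 2))),
    fifth = max(1L, as.integer(ceiling(p / 5))),
    sqrt = max(1L, as.integer(ceiling(sqrt(p)))))
}

#' Fit a random kernel KNN ensemble
#'
#' Fits the min-max scaler on the training features, then builds B ensemble
#' members: each draws a bootstrap sample of the rows and a random subset of
#' d features (seeds derived deterministically from the master seed), selects
#' its neighbor count k and bandwidth h by cross-validated grid search on its
#' own bootstrap sample (bandwidth candidates recomputed on that restricted
#' sample), and predicts by kernel-weighted neighbor averaging. With
#' `kernel = "none"` members are plain-mean KNN models (the R-KNN baseline).
#'
#' @param data An [rk_dataset()] with the raw (unscaled) features.
#' @param control An [rkknn_control()].
#' @return An object of class `rkknn`: config, fitted scaler, scaled
#'   training data and the list of members (each with `bootstrap_indices`,
#'   `feature_subset`, `k_opt`, `h_opt`).
#' @examples
#' d <- sine_dataset(n = 60, seed = 7)
#' m <- rkknn_fit(d, rkknn_control(B = 5, master_seed = 1))
#' predict(m, matrix(c(1, 2)))
#' @export
rkknn_fit <- function(data, control = rkknn_control()) {
  stopifnot(inherits(data, "rk_dataset"), inherits(control, "rkknn_control"))
  p <- data$p
  n <- data$n
  d <- control$d
  if (is.null(d)) d <- d_defaults(p)[["half"]]
  if (d < 1 || d > p) {
    stop("feature-subset size d = ", d, " is outside [1, p = ", p, "]")
  }
  k_cands <- control$k_candidates
  if (is.null(k_cands)) k_cands <- default_k_candidates(n, control$folds)
  cap <- floor(n * (control$folds - 1) / control$folds)
  if (min(k_cands) > cap) {
    stop("no admissible k candidate: smallest k = ", min(k_cands),
         " exceeds the training-fold capacity ", cap)
  }
  k_cands <- k_cands[k_cands <= cap]

  scaler <- fit_scaler(data$X)
  Xs <- apply_scaler(scaler, data$X)
  sdata <- rk_dataset(Xs, data$y, data$feature_names)

  B <- control$B
  seeds <- matrix(derive_seeds(control$master_seed, 3L * B), ncol = 3L)

  kernel <- control$kernel
  global_tune <- NULL
  if (control$tune_scope == "global") {
    h_cands <- if (kernel == "none") NULL else
      bandwidth_candidates(Xs, control$kappas)
    global_tune <- grid_search(sdata, k_cands, h_cands, family = kernel,
                               folds = control$folds,
                               seed = control$master_seed,
                               metric = control$tune_metric)
  }

  members <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- if (control$resample) bootstrap_indices(n, seeds[b, 1L]) else seq_len(n)
    feats <- sample_features(p, d, seeds[b, 2L])
    if (is.null(global_tune)) {
      Xb <- Xs[idx, feats, drop = FALSE]
      mdata <- rk_dataset(Xb, data$y[idx], data$feature_names[feats])
      h_cands <- if (kernel == "none") NULL else
        bandwidth_candidates(Xb, control$kappas)
      tune <- grid_search(mdata, k_cands, h_cands, family = kernel,
                          folds = control$folds, seed = seeds[b, 3L],
                          metric = control$tune_metric)
    } else {
      tune <- global_tune
    }
    members[[b]] <- list(bootstrap_indices = idx, feature_subset = feats,
                         k_opt = tune$k_opt, h_opt = tune$h_opt)
  }

  structure(
    list(control = control, d = as.integer(d), scaler = scaler,
         X = Xs, y = data$y, feature_names = data$feature_names,
         members = members),
    class = "rkknn"
  )
}

#' @export
print.rkknn <- function(x, ...) {
  cat("rkknn ensemble:", length(x$members), "members, kernel =",
      x$control$kernel, "\n")
  cat("  training data: n =", nrow(x$X), " p =", ncol(x$X),
      " d =", x$d, "\n")
  ks <- vapply(x$members, `[[`, integer(1), "k_opt")
  cat("  tuned k range: [", min(ks), ",", max(ks), "]\n")
  invisible(x)
}

#' Predict from a fitted RK-KNN ensemble
#'
#' Scales the query rows with the stored training scaler, lets every member
#' predict by kernel-weighted (or plain, for R-KNN) neighbor averaging over
#' its own bootstrap rows and feature subset, and aggregates members by the
#' configured statistic (mean by default).
#'
#' @param object A fitted [rkknn_fit()] model.
#' @param newdata Numeric matrix (or data frame) with the training column
#'   count, raw scale.
#' @param per_member If `TRUE`, also return the m x B member prediction
#'   matrix.
#' @param ... Unused.
#' @return Numeric vector of length `nrow(newdata)`; with
#'   `per_member = TRUE`, a list with `aggregate` and `members`.
#' @export
predict.rkknn <- function(object, newdata, per_member = FALSE, ...) {
  X0 <- as.matrix(newdata)
  if (ncol(X0) != ncol(object$X)) {
    stop("newdata has ", ncol(X0), " columns but the model was trained on ",
         ncol(object$X))
  }
  X0s <- apply_scaler(object$scaler, X0)
  m <- nrow(X0s)
  B <- length(object$members)
  kernel <- object$control$kernel
  P <- matrix(0, m, B)
  for (b in seq_len(B)) {
    mem <- object$members[[b]]
    Xb <- object$X[mem$bootstrap_indices, mem$feature_subset, drop = FALSE]
    yb <- object$y[mem$bootstrap_indices]
    Dm <- cross_dist(X0s[, mem$feature_subset, drop = FALSE], Xb)
    k <- mem$k_opt
    for (i in seq_len(m)) {
      ord <- stable_order(Dm[i, ])[seq_len(k)]
      ns <- list(distances = Dm[i, ord])
      P[i, b] <- if (kernel == "none") {
        knn_predict(yb[ord])
      } else {
        kernel_knn_predict(ns, yb[ord], kernel, mem$h_opt)
      }
    }
  }
  agg <- if (object$control$aggregate == "median") {
    apply(P, 1L, stats::median)
  } else {
    rowMeans(P)
  }
  if (per_member) list(aggregate = agg, members = P) else agg
}

#' Fit a plain cross-validation-tuned KNN baseline
#'
#' Min-max scaler plus a single KNN model on the full feature set whose
#' neighbor count k is chosen by seeded cross-validated grid search;
#' prediction is the unweighted mean of the k nearest responses.
#'
#' @param data An [rk_dataset()], raw features.
#' @param k_candidates Neighbor-count grid (default
#'   [default_k_candidates()]).
#' @param folds CV folds (default 5).
#' @param seed Fold-partition seed.
#' @param metric `"rmse"` (default) or `"mae"`.
#' @return Object of class `plain_knn` with the scaler, training data,
#'   `k_opt` and the CV table.
#' @export
fit_plain_knn <- function(data, k_candidates = NULL, folds = 5, seed = 1,
                          metric = c("rmse", "mae")) {
  stopifnot(inherits(data, "rk_dataset"))
  metric <- match.arg(metric)
  if (is.null(k_candidates)) k_candidates <- default_k_candidates(data$n, folds)
  scaler <- fit_scaler(data$X)
  Xs <- apply_scaler(scaler, data$X)
  sdata <- rk_dataset(Xs, data$y, data$feature_names)
  tune <- grid_search(sdata, k_candidates, NULL, family = "none",
                      folds = folds, seed = seed, metric = metric)
  structure(
    list(scaler = scaler, X = Xs, y = data$y, k_opt = tune$k_opt,
         cv_table = tune$cv_table),
    class = "plain_knn"
  )
}

#' @export
print.plain_knn <- function(x, ...) {
  cat("plain KNN: k_opt =", x$k_opt, " n =", nrow(x$X),
      " p =", ncol(x$X), "\n")
  invisible(x)
}

#' @rdname fit_plain_knn
#' @param object A fitted `plain_knn` model.
#' @param newdata Query matrix on the raw scale.
#' @param ... Unused.
#' @export
predict.plain_knn <- function(object, newdata, ...) {
  X0 <- as.matrix(newdata)
  X0s <- apply_scaler(object$scaler, X0)
  Dm <- cross_dist(X0s, object$X)
  k <- object$k_opt
  vapply(seq_len(nrow(X0s)), function(i) {
    ord <- stable_order(Dm[i, ])[seq_len(k)]
    mean(object$y[ord])
  }, numeric(1))
}

#' Choose the feature-subset size d on held-out data
#'
#' Outer model selection over candidate subset sizes: each candidate d gets
#' a full RK-KNN fit on a training portion and is scored on the held-out
#' remainder (default) or by outer cross-validation; the d with the lowest
#' RMSE wins.
#'
#' @param data An [rk_dataset()].
#' @param control Base [rkknn_control()]; its `d` is overridden per
#'   candidate.
#' @param d_candidates Integer vector of subset sizes (default
#'   [d_defaults()]).
#' @param method `"holdout"` (default, 70/30 split) or `"cv"` (outer
#'   folds).
#' @param holdout_frac Training fraction for the holdout split.
#' @param outer_folds Folds for `method = "cv"`.
#' @param seed Seed for the outer split.
#' @return List with `d_best`, `scores` (data frame of d and RMSE) and the
#'   refitted model at `d_best` on the full data.
#' @export
select_d <- function(data, control = rkknn_control(),
                     d_candidates = NULL, method = c("holdout", "cv"),
                     holdout_frac = 0.7, outer_folds = 5, seed = 1) {
  stopifnot(inherits(data, "rk_dataset"))
  method <- match.arg(method)
  if (is.null(d_candidates)) d_candidates <- unique(d_defaults(data$p))
  d_candidates <- sort(unique(as.integer(d_candidates)))
  if (any(d_candidates < 1 | d_candidates > data$p)) {
    stop("d candidates must lie in [1, p]")
  }
  score_one <- function(d) {
    ctl <- control
    ctl$d <- d
    if (method == "holdout") {
      n_tr <- max(2L, floor(holdout_frac * data$n))
      tr <- with_seed(seed, sample.int(data$n, n_tr))
      te <- setdiff(seq_len(data$n), tr)
      dtr <- rk_dataset(data$X[tr, , drop = FALSE], data$y[tr],
                        data$feature_names)
      fit <- rkknn_fit(dtr, ctl)
      rmse(data$y[te], predict(fit, data$X[te, , drop = FALSE]))
    } else {
      fold_id <- make_folds(data$n, outer_folds, seed)
      errs <- vapply(seq_len(outer_folds), function(f) {
        tr <- which(fold_id != f)
        te <- which(fold_id == f)
        dtr <- rk_dataset(data$X[tr, , drop = FALSE], data$y[tr],
                          data$feature_names)
        fit <- rkknn_fit(dtr, ctl)
        rmse(data$y[te], predict(fit, data$X[te, , drop = FALSE]))
      }, numeric(1))
      mean(errs)
    }
  }
  scores <- data.frame(d = d_candidates,
                       rmse = vapply(d_candidates, score_one, numeric(1)))
  d_best <- scores$d[which.min(scores$rmse)]
  ctl <- control
  ctl$d <- d_best
  list(d_best = d_best, scores = scores, model = rkknn_fit(data, ctl))
}
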