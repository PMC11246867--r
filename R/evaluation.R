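#' Regression error metrics
#'
#' Root-mean-square error, mean absolute error and the coefficient of
#' determination on an evaluation set. `r_squared` uses the evaluation-set
#' mean in the total sum of squares and can be negative when the model
#' underperforms the mean predictor; it is undefined for a constant
#' response.
#'
#' @param y Observed responses.
#' @param yhat Predictions, same length.
#' @return A nonnegative scalar (`rmse`, `mae`) or a scalar `<= 1`
#'   (`r_squared`).
#' @examples
#' rmse(c(0, 2), c(1, 1))      # 1
#' r_squared(c(0, 2), c(1, 1)) # 0
#' @export
rmse <- function(y, yhat) {
  check_metric_args(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse
#' @export
mae <- function(y, yhat) {
  check_metric_args(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname rmse
#' @export
r_squared <- function(y, yhat) {
  check_metric_args(y, yhat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("R-squared is undefined for a constant response")
  }
  1 - sum((y - yhat)^2) / ss_tot
}

check_metric_args <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop("y (", length(y), ") and yhat (", length(yhat),
         ") differ in length")
  }
  if (length(y) < 1L) stop("empty vectors")
  if (any(!is.finite(y)) || any(!is.finite(yhat))) {
    stop("non-finite values in metric inputs")
  }
  invisible(TRUE)
}

#' Metrics report for several methods on one test set
#'
#' @param y Observed test responses.
#' @param predictions Named list of prediction vectors, one per method.
#' @return Data frame with columns `method`, `rmse`, `mae`, `r2`.
#' @export
metrics_report <- function(y, predictions) {
  stopifnot(is.list(predictions), length(predictions) > 0,
            !is.null(names(predictions)))
  data.frame(
    method = names(predictions),
    rmse = vapply(predictions, function(p) rmse(y, p), numeric(1)),
    mae = vapply(predictions, function(p) mae(y, p), numeric(1)),
    r2 = vapply(predictions, function(p) r_squared(y, p), numeric(1)),
    row.names = NULL
  )
}

#' Competition ranks
#'
#' Rank of item i is 1 plus the number of strictly better items; ties share
#' the same (minimum) rank. The best value — lowest for errors, highest for
#' R-squared — receives rank 1.
#'
#' @param values Finite numeric vector.
#' @param lower_is_better If `TRUE` (default) small values rank first.
#' @return Integer vector of ranks.
#' @examples
#' competition_ranks(c(1, 1, 2)) # 1 1 3
#' @export
competition_ranks <- function(values, lower_is_better = TRUE) {
  if (length(values) == 0L) stop("empty values")
  if (any(!is.finite(values))) stop("non-finite values cannot be ranked")
  v <- if (lower_is_better) values else -values
  vapply(v, function(x) 1L + sum(v < x), integer(1))
}

#' Per-dataset rank matrix of methods under one metric
#'
#' Builds the datasets x methods matrix of competition ranks from a long
#' metrics table (one row per dataset/method pair).
#'
#' @param metrics Data frame with columns `dataset`, `method` and the
#'   metric columns (`rmse`, `mae`, `r2`).
#' @param metric Which column to rank on.
#' @param methods Optional method ordering for the columns.
#' @return Integer matrix, rownames = datasets, colnames = methods, with
#'   attribute `lower_is_better`.
#' @export
rank_matrix <- function(metrics, metric = c("rmse", "mae", "r2"),
                        methods = NULL) {
  metric <- match.arg(metric)
  stopifnot(all(c("dataset", "method", metric) %in% names(metrics)))
  lower <- metric != "r2"
  datasets <- unique(metrics$dataset)
  if (is.null(methods)) methods <- unique(metrics$method)
  M <- matrix(NA_integer_, length(datasets), length(methods),
              dimnames = list(datasets, methods))
  for (ds in datasets) {
    rows <- metrics[metrics$dataset == ds, ]
    if (!setequal(rows$method, methods)) {
      stop("dataset ", ds, " does not cover every method")
    }
    vals <- rows[[metric]][match(methods, rows$method)]
    M[ds, ] <- competition_ranks(vals, lower_is_better = lower)
  }
  attr(M, "lower_is_better") <- lower
  M
}

#' Average ranks per method
#'
#' Column means of a rank matrix, rounded half-away-from-zero to two
#' decimals — the conventional summary for comparing methods across many
#' datasets.
#'
#' @param ranks Matrix from [rank_matrix()] (datasets x methods).
#' @return Named numeric vector of mean ranks.
#' @export
average_ranks <- function(ranks) {
  if (any(is.na(ranks))) stop("rank matrix has missing entries")
  round_half_up(colMeans(ranks), 2)
}

#' Bundled benchmark metrics table
#'
#' The published benchmark comparison of eight methods (plain KNN, R-KNN,
#' and RK-KNN with six kernels) across 15 regression datasets, as RMSE, MAE
#' and R-squared values. Used to rebuild the per-dataset rank matrices and
#' average-rank summaries.
#'
#' @return Data frame with columns `dataset`, `method`, `rmse`, `mae`,
#'   `r2` (15 x 8 rows).
#' @export
table2_metrics <- function() {
  path <- system.file("extdata", "table2_metrics.csv", package = "rkknn",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Average-rank report across all three metrics
#'
#' Convenience wrapper: builds the RMSE, MAE and R-squared rank matrices
#' from a long metrics table and returns the per-method average ranks under
#' each metric.
#'
#' @param metrics Long metrics data frame (see [rank_matrix()]); defaults
#'   to the bundled benchmark table.
#' @return Data frame with columns `method`, `rmse`, `mae`, `r2` of
#'   average ranks.
#' @export
rank_report <- function(metrics = table2_metrics()) {
  methods <- unique(metrics$method)
  out <- data.frame(method = methods)
  for (m in c("rmse", "mae", "r2")) {
    out[[m]] <- average_ranks(rank_matrix(metrics, m, methods))[methods]
  }
  rownames(out) <- NULL
  out
}

#' Bar chart of average ranks
#'
#' Simple base-graphics visualization of an [average_ranks()] vector.
#'
#' @param avg Named numeric vector of average ranks.
#' @param main Plot title.
#' @return Invisibly, the bar midpoints.
#' @export
plot_average_ranks <- function(avg, main = "Average ranks (lower is better)") {
  ord <- order(avg)
  graphics::barplot(avg[ord], las = 2, ylab = "average rank", main = main)
}
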