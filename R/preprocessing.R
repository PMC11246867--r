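#' Fit a min-max scaler
#'
#' Records the per-feature minimum and maximum of the training matrix.
#' Distance-based learners need unitless predictors; all features are mapped
#' into \[0, 1\] on the training data so no single feature dominates the
#' Euclidean distance and kernel bandwidths live on a bounded scale.
#'
#' @param X Numeric training matrix, n x p.
#' @return An object of class `rk_scaler`: list with `min` and `max`
#'   vectors of length p.
#' @examples
#' s <- fit_scaler(matrix(c(0, 10), 2, 1))
#' apply_scaler(s, matrix(5)) # 0.5
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X) || nrow(X) < 1L) {
    stop("X must be a numeric matrix with at least one row")
  }
  if (any(!is.finite(X))) {
    bad <- which(colSums(!is.finite(X)) > 0)
    nm <- if (!is.null(colnames(X))) colnames(X)[bad] else paste0("x", bad)
    stop("missing or non-finite values in columns: ",
         paste(nm, collapse = ", "))
  }
  structure(
    list(min = apply(X, 2, min), max = apply(X, 2, max)),
    class = "rk_scaler"
  )
}

#' Apply a fitted min-max scaler
#'
#' Maps each entry to `(x - min) / (max - min)` using the training
#' extrema. Constant training columns (max equal to min) map to 0
#' everywhere, so they contribute nothing to any distance. Query values
#' outside the training range are NOT clipped: values below the training
#' minimum or above the maximum scale to numbers outside \[0, 1\], keeping
#' distances faithful to the data.
#'
#' @param scaler An `rk_scaler` from [fit_scaler()].
#' @param X Numeric matrix with the same column count as the training data.
#' @return Scaled matrix of the same shape.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "rk_scaler"))
  X <- as.matrix(X)
  p <- length(scaler$min)
  if (ncol(X) != p) {
    stop("scaler was fit on ", p, " columns but X has ", ncol(X))
  }
  range <- scaler$max - scaler$min
  out <- sweep(X, 2, scaler$min, "-")
  nonconst <- range > 0
  out[, nonconst] <- sweep(out[, nonconst, drop = FALSE], 2,
                           range[nonconst], "/")
  out[, !nonconst] <- 0
  out
}
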