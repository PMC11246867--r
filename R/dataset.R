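#' Construct a regression dataset
#'
#' Bundles a numeric feature matrix and response vector, the universe every
#' stage of the package consumes. All entries must be finite; the response
#' length must match the row count.
#'
#' @param X Numeric matrix (or coercible data frame), n rows by p columns.
#' @param y Numeric response vector of length n.
#' @param feature_names Optional character vector of p column names;
#'   defaults to existing column names or `x1..xp`.
#' @return An object of class `rk_dataset`: list with elements `X`, `y`,
#'   `feature_names`, `n`, `p`.
#' @examples
#' d <- rk_dataset(matrix(rnorm(20), 10, 2), rnorm(10))
#' d$n; d$p
#' @export
rk_dataset <- function(X, y, feature_names = NULL) {
  if (is.data.frame(X)) {
    bad <- names(X)[!vapply(X, is.numeric, logical(1))]
    if (length(bad)) {
      stop("non-numeric feature columns: ", paste(bad, collapse = ", "))
    }
    X <- as.matrix(X)
  }
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("X must be a numeric matrix or all-numeric data frame")
  }
  if (!is.numeric(y)) stop("y must be numeric")
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop("X has ", nrow(X), " rows but y has length ", length(y))
  }
  if (any(!is.finite(X))) {
    bad <- which(colSums(!is.finite(X)) > 0)
    nm <- if (!is.null(colnames(X))) colnames(X)[bad] else paste0("x", bad)
    stop("non-finite feature values in columns: ", paste(nm, collapse = ", "))
  }
  if (any(!is.finite(y))) stop("non-finite values in response")
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X)))
  }
  if (length(feature_names) != ncol(X)) {
    stop("feature_names length ", length(feature_names),
         " does not match p = ", ncol(X))
  }
  colnames(X) <- feature_names
  structure(
    list(X = X, y = y, feature_names = feature_names,
         n = nrow(X), p = ncol(X)),
    class = "rk_dataset"
  )
}

#' @export
print.rk_dataset <- function(x, ...) {
  cat("rk_dataset: n =", x$n, " p =", x$p, "\n")
  cat("  response range: [", min(x$y), ",", max(x$y), "]\n")
  invisible(x)
}

#' Read a dataset from CSV
#'
#' Reads a comma-separated file with a header row; the named response column
#' becomes `y` and every other column a feature. All feature columns must be
#' numeric.
#'
#' @param path Path to a CSV file.
#' @param response_column Name of the response column (default `"y"`).
#' @return An [rk_dataset()].
#' @export
read_dataset <- function(path, response_column = "y") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty dataset file: ", path)
  if (!(response_column %in% names(df))) {
    stop("response column '", response_column, "' not found; available: ",
         paste(names(df), collapse = ", "))
  }
  y <- df[[response_column]]
  if (!is.numeric(y)) stop("response column '", response_column,
                           "' is not numeric")
  Xdf <- df[setdiff(names(df), response_column)]
  if (ncol(Xdf) == 0L) stop("no feature columns in ", path)
  rk_dataset(Xdf, y)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_dataset()]: features as named columns plus the response
#' column.
#'
#' @param data An [rk_dataset()].
#' @param path Output CSV path.
#' @param response_column Response column name (default `"y"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, response_column = "y") {
  stopifnot(inherits(data, "rk_dataset"))
  df <- as.data.frame(data$X)
  df[[response_column]] <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
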