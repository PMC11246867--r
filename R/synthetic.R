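#' Synthetic one-dimensional sine benchmark
#'
#' Draws x uniformly on `x_range` and sets
#' `y = sin(x) + sin(2x) + rnorm(n, 0, noise_sd)` — a smooth bimodal target
#' on which nonparametric smoothers are easy to visualize and to test
#' against the known truth.
#'
#' @param n Sample size (>= 2).
#' @param noise_sd Noise standard deviation (default 0.3).
#' @param x_range Length-2 range of x (default `c(0, 2*pi)`).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return An [rk_dataset()] with p = 1 (feature `x`). The attribute
#'   `truth` holds the noiseless regression function.
#' @examples
#' d <- sine_dataset(100, seed = 1)
#' attr(d, "truth")(pi) # 0
#' @export
sine_dataset <- function(n, noise_sd = 0.3, x_range = c(0, 2 * pi),
                         seed = 1) {
  if (n < 2) stop("n must be at least 2")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (length(x_range) != 2L || x_range[2] <= x_range[1]) {
    stop("x_range must be an increasing length-2 vector")
  }
  f <- function(x) sin(x) + sin(2 * x)
  dat <- with_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    y <- f(x) + stats::rnorm(n, 0, noise_sd)
    list(x = x, y = y)
  })
  out <- rk_dataset(matrix(dat$x, ncol = 1), dat$y, "x")
  attr(out, "truth") <- f
  out
}

#' Synthetic small-n / large-p nonlinear benchmark
#'
#' Emulates the shape of high-dimensional molecular-descriptor regression
#' tables: features uniform on \[0, 1\], a sparse nonlinear signal
#' `y = sum_j c_j sin(2 pi x_j)` over the first `n_informative` columns
#' (seeded coefficients `c_j` uniform on \[0.5, 2\]), the remaining
#' `p - n_informative` columns pure noise, plus Gaussian response noise.
#'
#' @param n Sample size.
#' @param p Feature count.
#' @param n_informative Number of signal-carrying columns,
#'   `1 <= n_informative <= p`.
#' @param noise_sd Response noise standard deviation (default 0.3).
#' @param seed Integer seed.
#' @return An [rk_dataset()]; attribute `truth` holds the noiseless
#'   regression function of a feature matrix, attribute `informative` the
#'   informative column indices.
#' @export
highdim_dataset <- function(n, p, n_informative, noise_sd = 0.3, seed = 1) {
  if (n < 2) stop("n must be at least 2")
  if (n_informative < 1 || n_informative > p) {
    stop("n_informative must lie in [1, p]")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  dat <- with_seed(seed, {
    coef <- stats::runif(n_informative, 0.5, 2)
    X <- matrix(stats::runif(n * p), n, p)
    eps <- stats::rnorm(n, 0, noise_sd)
    list(coef = coef, X = X, eps = eps)
  })
  f <- function(X) {
    X <- as.matrix(X)
    as.vector(sin(2 * pi * X[, seq_len(n_informative), drop = FALSE]) %*%
                dat$coef)
  }
  y <- f(dat$X) + dat$eps
  out <- rk_dataset(dat$X, y)
  attr(out, "truth") <- f
  attr(out, "informative") <- seq_len(n_informative)
  out
}
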