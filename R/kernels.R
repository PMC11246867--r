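#' Kernel weighting families
#'
#' The six kernel families available for distance weighting in kernel KNN
#' regression.
#'
#' @return Character vector of family names.
#' @export
kernel_families <- function() {
  c("gaussian", "epanechnikov", "uniform", "triangular", "quartic", "tricube")
}

check_family <- function(family) {
  if (!is.character(family) || length(family) != 1L ||
      !(family %in% kernel_families())) {
    stop("unknown kernel family: ", deparse(family),
         "; must be one of ", paste(kernel_families(), collapse = ", "))
  }
  family
}

#' Kernel weight of a distance
#'
#' Evaluates the kernel weighting profile `K(u; h)` used to weight a
#' neighbor at Euclidean distance `u` from the query, with bandwidth `h`.
#' The five compact-support families (epanechnikov, uniform, triangular,
#' quartic, tricube) assign weight zero whenever `u >= h` (strict support
#' `u < h`); the Gaussian assigns positive weight everywhere, with `h`
#' playing the role of the standard deviation sigma:
#'
#' \describe{
#'   \item{gaussian}{`exp(-u^2 / (2 h^2))`}
#'   \item{epanechnikov}{`3/4 (1 - u^2/h^2)` for `u < h`}
#'   \item{uniform}{`1/(2h)` for `u < h`}
#'   \item{triangular}{`1 - u/h` for `u < h`}
#'   \item{quartic}{`15/16 (1 - (u/h)^2)^2` for `u < h`}
#'   \item{tricube}{`70/81 (1 - (u/h)^3)^3` for `u < h`}
#' }
#'
#' The normalizing constants cancel in the kernel-weighted average but are
#' retained so each profile matches its textbook form.
#'
#' @param family One of [kernel_families()].
#' @param u Nonnegative numeric vector of distances.
#' @param h Positive scalar bandwidth.
#' @return Numeric vector of nonnegative weights, same length as `u`.
#' @examples
#' kernel_weight("epanechnikov", 0, 1)   # 0.75
#' kernel_weight("tricube", 0, 1)        # 70/81
#' kernel_weight("triangular", c(0, 0.5, 1), 1)
#' @export
kernel_weight <- function(family, u, h) {
  check_family(family)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("bandwidth h must be a positive finite scalar, got ", deparse(h))
  }
  if (!is.numeric(u) || any(!is.finite(u)) || any(u < 0)) {
    stop("distances u must be finite and nonnegative")
  }
  t <- u / h
  inside <- t < 1
  w <- switch(family,
    gaussian     = exp(-u^2 / (2 * h^2)),
    epanechnikov = 0.75 * (1 - t^2) * inside,
    uniform      = (1 / (2 * h)) * inside,
    triangular   = (1 - t) * inside,
    quartic      = (15 / 16) * (1 - t^2)^2 * inside,
    tricube      = (70 / 81) * (1 - t^3)^3 * inside
  )
  as.numeric(w)
}

#' Numerical moment checks of a kernel profile
#'
#' Computes, by composite-trapezoid quadrature, the mass, first moment and
#' second moment of the one-dimensional unit-bandwidth kernel profile: the
#' three conditions a kernel weighting function must satisfy (integrates to
#' one, zero mean, positive finite variance). Compact-support profiles are
#' integrated over \[-1, 1\]; the Gaussian is integrated as the standard
#' normal density over \[-8, 8\] (tail mass below 1e-14).
#'
#' Note the Gaussian used for prediction weights is unnormalized
#' (`exp(-u^2/2)` at `h = 1`); the moment check uses its density-normalized
#' form `dnorm(t)`, which carries the same shape.
#'
#' @param family One of [kernel_families()].
#' @param resolution Number of quadrature nodes, at least 100 (default 1e5).
#' @return Named list with `mass`, `first_moment`, `second_moment`.
#' @examples
#' kernel_moments("epanechnikov")$mass        # ~1
#' kernel_moments("uniform")$second_moment    # ~1/3
#' @export
kernel_moments <- function(family, resolution = 1e5) {
  check_family(family)
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution < 100) {
    stop("resolution must be a single number >= 100")
  }
  resolution <- as.integer(resolution)
  L <- if (family == "gaussian") 8 else 1
  t <- seq(-L, L, length.out = resolution)
  f <- if (family == "gaussian") {
    stats::dnorm(t)
  } else {
    kernel_weight(family, abs(t), 1)
  }
  trap <- function(g) {
    dx <- t[2L] - t[1L]
    dx * (sum(g) - 0.5 * (g[1L] + g[resolution]))
  }
  list(
    mass          = trap(f),
    first_moment  = trap(t * f),
    second_moment = trap(t^2 * f)
  )
}
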