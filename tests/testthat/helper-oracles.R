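# Independent brute-force reference implementations used to cross-check the
# package's predictors. These deliberately share no code with the package:
# distances by explicit summation, neighbor selection by full sort.

oracle_distance <- function(a, b) {
  s <- 0
  for (j in seq_along(a)) s <- s + (a[j] - b[j])^2
  sqrt(s)
}

oracle_neighbors <- function(Xtr, x0, k) {
  d <- apply(Xtr, 1L, oracle_distance, b = x0)
  ord <- order(d, seq_along(d))
  list(indices = ord[seq_len(k)], distances = d[ord[seq_len(k)]])
}

oracle_knn_mean <- function(Xtr, ytr, x0, k) {
  nb <- oracle_neighbors(Xtr, x0, k)
  sum(ytr[nb$indices]) / k
}

# Direct weighted-average arithmetic with explicit kernel formulas.
oracle_kernel_value <- function(family, u, h) {
  t <- u / h
  if (family == "gaussian") return(exp(-u^2 / (2 * h^2)))
  if (t >= 1) return(0)
  switch(family,
    epanechnikov = 3 / 4 * (1 - t^2),
    uniform      = 1 / (2 * h),
    triangular   = 1 - t,
    quartic      = 15 / 16 * (1 - t^2)^2,
    tricube      = 70 / 81 * (1 - t^3)^3
  )
}

oracle_kernel_knn <- function(Xtr, ytr, x0, k, family, h) {
  nb <- oracle_neighbors(Xtr, x0, k)
  w <- vapply(nb$distances, oracle_kernel_value, numeric(1),
              family = family, h = h)
  y <- ytr[nb$indices]
  if (sum(w) == 0) return(mean(y))
  sum(w * y) / sum(w)
}

# Small random regression instance for oracle-equivalence loops.
random_instance <- function(seed, n_max = 30, p_max = 5) {
  set.seed(seed)
  n <- sample(5:n_max, 1)
  p <- sample(1:p_max, 1)
  list(X = matrix(runif(n * p), n, p), y = rnorm(n), n = n, p = p)
}
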