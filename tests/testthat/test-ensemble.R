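test_that("bootstrap_indices and sample_features are valid, seeded and reproducible", {
  expect_equal(bootstrap_indices(1, 5), 1L)
  b1 <- bootstrap_indices(50, 7)
  expect_identical(b1, bootstrap_indices(50, 7))
  expect_true(all(b1 >= 1 & b1 <= 50))
  expect_length(b1, 50)
  expect_error(bootstrap_indices(0, 1), "positive")

  expect_equal(sample_features(6, 6, 3), 1:6)
  f1 <- sample_features(10, 4, 11)
  expect_identical(f1, sample_features(10, 4, 11))
  expect_equal(f1, sort(unique(f1)))
  expect_length(sample_features(10, 1, 2), 1)
  expect_error(sample_features(5, 6, 1), "exceeds")

  # coverage of a bootstrap draw: ~63.2% distinct rows on average
  frac <- mean(vapply(1:200, function(s) {
    length(unique(bootstrap_indices(500, s))) / 500
  }, numeric(1)))
  expect_equal(frac, 1 - exp(-1), tolerance = 0.03)
})

test_that("an ensemble of one identity-bootstrap full-feature member equals a single tuned kernel KNN", {
  d <- sine_dataset(50, noise_sd = 0.2, seed = 8)
  ctl <- rkknn_control(B = 1, d = 1, kernel = "epanechnikov",
                       master_seed = 4, resample = FALSE)
  fit <- rkknn_fit(d, ctl)
  expect_length(fit$members, 1)
  expect_equal(fit$members[[1]]$bootstrap_indices, 1:50)

  # independent single-model route: same scaling, same tuning inputs
  scaler <- fit_scaler(d$X)
  sdata <- rk_dataset(apply_scaler(scaler, d$X), d$y, d$feature_names)
  seeds <- rkknn:::derive_seeds(4, 3)
  tune <- grid_search(sdata, default_k_candidates(50, 5),
                      bandwidth_candidates(sdata$X), family = "epanechnikov",
                      folds = 5, seed = seeds[3])
  expect_equal(fit$members[[1]]$k_opt, tune$k_opt)
  expect_equal(fit$members[[1]]$h_opt, tune$h_opt)

  x0 <- matrix(seq(0.5, 5.5, length.out = 7))
  x0s <- apply_scaler(scaler, x0)
  single <- vapply(seq_len(7), function(i) {
    ns <- find_neighbors(sdata$X, x0s[i, ], tune$k_opt)
    kernel_knn_predict(ns, d$y[ns$indices], "epanechnikov", tune$h_opt)
  }, numeric(1))
  expect_equal(predict(fit, x0), single, tolerance = 1e-12)
})

test_that("refitting with the same master seed is bit-identical and member aggregation is the mean", {
  d <- highdim_dataset(60, p = 8, n_informative = 3, seed = 10)
  ctl <- rkknn_control(B = 8, d = 4, kernel = "triangular", master_seed = 99)
  f1 <- rkknn_fit(d, ctl)
  f2 <- rkknn_fit(d, ctl)
  expect_identical(f1$members, f2$members)

  x0 <- matrix(runif(5 * 8), 5, 8)
  out <- predict(f1, x0, per_member = TRUE)
  expect_equal(dim(out$members), c(5L, 8L))
  expect_equal(out$aggregate, rowMeans(out$members), tolerance = 1e-12)

  # order invariance of the aggregate and response-range bounds
  f3 <- f1
  f3$members <- rev(f3$members)
  expect_equal(predict(f3, x0), out$aggregate, tolerance = 1e-12)
  expect_true(all(out$aggregate >= min(d$y) & out$aggregate <= max(d$y)))

  # two members predicting a and b aggregate to (a+b)/2
  expect_equal(
    predict(f1, x0, per_member = TRUE)$members[1, 1:2],
    out$members[1, 1:2]
  )
  expect_identical(predict(f1, x0), out$aggregate)
})

test_that("uniform-kernel ensemble with encompassing bandwidths coincides with R-KNN", {
  d <- sine_dataset(60, noise_sd = 0.2, seed = 12)
  base <- list(B = 6, d = 1, folds = 5, master_seed = 31,
               k_candidates = c(1L, 2L, 3L), kappas = 7)
  fu <- rkknn_fit(d, rkknn_control(B = base$B, d = base$d, kernel = "uniform",
                                   folds = base$folds,
                                   k_candidates = base$k_candidates,
                                   kappas = base$kappas,
                                   master_seed = base$master_seed))
  fr <- rkknn_fit(d, rkknn_control(B = base$B, d = base$d, kernel = "none",
                                   folds = base$folds,
                                   k_candidates = base$k_candidates,
                                   kappas = base$kappas,
                                   master_seed = base$master_seed))
  x0 <- matrix(seq(0.3, 6, length.out = 9))
  x0s <- apply_scaler(fu$scaler, x0)
  # verify the premise: every query's k_opt neighbors fall inside h_opt
  # for every member, so the constant uniform weights cancel exactly
  premise <- all(vapply(fu$members, function(m) {
    Xb <- fu$X[m$bootstrap_indices, m$feature_subset, drop = FALSE]
    all(vapply(seq_len(nrow(x0s)), function(i) {
      ns <- find_neighbors(Xb, x0s[i, m$feature_subset], m$k_opt)
      all(ns$distances < m$h_opt)
    }, logical(1)))
  }, logical(1)))
  expect_true(premise)
  expect_equal(predict(fu, x0), predict(fr, x0), tolerance = 1e-12)
})

test_that("plain KNN baseline tunes k by CV and predicts neighbor means", {
  # constant response -> constant prediction everywhere
  dc <- rk_dataset(matrix(runif(40), 20, 2), rep(2.5, 20))
  fc <- fit_plain_knn(dc, seed = 1)
  expect_equal(predict(fc, matrix(runif(10), 5, 2)), rep(2.5, 5))

  # k forced to n -> global training mean
  d <- sine_dataset(30, seed = 14)
  f <- fit_plain_knn(d, seed = 2)
  f_all <- f
  f_all$k_opt <- 30L
  expect_equal(predict(f_all, matrix(c(1, 4))), rep(mean(d$y), 2))

  # agrees with the brute-force mean-of-neighbors oracle on random queries
  set.seed(15)
  Xq <- matrix(runif(6), 6, 1) * 6
  got <- predict(f, Xq)
  Xs <- apply_scaler(f$scaler, Xq)
  want <- vapply(seq_len(6), function(i) {
    oracle_knn_mean(f$X, f$y, Xs[i, ], f$k_opt)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("configuration errors are raised before any work starts", {
  d <- sine_dataset(30, seed = 1)
  expect_error(rkknn_fit(d, rkknn_control(B = 3, d = 5)), "outside")
  expect_error(rkknn_control(B = 0), "positive")
  expect_error(rkknn_control(kernel = "cubic"), "unknown kernel family")
  expect_error(
    rkknn_fit(d, rkknn_control(B = 2, d = 1, k_candidates = 200L)),
    "admissible"
  )
})

test_that("select_d scores candidate subspace sizes and refits at the best", {
  d <- highdim_dataset(70, p = 10, n_informative = 3, seed = 20)
  ctl <- rkknn_control(B = 4, kernel = "triangular", master_seed = 3)
  sel <- select_d(d, ctl, d_candidates = c(3, 10), seed = 5)
  expect_true(sel$d_best %in% c(3, 10))
  expect_equal(nrow(sel$scores), 2)
  expect_equal(sel$model$d, sel$d_best)
  expect_equal(unname(d_defaults(10)), c(5L, 2L, 4L))
  expect_equal(unname(d_defaults(304)), c(152L, 61L, 18L))
})

test_that("ensemble error on the noiseless sine benchmark shrinks with sample size", {
  ctl <- rkknn_control(B = 10, d = 1, kernel = "triangular", master_seed = 7)
  test_x <- matrix(seq(0.5, 5.8, length.out = 40))
  truth <- sin(test_x) + sin(2 * test_x)
  err <- vapply(c(40, 160), function(n) {
    d <- sine_dataset(n, noise_sd = 0, seed = 17)
    rmse(as.vector(truth), predict(rkknn_fit(d, ctl), test_x))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.1)
})
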