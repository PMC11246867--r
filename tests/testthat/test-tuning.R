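test_that("bandwidth candidates are the global maxima of kappa-th neighbor distances", {
  # 5 collinear points: endpoints are 0.2 from their 2nd and 0.3 from their
  # 3rd nearest other point, the global maxima
  X <- matrix(c(0, 0.1, 0.2, 0.3, 0.4))
  expect_equal(bandwidth_candidates(X, kappas = 2), 0.2)
  expect_equal(bandwidth_candidates(X, kappas = c(2, 3)), c(0.2, 0.3))

  # duplicated rows give distance 0 to the first neighbor; the 2nd-nearest
  # distance is to the distant row
  Xd <- matrix(c(0, 0, 1))
  expect_equal(bandwidth_candidates(Xd, kappas = 2), 1)

  expect_error(bandwidth_candidates(X, kappas = 5), "below the number of rows")
  expect_error(bandwidth_candidates(matrix(c(1, 1, 1)), kappas = 2),
               "degenerate")

  # non-decreasing in kappa, strictly positive
  set.seed(4)
  Xr <- matrix(runif(80), 20, 4)
  h <- bandwidth_candidates(Xr, kappas = c(2, 3, 5, 7))
  expect_true(all(h > 0))
  expect_equal(h, sort(h))
})

test_that("largest bandwidth candidate encompasses all neighbors of every training point", {
  set.seed(5)
  X <- matrix(runif(60), 20, 3)
  kappas <- c(2, 3, 5, 7)
  h_max <- max(bandwidth_candidates(X, kappas))
  for (i in 1:20) {
    ns <- find_neighbors(X[-i, , drop = FALSE], X[i, ], max(kappas))
    expect_true(all(ns$distances <= h_max))
  }
})

test_that("cv_error is deterministic, zero for a constant response, and matches a two-fold oracle", {
  set.seed(6)
  d_const <- rk_dataset(matrix(runif(40), 20, 2), rep(3.5, 20))
  expect_equal(cv_error(d_const, k = 3, h = 0.5, family = "triangular",
                        folds = 5, seed = 1), 0)
  expect_equal(cv_error(d_const, k = 3, family = "none", folds = 5, seed = 1), 0)

  d <- rk_dataset(matrix(runif(90), 30, 3), rnorm(30))
  e1 <- cv_error(d, k = 4, h = 0.7, family = "quartic", folds = 5, seed = 9)
  e2 <- cv_error(d, k = 4, h = 0.7, family = "quartic", folds = 5, seed = 9)
  expect_identical(e1, e2)

  # hand-rolled two-split oracle replaying the documented fold assignment
  seed <- 13; folds <- 2L; n <- 30L
  set.seed(seed)
  perm <- sample.int(n)
  fold_id <- integer(n)
  fold_id[perm] <- rep(1:2, each = 15)
  errs <- sapply(1:2, function(f) {
    val <- which(fold_id == f); trn <- which(fold_id != f)
    pred <- sapply(val, function(i) {
      oracle_kernel_knn(d$X[trn, , drop = FALSE], d$y[trn], d$X[i, ],
                        k = 4, family = "quartic", h = 0.7)
    })
    sqrt(mean((d$y[val] - pred)^2))
  })
  expect_equal(cv_error(d, k = 4, h = 0.7, family = "quartic",
                        folds = 2, seed = seed),
               mean(errs), tolerance = 1e-10)

  expect_error(cv_error(d, k = 25, h = 0.5, family = "quartic",
                        folds = 5, seed = 1), "training-fold size")
})

test_that("grid_search finds the exhaustive argmin on one shared fold partition", {
  set.seed(7)
  d <- rk_dataset(matrix(runif(120), 40, 3), rnorm(40))
  ks <- c(2, 4, 6); hs <- c(0.4, 0.9)
  res <- grid_search(d, ks, hs, family = "epanechnikov", folds = 5, seed = 21)

  # exhaustive independent re-evaluation of all six cells
  cells <- expand.grid(k = ks, h = hs)
  cells$err <- mapply(function(k, h) {
    cv_error(d, k, h, family = "epanechnikov", folds = 5, seed = 21)
  }, cells$k, cells$h)
  best <- cells[order(cells$err, cells$k, cells$h), ][1, ]
  expect_equal(res$k_opt, best$k)
  expect_equal(res$h_opt, best$h)
  expect_equal(min(res$cv_table$mean_rmse), min(cells$err), tolerance = 1e-12)

  # cv_table minimum equals the returned pair's error
  row <- res$cv_table[res$cv_table$k == res$k_opt &
                        res$cv_table$h == res$h_opt, ]
  expect_equal(row$mean_rmse, min(res$cv_table$mean_rmse))

  # single cell grid returns that cell
  one <- grid_search(d, 3, 0.5, family = "uniform", folds = 5, seed = 2)
  expect_equal(one$k_opt, 3)
  expect_equal(one$h_opt, 0.5)
})

test_that("numerically tied grid cells resolve to smaller k then smaller h", {
  # constant response: every cell has CV error exactly 0
  d <- rk_dataset(matrix(runif(60), 20, 3), rep(1, 20))
  res <- grid_search(d, c(5, 2), c(0.9, 0.3), family = "triangular",
                     folds = 4, seed = 3)
  expect_equal(res$k_opt, 2)
  expect_equal(res$h_opt, 0.3)
  res_plain <- grid_search(d, c(7, 3), family = "none", folds = 4, seed = 3)
  expect_equal(res_plain$k_opt, 3)
  expect_true(is.na(res_plain$h_opt))
})

test_that("default k candidates respect the training-fold capacity", {
  expect_equal(default_k_candidates(100, 5), c(1L, 3L, 5L, 7L, 9L, 11L, 15L, 21L))
  expect_true(all(default_k_candidates(10, 5) <= 8))
  expect_equal(default_k_candidates(2, 2), 1L)
})
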