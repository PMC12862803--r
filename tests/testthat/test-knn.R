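test_that("basic neighbor queries return the expected points", {
  X <- matrix(c(0, 1, 2), 3, 1)
  idx <- build_index(X, mode = "euclidean")
  nb <- query_neighbors(idx, 1, 2)
  expect_setequal(nb$idx[1], 2)  # the stored middle point itself
  nb2 <- query_neighbors(idx, 0.9, 2)
  expect_equal(sort(nb2$idx), c(1, 2))
  # querying a stored point at k = 1 returns itself at distance 0
  nb3 <- query_neighbors(idx, 2, 1)
  expect_equal(nb3$idx, 3)
  expect_equal(nb3$dist, 0)
  expect_error(query_neighbors(idx, 1, 4), "k must be")
})

test_that("tree and brute backends agree exactly, including tie-breaks", {
  set.seed(51)
  X <- matrix(rnorm(500 * 10), 500, 10)
  brute <- build_index(X, backend = "brute")
  tree <- build_index(X, backend = "tree")
  for (q in 1:50) {
    query <- rnorm(10)
    k <- sample(1:20, 1)
    nb_b <- query_neighbors(brute, query, k)
    nb_t <- query_neighbors(tree, query, k)
    expect_identical(nb_t$idx, nb_b$idx)
    expect_identical(nb_t$dist, nb_b$dist)
    # independent oracle
    o <- oracle_knn(X, query, k)
    expect_equal(nb_b$idx, o$idx)
    expect_equal(nb_b$dist, o$dist, tolerance = 1e-12)
  }
})

test_that("duplicate points break distance ties by ascending stored index", {
  X <- rbind(c(0, 0), c(1, 1), c(1, 1), c(1, 1), c(3, 3))
  for (backend in c("brute", "tree")) {
    idx <- build_index(X, backend = backend)
    nb <- query_neighbors(idx, c(1, 1), 2)
    expect_equal(nb$idx, c(2, 3))
    expect_equal(nb$dist, c(0, 0))
  }
})

test_that("kernel-induced mode takes precomputed distances and rejects trees", {
  set.seed(52)
  rk <- random_psd_kernel(6, p = 3)
  D <- kernel_induced_distance(diag(rk$K), diag(rk$K), rk$K)
  expect_error(build_index(D, mode = "kernel_induced", backend = "tree"),
               "brute")
  idx <- build_index(D, mode = "kernel_induced")
  nb <- query_neighbors(idx, D[2, ], 1)
  expect_equal(nb$idx, 2)
  expect_equal(nb$dist, 0)
  # agrees with the explicit feature-map geometry
  o <- oracle_knn(rk$phi, rk$phi[2, ], 3)
  expect_equal(query_neighbors(idx, D[2, ], 3)$idx, o$idx)
})

test_that("knn_predict implements uniform and reciprocal weighting", {
  X <- matrix(c(0, 1, 2), 3, 1)
  y <- c(0, 1, 2)
  idx <- build_index(X)
  expect_equal(knn_predict(idx, y, 0, 1)$estimate, 0)           # k = 1
  expect_equal(knn_predict(idx, y, 5, 3, "uniform")$estimate, mean(y))
  # query at 0.5: both neighbors at distance 0.5, equal reciprocal weights
  expect_equal(knn_predict(idx, y, 0.5, 2, "reciprocal")$estimate, 0.5)
  # zero-distance rule: prediction is the mean of zero-distance labels
  Xz <- matrix(c(0, 0, 1), 3, 1)
  idxz <- build_index(Xz)
  expect_equal(knn_predict(idxz, c(2, 4, 9), 0, 3, "reciprocal")$estimate, 3)
  expect_error(knn_predict(idx, y, 0, 9), "k must be")
})

test_that("knn estimates are convex combinations of neighbor labels", {
  set.seed(53)
  X <- matrix(rnorm(100), 50, 2)
  y <- rnorm(50)
  idx <- build_index(X)
  for (trial in 1:20) {
    q <- rnorm(2)
    k <- sample(1:10, 1)
    w <- sample(c("uniform", "reciprocal"), 1)
    p <- knn_predict(idx, y, q, k, w)
    expect_gte(p$estimate, min(p$neighbor_labels) - 1e-12)
    expect_lte(p$estimate, max(p$neighbor_labels) + 1e-12)
    expect_true(!is.unsorted(p$neighbor_distances))
  }
})

test_that("MLKR-metric kernel regression is a softmax-weighted label average", {
  m <- mahalanobis_metric(diag(2))
  X1 <- matrix(c(0, 0), 1, 2)
  expect_equal(mlkr_kernel_regression_predict(m, X1, 7, c(100, 100)), 7)
  # constant labels are reproduced exactly
  set.seed(54)
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(mlkr_kernel_regression_predict(m, X, rep(2.5, 10), rnorm(2)),
               2.5)
  # query on a training point with all others >= 10 sigma away
  Xf <- rbind(c(0, 0), c(50, 0), c(0, 50))
  yf <- c(1, -5, 9)
  expect_equal(mlkr_kernel_regression_predict(m, Xf, yf, c(0, 0)), 1,
               tolerance = 1e-4)
  # brute-force softmax oracle
  y <- rnorm(10)
  q <- rnorm(2)
  d2 <- colSums((t(X) - q)^2)
  expect_equal(mlkr_kernel_regression_predict(m, X, y, q),
               sum(y * exp(-d2)) / sum(exp(-d2)), tolerance = 1e-10)
})

test_that("uniform-weight LOO shortcut equals explicit leave-one-out re-queries", {
  set.seed(55)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  res <- tune_k_loo(X, y, 1:10, "uniform")
  for (k in 1:10) {
    # explicit oracle: refit on n-1 points for every held-out point
    err <- vapply(seq_len(n), function(i) {
      o <- oracle_knn(X[-i, , drop = FALSE], X[i, ], k)
      abs(y[i] - mean(y[-i][o$idx]))
    }, numeric(1))
    expect_equal(unname(res$loo_mae[as.character(k)]), mean(err),
                 tolerance = 1e-12)
  }
})

test_that("reciprocal-weight LOO drops the self point and uses the next k", {
  set.seed(56)
  n <- 60
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rnorm(n)
  res <- tune_k_loo(X, y, c(1, 3, 5), "reciprocal")
  for (k in c(1, 3, 5)) {
    err <- vapply(seq_len(n), function(i) {
      o <- oracle_knn(X[-i, , drop = FALSE], X[i, ], k)
      w <- 1 / o$dist
      abs(y[i] - sum(w * y[-i][o$idx]) / sum(w))
    }, numeric(1))
    expect_equal(unname(res$loo_mae[as.character(k)]), mean(err),
                 tolerance = 1e-12)
  }
  # n = 2, k = 1: LOO predictions are the swapped labels
  r2 <- tune_k_loo(matrix(c(0, 1), 2, 1), c(4, 8), 1, "uniform")
  expect_equal(unname(r2$loo_mae), mean(abs(c(4, 8) - c(8, 4))))
})

test_that("neighbor quantiles follow the linear-interpolation definition", {
  mk_pred <- function(labels) {
    structure(list(estimate = mean(labels), neighbor_ids = seq_along(labels),
                   neighbor_distances = seq_along(labels) * 0.1,
                   neighbor_labels = labels, quantiles = NULL),
              class = "neighbor_prediction")
  }
  q <- neighbor_quantiles(mk_pred(1:5), c(25, 75))
  expect_equal(unname(q), c(2, 4))
  expect_equal(unname(neighbor_quantiles(mk_pred(c(1, 2, 3)), 50)), 2)
  qc <- neighbor_quantiles(mk_pred(rep(7, 9)), c(10, 50, 90))
  expect_equal(unname(qc), c(7, 7, 7))
  expect_error(neighbor_quantiles(mk_pred(1:5), numeric(0)), "empty")
})

test_that("calibration curve counts items below each estimated percentile", {
  set.seed(57)
  qs <- rbind(c(1, 2, 3), c(0, 1, 2))
  colnames(qs) <- c("25", "50", "75")
  # y_true equal to each item's median (distinct labels):
  obs <- calibration_curve(qs, c(2, 1))
  expect_equal(unname(obs), c(0, 1, 1))
  expect_true(!is.unsorted(obs))
  expect_error(calibration_curve(qs, 1:3), "length")
})

test_that("neighbor quantiles are calibrated on a well-specified synthetic case", {
  set.seed(58)
  n_items <- 1200; k <- 31
  grid <- seq(10, 90, by = 10)
  qs <- matrix(NA_real_, n_items, length(grid))
  y_true <- numeric(n_items)
  for (i in seq_len(n_items)) {
    mu <- rnorm(1, sd = 3)
    labels <- rnorm(k, mean = mu)
    y_true[i] <- rnorm(1, mean = mu)
    pred <- structure(list(neighbor_labels = labels),
                      class = "neighbor_prediction")
    qs[i, ] <- neighbor_quantiles(pred, grid)
  }
  colnames(qs) <- as.character(grid)
  obs <- calibration_curve(qs, y_true)
  se <- sqrt(grid / 100 * (1 - grid / 100) / n_items)
  expect_true(all(abs(obs - grid / 100) <= 3 * se + 0.02))
  expect_true(!is.unsorted(obs))
})

test_that("reciprocal weighting beats uniform on a smooth 1-d function", {
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- 300
    x <- matrix(runif(n, 0, 3 * pi), n, 1)
    y <- sin(x[, 1]) + rnorm(n, sd = 0.05)
    tr <- 1:250; te <- 251:n
    idx <- build_index(x[tr, , drop = FALSE])
    pr <- vapply(te, function(i)
      knn_predict(idx, y[tr], x[i, ], 8, "reciprocal")$estimate, numeric(1))
    pu <- vapply(te, function(i)
      knn_predict(idx, y[tr], x[i, ], 8, "uniform")$estimate, numeric(1))
    if (mae(y[te], pr) <= mae(y[te], pu)) wins <- wins + 1
  }
  expect_gte(wins, 6)
})
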