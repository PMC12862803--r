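# Experimental harness: loss, delta-learning targets, cross-validated
# learning curves, the largest-cluster extrapolation split, and
# hyperparameter tuning.

#' Mean absolute error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `mean(|y_true - y_pred|)` in the label units (kcal/mol).
#' @export
mae <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  mean(abs(y_true - y_pred))
}

#' Delta-learning targets
#'
#' The residual between the two label levels, `y_high - y_low`. A model
#' trained on this residual predicts at test time as
#' `y_low(test) + model(residual)`.
#'
#' @param dataset A `mol_dataset` with both label levels.
#' @return Numeric residual vector.
#' @export
delta_targets <- function(dataset) {
  if (is.null(dataset$y_low)) {
    stop("delta-learning requires low-level labels (y_low)")
  }
  if (is.null(dataset$y_high)) stop("dataset has no high-level labels")
  dataset$y_high - dataset$y_low
}

#' Evaluation plan for cross-validated learning curves
#'
#' @param models Character vector of model specs, any of `"krr"`,
#'   `"knn_euclidean"`, `"knn_mlkr"`, `"knn_kernel_distance"`,
#'   `"kernel_regression_mlkr"`.
#' @param target_mode `"direct"` (predict `y_high`) or `"delta"` (predict
#'   the level residual, add back `y_low` at test time).
#' @param n_folds Number of CV folds (default 5); the test-fold size is
#'   fixed across all curve points.
#' @param train_sizes Training-set sizes; defaults to a geometric ladder
#'   `{125, 250, 500, ...}` capped at 80% of n.
#' @param folds Which folds to evaluate (default all); restricting to a
#'   subset trades statistical replication for runtime.
#' @param seed Master seed; folds, subsamples and metric fits derive named
#'   substreams from it.
#' @param k Neighbor count for the k-NN models (default 10, a robust first
#'   guess on the plateau).
#' @param weighting k-NN label weighting (default `"reciprocal"`).
#' @param sigma RBF width for KRR and the kernel-induced distance; `NULL`
#'   uses the median-pairwise-distance heuristic per fold.
#' @param lambda Ridge penalty for KRR.
#' @param rank_limit MLKR rank cap (truncated to the feature dimension).
#' @param mlkr_subsample_cap Subsample cap for the MLKR objective.
#' @param mlkr_max_iter MLKR optimizer iteration cap.
#' @return An object of class `evaluation_plan`.
#' @export
evaluation_plan <- function(models = "knn_euclidean",
                            target_mode = c("direct", "delta"),
                            n_folds = 5L, train_sizes = NULL, folds = NULL,
                            seed = 1L, k = 10L,
                            weighting = c("reciprocal", "uniform"),
                            sigma = NULL, lambda = 1e-4, rank_limit = 50L,
                            mlkr_subsample_cap = 25000L,
                            mlkr_max_iter = 200L) {
  target_mode <- match.arg(target_mode)
  weighting <- match.arg(weighting)
  known <- c("krr", "knn_euclidean", "knn_mlkr", "knn_kernel_distance",
             "kernel_regression_mlkr")
  bad <- setdiff(models, known)
  if (length(bad) > 0L) stop("unknown model spec(s): ",
                             paste(bad, collapse = ", "))
  structure(list(models = models, target_mode = target_mode,
                 n_folds = as.integer(n_folds), train_sizes = train_sizes,
                 folds = folds, seed = as.integer(seed), k = as.integer(k),
                 weighting = weighting, sigma = sigma, lambda = lambda,
                 rank_limit = as.integer(rank_limit),
                 mlkr_subsample_cap = as.integer(mlkr_subsample_cap),
                 mlkr_max_iter = as.integer(mlkr_max_iter)),
            class = "evaluation_plan")
}

default_train_sizes <- function(n_avail) {
  sizes <- 125 * 2^(0:20)
  sizes <- sizes[sizes <= n_avail]
  if (length(sizes) == 0L) sizes <- n_avail
  as.integer(sizes)
}

# fit the requested models on one train set and predict the test set;
# returns a list model -> list(pred, fit_s, predict_s)
fit_predict_models <- function(models, X_tr, y_tr, X_te, plan, fold_seed) {
  out <- list()
  sigma <- plan$sigma %||% median_pairwise_distance(X_tr, seed = fold_seed)
  need_mlkr <- any(models %in% c("knn_mlkr", "kernel_regression_mlkr"))
  mlkr <- NULL
  mlkr_s <- 0
  if (need_mlkr) {
    t0 <- proc.time()[["elapsed"]]
    mlkr <- mlkr_fit(X_tr, y_tr,
                     rank_limit = min(plan$rank_limit, ncol(X_tr)),
                     subsample_cap = plan$mlkr_subsample_cap,
                     seed = fold_seed, max_iter = plan$mlkr_max_iter)
    mlkr_s <- proc.time()[["elapsed"]] - t0
  }
  for (m in models) {
    t0 <- proc.time()[["elapsed"]]
    if (m == "krr") {
      spec <- kernel_spec("global_rbf", sigma = sigma)
      K <- kernel_matrix(X_tr, X_tr, spec)
      fit <- krr_fit(K, y_tr, plan$lambda)
      fit_s <- proc.time()[["elapsed"]] - t0
      t1 <- proc.time()[["elapsed"]]
      pred <- krr_predict(fit, kernel_matrix(X_te, X_tr, spec))
      pred_s <- proc.time()[["elapsed"]] - t1
    } else if (m == "knn_euclidean") {
      index <- build_index(X_tr, mode = "euclidean", backend = "brute")
      fit_s <- proc.time()[["elapsed"]] - t0
      t1 <- proc.time()[["elapsed"]]
      pred <- apply(X_te, 1, function(q) {
        knn_predict(index, y_tr, q, plan$k, plan$weighting)$estimate
      })
      pred_s <- proc.time()[["elapsed"]] - t1
    } else if (m == "knn_mlkr") {
      index <- build_index(X_tr, mode = "mahalanobis", backend = "brute",
                           metric = mlkr$metric)
      fit_s <- mlkr_s + proc.time()[["elapsed"]] - t0
      t1 <- proc.time()[["elapsed"]]
      pred <- apply(X_te, 1, function(q) {
        knn_predict(index, y_tr, q, plan$k, plan$weighting)$estimate
      })
      pred_s <- proc.time()[["elapsed"]] - t1
    } else if (m == "kernel_regression_mlkr") {
      fit_s <- mlkr_s + proc.time()[["elapsed"]] - t0
      t1 <- proc.time()[["elapsed"]]
      pred <- mlkr_kernel_regression_predict(mlkr$metric, X_tr, y_tr, X_te)
      pred_s <- proc.time()[["elapsed"]] - t1
    } else if (m == "knn_kernel_distance") {
      spec <- kernel_spec("global_rbf", sigma = sigma)
      K_tr <- kernel_matrix(X_tr, X_tr, spec)
      D_tr <- kernel_induced_distance(diag(K_tr), diag(K_tr), K_tr)
      index <- build_index(D_tr, mode = "kernel_induced", backend = "brute")
      fit_s <- proc.time()[["elapsed"]] - t0
      t1 <- proc.time()[["elapsed"]]
      K_te <- kernel_matrix(X_te, X_tr, spec)
      D_te <- kernel_induced_distance(rep(1, nrow(X_te)), diag(K_tr), K_te)
      pred <- apply(D_te, 1, function(dq) {
        knn_predict(index, y_tr, dq, plan$k, plan$weighting)$estimate
      })
      pred_s <- proc.time()[["elapsed"]] - t1
    }
    out[[m]] <- list(pred = as.numeric(pred), fit_s = fit_s,
                     predict_s = pred_s)
  }
  out
}

#' Cross-validated learning curves
#'
#' Splits the data into `n_folds` near-equal folds by a seeded permutation.
#' For each evaluated fold, the fold is the fixed-size test set and training
#' sets of each requested size are seeded subsamples of the remaining data.
#' In delta mode, models are trained on the level residual and predictions
#' are `y_low(test) + model(residual)`, scored against `y_high`.
#'
#' @param x n x p global feature matrix (rows aligned with the dataset).
#' @param dataset A labeled `mol_dataset` (needs `y_low` for delta mode).
#' @param plan An `evaluation_plan`.
#' @return A data frame of class `learning_curve_result` with columns
#'   `model`, `mode`, `train_size`, `fold`, `mae`, `fit_s`, `predict_s`.
#' @export
cross_validate <- function(x, dataset, plan) {
  stopifnot(inherits(plan, "evaluation_plan"))
  x <- as.matrix(x)
  n <- length(dataset)
  if (nrow(x) != n) stop("feature rows != dataset size")
  if (n < plan$n_folds) stop("need at least n_folds structures")
  y_high <- dataset$y_high
  if (is.null(y_high)) stop("dataset is unlabeled")
  delta <- plan$target_mode == "delta"
  y_fit <- if (delta) delta_targets(dataset) else y_high
  set.seed(derive_seed(plan$seed, "folds"))
  fold_id <- sample(rep(seq_len(plan$n_folds), length.out = n))
  n_avail <- n - max(table(fold_id))
  sizes <- plan$train_sizes %||% default_train_sizes(floor(0.8 * n))
  if (any(sizes > n_avail)) {
    stop("train_size ", max(sizes), " exceeds available training pool (",
         n_avail, ", i.e. data outside the test fold)")
  }
  eval_folds <- plan$folds %||% seq_len(plan$n_folds)
  rows <- list()
  for (f in eval_folds) {
    te <- which(fold_id == f)
    pool <- which(fold_id != f)
    for (sz in sizes) {
      set.seed(derive_seed(plan$seed, sprintf("subsample_f%d_s%d", f, sz)))
      tr <- sort(sample(pool, sz))
      res <- fit_predict_models(plan$models, x[tr, , drop = FALSE], y_fit[tr],
                                x[te, , drop = FALSE], plan,
                                fold_seed = derive_seed(plan$seed,
                                                        sprintf("fit_f%d_s%d", f, sz)))
      for (m in names(res)) {
        pred <- res[[m]]$pred
        if (delta) pred <- dataset$y_low[te] + pred
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, mode = plan$target_mode, train_size = sz, fold = f,
          mae = mae(y_high[te], pred),
          fit_s = res[[m]]$fit_s, predict_s = res[[m]]$predict_s,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("learning_curve_result", class(out))
  out
}

#' Hold out one cluster composition for extrapolation
#'
#' Test set: every structure whose composition equals `holdout_composition`
#' (typically the largest clusters); training set: all others. The
#' extrapolation analogue of a cross-validation split.
#'
#' @param dataset A `mol_dataset` with composition metadata.
#' @param holdout_composition Composition string or named count vector.
#' @return List with `train` and `test` (`mol_dataset`s).
#' @export
extrapolation_split <- function(dataset, holdout_composition) {
  if (is.character(holdout_composition)) {
    holdout_composition <- parse_composition(holdout_composition)
  }
  in_test <- vapply(dataset$structures, function(s) {
    !is.null(s$composition) && same_composition(s$composition,
                                                holdout_composition)
  }, logical(1))
  if (!any(in_test)) {
    stop("no structures with composition ",
         format_composition(holdout_composition), " in the dataset")
  }
  list(train = dataset[which(!in_test)], test = dataset[which(in_test)])
}

#' Grid search for the KRR width and ridge penalty
#'
#' Seeded split into up to 4000 training and 1000 validation items (capped
#' at a 4:1 ratio of the available data); evaluates every
#' `(sigma, lambda)` grid point and returns the pair minimizing validation
#' MAE. Ties are resolved toward the larger lambda, then the larger sigma
#' (the more regularized model).
#'
#' @param x Global feature matrix.
#' @param y Labels.
#' @param sigma_grid,lambda_grid Nonempty numeric grids.
#' @param seed Split seed.
#' @return List with `sigma`, `lambda`, and the full `mae` grid (data
#'   frame).
#' @export
tune_krr_hyperparams <- function(x, y, sigma_grid, lambda_grid, seed = 1L) {
  if (length(sigma_grid) == 0L || length(lambda_grid) == 0L) {
    stop("grids must be nonempty")
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 items to tune")
  n_tr <- min(4000L, as.integer(floor(n * 0.8)))
  n_va <- min(1000L, n - n_tr, as.integer(ceiling(n_tr / 4)))
  set.seed(derive_seed(seed, "krr_tune"))
  perm <- sample.int(n)
  tr <- perm[seq_len(n_tr)]
  va <- perm[(n_tr + 1L):(n_tr + n_va)]
  grid <- expand.grid(sigma = sort(sigma_grid), lambda = sort(lambda_grid))
  grid$mae <- NA_real_
  D2_tr <- cross_dist2(x[tr, , drop = FALSE], x[tr, , drop = FALSE])
  D2_va <- cross_dist2(x[va, , drop = FALSE], x[tr, , drop = FALSE])
  for (s in unique(grid$sigma)) {
    K <- rbf_from_dist2(D2_tr, s)
    K_va <- rbf_from_dist2(D2_va, s)
    for (l in unique(grid$lambda)) {
      # numerically infeasible corners of the grid (singular solves at tiny
      # lambda) are scored Inf rather than aborting the search
      m <- tryCatch(
        mae(y[va], krr_predict(krr_fit(K, y[tr], l), K_va)),
        error = function(e) Inf
      )
      grid$mae[grid$sigma == s & grid$lambda == l] <- m
    }
  }
  best <- which(grid$mae == min(grid$mae))
  best <- best[order(-grid$lambda[best], -grid$sigma[best])][1]
  list(sigma = grid$sigma[best], lambda = grid$lambda[best], mae = grid)
}

#' Cross-validated grid search for the k-NN neighbor count
#'
#' Subsamples at most 5000 items, then runs 5-fold CV over the k grid and
#' returns the k minimizing mean validation MAE (ties go to the smaller k).
#'
#' @param x Global feature matrix.
#' @param y Labels.
#' @param k_grid Integer candidate grid (default 1-30).
#' @param weighting k-NN weighting.
#' @param metric Optional `mahalanobis_metric`: distances are then taken in
#'   the learned metric space.
#' @param seed Seed for subsample and folds.
#' @param subsample_cap Items entering the search (default 5000).
#' @return List with `best_k` and the per-k CV `mae`.
#' @export
tune_knn_k <- function(x, y, k_grid = 1:30,
                       weighting = c("reciprocal", "uniform"),
                       metric = NULL, seed = 1L, subsample_cap = 5000L) {
  weighting <- match.arg(weighting)
  if (length(k_grid) == 0L) stop("k_grid is empty")
  x <- as.matrix(x)
  if (!is.null(metric)) x <- metric_transform(metric, x)
  n <- nrow(x)
  set.seed(derive_seed(seed, "knn_tune_subsample"))
  if (n > subsample_cap) {
    keep <- sort(sample.int(n, subsample_cap))
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
    n <- subsample_cap
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  set.seed(derive_seed(seed, "knn_tune_folds"))
  fold_id <- sample(rep(seq_len(5L), length.out = n))
  errs <- matrix(NA_real_, 5L, length(k_grid))
  for (f in seq_len(5L)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    if (max(k_grid) > length(tr)) stop("max(k_grid) exceeds fold train size")
    D <- sqrt(cross_dist2(x[te, , drop = FALSE], x[tr, , drop = FALSE]))
    kmax <- max(k_grid)
    abs_err <- matrix(0, length(te), length(k_grid))
    for (ii in seq_along(te)) {
      ord <- order(D[ii, ], seq_along(tr))[seq_len(kmax)]
      dn <- D[ii, ord]
      yn <- y[tr][ord]
      pred <- vapply(k_grid, function(k) {
        knn_estimate(dn[seq_len(k)], yn[seq_len(k)], weighting)
      }, numeric(1))
      abs_err[ii, ] <- abs(y[te][ii] - pred)
    }
    errs[f, ] <- colMeans(abs_err)
  }
  cv_mae <- colMeans(errs)
  names(cv_mae) <- k_grid
  list(best_k = k_grid[which.min(cv_mae)], mae = cv_mae)
}

#' Plot learning curves on log-log axes
#'
#' @param x A `learning_curve_result` from [cross_validate()].
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of mean MAE per (train_size, model).
#' @export
plot.learning_curve_result <- function(x, ...) {
  agg <- stats::aggregate(mae ~ model + train_size, data = x, FUN = mean)
  wide <- stats::reshape(agg, idvar = "train_size", timevar = "model",
                         direction = "wide")
  wide <- wide[order(wide$train_size), , drop = FALSE]
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^mae\\.", "", colnames(m))
  graphics::matplot(wide$train_size, m, type = "b", log = "xy", pch = 19,
                    lty = 1, xlab = "training set size",
                    ylab = "test MAE (kcal/mol)", ...)
  graphics::legend("bottomleft", legend = colnames(m), col = seq_len(ncol(m)),
                   pch = 19, lty = 1, bty = "n")
  invisible(m)
}
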