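# Nearest-neighbor search and weighted k-NN regression.
#
# Two backends: brute force and a KD-tree written in plain R (exactly
# equivalent results, including the ascending-index tie-break, by
# construction of the pruning rule). Distance modes: euclidean coordinates,
# mahalanobis (points projected through a learned metric, then euclidean),
# and kernel_induced (precomputed dense distances; no coordinates exist, so
# only the brute backend applies).

# ---------------------------------------------------------------------------
# KD-tree

kd_build <- function(X, idx = seq_len(nrow(X)), leaf_size = 16L) {
  if (length(idx) <= leaf_size) {
    return(list(leaf = TRUE, idx = idx))
  }
  ranges <- apply(X[idx, , drop = FALSE], 2, function(c) diff(range(c)))
  dim <- which.max(ranges)
  vals <- X[idx, dim]
  cut <- stats::median(vals)
  left <- idx[vals <= cut]
  right <- idx[vals > cut]
  if (length(left) == 0L || length(right) == 0L) {
    # degenerate split (ties at the median): fall back to an even split
    ord <- idx[order(vals, idx)]
    half <- length(ord) %/% 2L
    left <- ord[seq_len(half)]
    right <- ord[(half + 1L):length(ord)]
    cut <- max(X[left, dim])
  }
  list(leaf = FALSE, dim = dim, cut = cut,
       left = kd_build(X, left, leaf_size),
       right = kd_build(X, right, leaf_size))
}

# collect all points with distance <= current k-th best bound (ties kept)
kd_query <- function(node, X, q, k, state) {
  if (node$leaf) {
    for (i in node$idx) {
      d2 <- sum((X[i, ] - q)^2)
      if (d2 <= state$bound) {
        state$idx <- c(state$idx, i)
        state$d2 <- c(state$d2, d2)
        if (length(state$idx) >= k) {
          srt <- sort(state$d2, partial = k)[k]
          state$bound <- srt
        }
      }
    }
    return(state)
  }
  delta <- q[node$dim] - node$cut
  first <- if (delta <= 0) node$left else node$right
  second <- if (delta <= 0) node$right else node$left
  state <- kd_query(first, X, q, k, state)
  if (delta^2 <= state$bound) {
    state <- kd_query(second, X, q, k, state)
  }
  state
}

# ---------------------------------------------------------------------------

#' Build a nearest-neighbor index
#'
#' @param x For `mode = "euclidean"`: an n x d coordinate matrix. For
#'   `mode = "mahalanobis"`: an n x d matrix in original feature coordinates
#'   together with `metric`; points are projected through the metric and
#'   searched in Euclidean space. For `mode = "kernel_induced"`: a
#'   precomputed n x n train-train distance matrix from
#'   [kernel_induced_distance()] (queries then supply distance vectors).
#' @param mode Distance mode.
#' @param backend `"brute"` or `"tree"`. The tree backend requires true
#'   metric coordinates and is rejected for `kernel_induced`.
#' @param metric A `mahalanobis_metric`, required for mahalanobis mode.
#' @return An object of class `neighbor_index`.
#' @export
build_index <- function(x, mode = c("euclidean", "mahalanobis", "kernel_induced"),
                        backend = c("brute", "tree"), metric = NULL) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  if (mode == "kernel_induced") {
    if (backend == "tree") {
      stop("tree backend requires explicit coordinates; kernel_induced ",
           "distances have none -- use backend = 'brute'")
    }
    x <- as.matrix(x)
    if (nrow(x) != ncol(x)) stop("kernel_induced mode expects a square ",
                                 "train-train distance matrix")
    return(structure(list(mode = mode, backend = backend, D = x, n = nrow(x)),
                     class = "neighbor_index"))
  }
  pts <- as.matrix(x)
  if (mode == "mahalanobis") {
    if (!inherits(metric, "mahalanobis_metric")) {
      stop("mahalanobis mode requires a mahalanobis_metric")
    }
    pts <- metric_transform(metric, pts)
  }
  tree <- if (backend == "tree") kd_build(pts) else NULL
  structure(list(mode = mode, backend = backend, points = pts,
                 n = nrow(pts), tree = tree, metric = metric),
            class = "neighbor_index")
}

#' @export
print.neighbor_index <- function(x, ...) {
  cat("<neighbor_index>", x$n, "points,", x$mode, "distance,",
      x$backend, "backend\n")
  invisible(x)
}

#' Query the k nearest neighbors of one point
#'
#' Ties at equal distance are broken by ascending stored index, so results
#' are deterministic and identical across backends.
#'
#' @param index A `neighbor_index`.
#' @param x Query: a coordinate vector (euclidean), an original-feature
#'   vector (mahalanobis; it is projected through the index's metric), or a
#'   length-n vector of precomputed distances to the stored points
#'   (kernel_induced).
#' @param k Number of neighbors, `1 <= k <= n`.
#' @return List with `idx` (stored indices) and `dist`, both length k,
#'   sorted by ascending distance.
#' @export
query_neighbors <- function(index, x, k) {
  if (k < 1L || k > index$n) stop("k must be between 1 and ", index$n)
  if (index$mode == "kernel_induced") {
    d <- as.numeric(x)
    if (length(d) != index$n) stop("query must be a length-", index$n,
                                   " distance vector")
    ord <- order(d, seq_along(d))[seq_len(k)]
    return(list(idx = ord, dist = d[ord]))
  }
  q <- as.numeric(x)
  if (index$mode == "mahalanobis") {
    q <- as.numeric(metric_transform(index$metric, matrix(q, nrow = 1)))
  }
  if (length(q) != ncol(index$points)) stop("query dimension mismatch")
  if (index$backend == "brute") {
    d2 <- rowSums(sweep(index$points, 2, q, "-")^2)
  } else {
    state <- new.env()
    state$idx <- integer(0)
    state$d2 <- numeric(0)
    state$bound <- Inf
    state <- kd_query(index$tree, index$points, q, k, state)
    d2 <- rep(Inf, index$n)
    d2[state$idx] <- state$d2
  }
  ord <- order(d2, seq_along(d2))[seq_len(k)]
  list(idx = ord, dist = sqrt(d2[ord]))
}

#' Weighted k-nearest-neighbor prediction
#'
#' Uniform weighting averages the neighbor labels; reciprocal weighting uses
#' `w_i = d_i^-1 / sum_l d_l^-1`. If any neighbor distance is exactly zero,
#' the prediction is the mean label of the zero-distance neighbors (the
#' limit of reciprocal weighting).
#'
#' @param index A `neighbor_index`.
#' @param y Training labels (length n, in stored-point order).
#' @param x Query (see [query_neighbors()]).
#' @param k Number of neighbors.
#' @param weighting `"uniform"` or `"reciprocal"`.
#' @param percentiles Optional numeric percentiles (0-100) at which to
#'   attach neighbor-label quantiles to the prediction.
#' @return An object of class `neighbor_prediction`: `estimate`,
#'   `neighbor_ids`, `neighbor_distances`, `neighbor_labels`, `quantiles`.
#' @export
knn_predict <- function(index, y, x, k,
                        weighting = c("uniform", "reciprocal"),
                        percentiles = NULL) {
  weighting <- match.arg(weighting)
  if (length(y) != index$n) stop("length(y) != number of stored points")
  nb <- query_neighbors(index, x, k)
  labels <- y[nb$idx]
  est <- knn_estimate(nb$dist, labels, weighting)
  pred <- structure(
    list(estimate = est, neighbor_ids = nb$idx,
         neighbor_distances = nb$dist, neighbor_labels = labels,
         quantiles = NULL),
    class = "neighbor_prediction"
  )
  if (!is.null(percentiles)) {
    pred$quantiles <- neighbor_quantiles(pred, percentiles)
  }
  pred
}

knn_estimate <- function(dist, labels, weighting) {
  if (weighting == "uniform") return(mean(labels))
  zero <- dist == 0
  if (any(zero)) return(mean(labels[zero]))
  w <- 1 / dist
  sum(w * labels) / sum(w)
}

#' @export
print.neighbor_prediction <- function(x, ...) {
  cat("<neighbor_prediction>", format(x$estimate), "from",
      length(x$neighbor_ids), "neighbors (label range",
      format(min(x$neighbor_labels)), "..",
      format(max(x$neighbor_labels)), ")\n")
  invisible(x)
}

#' Kernel regression prediction under a learned metric
#'
#' Softmax-of-distance weighted average over all training points:
#' `w_j = k(d_M(x, x_j)) / sum_l k(d_M(x, x_l))` with the MLKR RBF kernel.
#' Distances are stabilized by subtracting the minimum squared distance
#' before exponentiation; if every weight still underflows the nearest
#' neighbor's label is returned.
#'
#' @param metric A `mahalanobis_metric`.
#' @param X_train n x d training features (original coordinates).
#' @param y Training labels.
#' @param x Query vector, or an m x d matrix of queries.
#' @param sigma RBF width (defaults to the metric's sigma).
#' @return Numeric prediction(s).
#' @export
mlkr_kernel_regression_predict <- function(metric, X_train, y, x,
                                           sigma = metric$sigma) {
  Xq <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
  D2 <- mahalanobis_distance(metric, Xq, X_train)^2
  m <- apply(D2, 1, min)
  K <- exp(-(D2 - m) / sigma^2)
  K[!is.finite(K)] <- 0
  S <- rowSums(K)
  out <- numeric(nrow(Xq))
  deg <- S <= 0
  if (any(deg)) {
    for (i in which(deg)) out[i] <- y[which.min(D2[i, ])]
  }
  out[!deg] <- ((K %*% y) / S)[!deg]
  out
}

#' Tune k by leave-one-out cross-validation in one distance-matrix pass
#'
#' For uniform weights, the LOO prediction at `k` is recovered from the
#' self-including `(k+1)`-neighbor mean `f_{k+1}` by
#' `f_LOO(x_i) = ((k + 1) f_{k+1}(x_i) - y_i) / k`, so the entire k-grid is
#' scored from one sorted distance matrix. For reciprocal weights the self
#' point is dropped (its zero distance would degenerate the weights) and the
#' next k neighbors are used directly.
#'
#' @param x n x d coordinate matrix, or an n x n distance matrix (used as-is
#'   when square and symmetric), or a `neighbor_index` in a coordinate mode.
#' @param y Labels.
#' @param k_grid Integer vector of candidate k; all `< n`.
#' @param weighting `"uniform"` or `"reciprocal"`.
#' @return List with `best_k` (ties go to the smaller k) and `loo_mae`
#'   (named numeric, one entry per k in the grid).
#' @export
tune_k_loo <- function(x, y, k_grid, weighting = c("uniform", "reciprocal")) {
  weighting <- match.arg(weighting)
  if (length(k_grid) == 0L) stop("k_grid is empty")
  k_grid <- sort(unique(as.integer(k_grid)))
  D <- loo_distance_matrix(x)
  n <- nrow(D)
  if (length(y) != n) stop("length(y) != point count")
  if (max(k_grid) >= n) stop("max(k_grid) must be < n")
  kmax <- max(k_grid)
  abs_err <- matrix(0, n, length(k_grid))
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- -Inf                       # self always first in the ranking
    ord <- order(d, seq_len(n))[seq_len(kmax + 1L)]
    ys <- y[ord]
    if (weighting == "uniform") {
      cs <- cumsum(ys)
      # ((k+1) * mean of first k+1 - y_i) / k = mean of neighbors 2..k+1
      pred <- (cs[k_grid + 1L] - y[i]) / k_grid
    } else {
      dn <- D[i, ord[-1L]]             # true distances to the k nearest others
      yn <- ys[-1L]
      pred <- vapply(k_grid, function(k) {
        knn_estimate(dn[seq_len(k)], yn[seq_len(k)], "reciprocal")
      }, numeric(1))
    }
    abs_err[i, ] <- abs(y[i] - pred)
  }
  loo_mae <- colMeans(abs_err)
  names(loo_mae) <- k_grid
  list(best_k = k_grid[which.min(loo_mae)], loo_mae = loo_mae)
}

loo_distance_matrix <- function(x) {
  if (inherits(x, "neighbor_index")) {
    if (x$mode == "kernel_induced") return(x$D)
    return(sqrt(cross_dist2(x$points, x$points)))
  }
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && isSymmetric(unname(x), tol = 1e-12) &&
      all(abs(diag(x)) < 1e-12) && all(x >= 0)) {
    return(x)
  }
  sqrt(cross_dist2(x, x))
}

#' Empirical quantiles of the neighbor labels
#'
#' Unweighted quantiles of the k neighbor labels, used as a per-item
#' uncertainty estimate. The default `"interpolated"` definition is the
#' standard mode-based linear interpolation (labels `{1,...,5}` give 2.0 at
#' the 25th and 4.0 at the 75th percentile). For calibration studies the
#' `"coverage_unbiased"` definition interpolates on the `p(k+1)` rule, whose
#' expected coverage `P(y <= q_p)` equals `p` for a sample of size k --
#' the interpolated definition's coverage is `((k-1)p + 1)/(k+1)`, which at
#' small k visibly over-covers low percentiles and under-covers high ones.
#'
#' @param prediction A `neighbor_prediction`.
#' @param percentiles Numeric vector of percentiles in `[0, 100]`.
#' @param definition `"interpolated"` (quantile type 7, default) or
#'   `"coverage_unbiased"` (type 6).
#' @return Named numeric vector, one value per percentile.
#' @export
neighbor_quantiles <- function(prediction, percentiles,
                               definition = c("interpolated",
                                              "coverage_unbiased")) {
  definition <- match.arg(definition)
  if (length(percentiles) == 0L) stop("percentile list is empty")
  if (any(percentiles < 0 | percentiles > 100)) {
    stop("percentiles must lie in [0, 100]")
  }
  q <- stats::quantile(prediction$neighbor_labels, probs = percentiles / 100,
                       type = if (definition == "interpolated") 7 else 6,
                       names = FALSE)
  names(q) <- as.character(percentiles)
  q
}

#' Observed-vs-nominal quantile calibration curve
#'
#' For each percentile p in the grid, the fraction of test items whose true
#' label falls at or below that item's estimated p-th percentile. A
#' well-calibrated uncertainty model tracks the diagonal.
#'
#' @param quantile_sets Matrix (items x percentiles) of estimated quantile
#'   values, columns named by percentile as produced by
#'   [neighbor_quantiles()], or a list of such named vectors.
#' @param y_true True labels, one per item.
#' @param percent_grid Percentiles to evaluate (default: the columns
#'   present).
#' @return Named numeric vector: observed fraction per percentile.
#' @export
calibration_curve <- function(quantile_sets, y_true, percent_grid = NULL) {
  if (is.list(quantile_sets) && !is.matrix(quantile_sets)) {
    quantile_sets <- do.call(rbind, quantile_sets)
  }
  quantile_sets <- as.matrix(quantile_sets)
  if (nrow(quantile_sets) != length(y_true)) {
    stop("quantile_sets rows (", nrow(quantile_sets),
         ") != length(y_true) (", length(y_true), ")")
  }
  if (is.null(percent_grid)) {
    percent_grid <- as.numeric(colnames(quantile_sets))
  }
  cols <- match(as.character(percent_grid), colnames(quantile_sets))
  if (anyNA(cols)) stop("percent_grid values missing from quantile_sets")
  obs <- vapply(cols, function(j) mean(y_true <= quantile_sets[, j]),
                numeric(1))
  names(obs) <- as.character(percent_grid)
  obs
}
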