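# Kernel evaluation: global RBF on fixed-length vectors, extensive
# sum-of-atomic-kernels on per-atom representations, the kernel-induced
# distance, and kernel normalization.

#' Kernel specification
#'
#' @param kind `"global_rbf"` (RBF between global vectors) or
#'   `"extensive_atomic"` (sum of pairwise atomic RBF kernels; for extensive
#'   properties such as binding energies).
#' @param sigma RBF width, > 0.
#' @param element_matched For the extensive kernel, restrict atomic pairs to
#'   identical elements (default TRUE, the standard practice for
#'   atomic-decomposition kernels).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("global_rbf", "extensive_atomic"),
                        sigma, element_matched = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive number")
  }
  structure(list(kind = kind, sigma = sigma,
                 element_matched = isTRUE(element_matched)),
            class = "kernel_spec")
}

rbf_from_dist2 <- function(d2, sigma) exp(-d2 / (2 * sigma^2))

#' Kernel matrix between two sets of representations
#'
#' For `global_rbf`, `A` and `B` are numeric matrices of global vectors and
#' `K_ij = exp(-||a_i - b_j||^2 / (2 sigma^2))`. For `extensive_atomic`,
#' `A` and `B` are lists of `local_representation` and
#' `K_ij = sum_{alpha in i} sum_{beta in j} [Z_alpha = Z_beta]
#' exp(-||q_alpha - q_beta||^2 / (2 sigma^2))` (the element indicator is
#' dropped when `spec$element_matched` is FALSE). Evaluation is blocked to
#' bound memory; results do not depend on the block size.
#'
#' @param A,B Representations (matrix or list of `local_representation`);
#'   `B = A` gives the symmetric Gram matrix.
#' @param spec A `kernel_spec`.
#' @param block_size Rows per evaluation block.
#' @return Numeric `nrow(A)` x `nrow(B)` kernel matrix.
#' @export
kernel_matrix <- function(A, B = A, spec, block_size = 512L) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$kind == "global_rbf") {
    A <- as.matrix(A); B <- as.matrix(B)
    if (ncol(A) != ncol(B)) {
      stop("representation schemas disagree: ", ncol(A), " vs ", ncol(B),
           " features")
    }
    K <- matrix(0, nrow(A), nrow(B))
    starts <- seq(1L, nrow(A), by = block_size)
    for (s in starts) {
      e <- min(s + block_size - 1L, nrow(A))
      K[s:e, ] <- rbf_from_dist2(cross_dist2(A[s:e, , drop = FALSE], B),
                                 spec$sigma)
    }
    K
  } else {
    extensive_kernel_matrix(A, B, spec)
  }
}

# stack per-atom rows, remember owning structure
stack_locals <- function(L) {
  p <- ncol(L[[1]]$per_atom)
  for (l in L) {
    if (ncol(l$per_atom) != p) stop("local representation schemas disagree")
  }
  X <- do.call(rbind, lapply(L, `[[`, "per_atom"))
  owner <- rep(seq_along(L), vapply(L, function(l) nrow(l$per_atom), integer(1)))
  el <- unlist(lapply(L, `[[`, "elements"))
  list(X = X, owner = owner, el = el)
}

extensive_kernel_matrix <- function(A, B, spec) {
  sa <- stack_locals(A)
  sb <- stack_locals(B)
  K <- matrix(0, length(A), length(B))
  groups <- if (spec$element_matched) {
    intersect(unique(sa$el), unique(sb$el))
  } else "all"
  for (g in groups) {
    ia <- if (identical(g, "all")) seq_along(sa$el) else which(sa$el == g)
    ib <- if (identical(g, "all")) seq_along(sb$el) else which(sb$el == g)
    ka <- rbf_from_dist2(cross_dist2(sa$X[ia, , drop = FALSE],
                                     sb$X[ib, , drop = FALSE]), spec$sigma)
    # aggregate atomic kernel into structure blocks
    oa <- sa$owner[ia]; ob <- sb$owner[ib]
    agg <- rowsum(t(rowsum(ka, oa)), ob)  # (structures B) x (structures A)
    rows_a <- as.integer(colnames(agg))
    rows_b <- as.integer(rownames(agg))
    K[rows_a, rows_b] <- K[rows_a, rows_b] + t(agg)
  }
  K
}

#' Kernel-induced distance matrix
#'
#' The feature-space Euclidean distance implied by a positive-definite
#' kernel: `d(x, x')^2 = k(x, x) + k(x', x') - 2 k(x, x')`. Tiny negative
#' arguments under the root (relative magnitude below 1e-9) are clamped to
#' zero; larger negativity signals a non-positive-definite kernel and raises
#' an error.
#'
#' @param K_aa_diag Self-similarities `k(a_i, a_i)` of the first set.
#' @param K_bb_diag Self-similarities of the second set.
#' @param K_ab Cross kernel matrix between the sets.
#' @return Matrix of distances, `length(K_aa_diag)` x `length(K_bb_diag)`.
#' @export
kernel_induced_distance <- function(K_aa_diag, K_bb_diag, K_ab) {
  K_ab <- as.matrix(K_ab)
  if (nrow(K_ab) != length(K_aa_diag) || ncol(K_ab) != length(K_bb_diag)) {
    stop("K_ab dimensions do not match the diagonal vectors")
  }
  arg <- outer(K_aa_diag, K_bb_diag, "+") - 2 * K_ab
  scale <- pmax(outer(K_aa_diag, K_bb_diag, "+"), 1)
  bad <- arg < -1e-9 * scale
  if (any(bad)) {
    stop("kernel-induced distance argument strongly negative (min relative ",
         format(min(arg / scale)), "); kernel is not positive definite")
  }
  arg[arg < 0] <- 0
  sqrt(arg)
}

#' Normalize a kernel matrix to unit diagonal
#'
#' `K_ij / sqrt(K_ii K_jj)`; discards the extensiveness of a
#' sum-of-atomic-kernels Gram matrix in exchange for unit self-similarity.
#'
#' @param K Square kernel matrix with a strictly positive diagonal.
#' @return Normalized kernel matrix with unit diagonal.
#' @export
normalize_kernel <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  d <- diag(K)
  if (any(d <= 0)) stop("kernel diagonal must be strictly positive")
  K / sqrt(outer(d, d))
}

#' Median pairwise distance heuristic for the RBF width
#'
#' @param X Numeric matrix of global representations.
#' @param max_points Random subsample cap for the median computation.
#' @param seed Seed for the subsample.
#' @return Median Euclidean pairwise distance.
#' @export
median_pairwise_distance <- function(X, max_points = 500L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) > max_points) {
    set.seed(seed)
    X <- X[sample.int(nrow(X), max_points), , drop = FALSE]
  }
  d2 <- cross_dist2(X, X)
  stats::median(sqrt(d2[upper.tri(d2)]))
}
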