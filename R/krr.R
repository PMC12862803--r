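# Kernel ridge regression: closed-form solve and prediction.

#' Fit a kernel ridge regression model
#'
#' Solves `(K + lambda I) alpha = y` via a Cholesky factorization of the
#' symmetric system. If the factorization fails (e.g. `lambda = 0` with a
#' singular Gram matrix), one retry adds a jitter of
#' `1e-10 * trace(K) / n` to the diagonal; if that also fails, an error
#' advises a positive `lambda`.
#'
#' @param K Symmetric n x n training kernel matrix.
#' @param y Numeric label vector of length n.
#' @param lambda Ridge penalty, >= 0.
#' @return An object of class `krr_model` with fields `alpha` and `lambda`.
#' @export
krr_fit <- function(K, y, lambda) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("K must be square")
  if (length(y) != n) stop("length(y) != nrow(K)")
  if (lambda < 0) stop("lambda must be non-negative")
  M <- K + diag(lambda, n)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    jitter <- 1e-10 * sum(diag(K)) / n
    R <- tryCatch(chol(M + diag(jitter, n)), error = function(e) {
      stop("kernel system factorization failed; K + lambda*I is not ",
           "positive definite -- use lambda > 0")
    })
  }
  alpha <- backsolve(R, forwardsolve(t(R), y))
  resid <- sqrt(sum((M %*% alpha - y)^2))
  if (resid > 1e-8 * max(sqrt(sum(y^2)), 1)) {
    stop("KRR solve residual ", format(resid), " exceeds tolerance; ",
         "the kernel system is numerically singular -- use lambda > 0")
  }
  structure(list(alpha = as.numeric(alpha), lambda = lambda),
            class = "krr_model")
}

#' Predict from a kernel ridge regression model
#'
#' @param model A `krr_model`.
#' @param K_test m x n kernel matrix between test and training
#'   representations (columns in training order).
#' @return Numeric vector of m predictions `f_i = sum_j alpha_j K_test[i, j]`.
#' @export
krr_predict <- function(model, K_test) {
  n <- length(model$alpha)
  if (!is.matrix(K_test)) {
    if (length(K_test) != n) {
      stop("kernel row length ", length(K_test), " != training size ", n)
    }
    K_test <- matrix(as.numeric(K_test), 1L, n)
  }
  if (ncol(K_test) != n) {
    stop("K_test has ", ncol(K_test), " columns but the model was trained ",
         "on ", n, " points")
  }
  as.numeric(K_test %*% model$alpha)
}
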