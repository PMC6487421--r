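#' Gaussian radial basis function kernel
#'
#' `K(t1, t2) = exp(-||t1 - t2||^2 / (2 sigma2))`, the "Gaussian"
#' parameterisation with the squared bandwidth in the denominator's
#' `2 sigma2`. `K(t, t) = 1` always.
#'
#' @param t1,t2 numeric score vectors of equal length.
#' @param sigma2 squared bandwidth, > 0 (score-space units squared).
#' @return scalar in (0, 1].
#' @export
rbf_kernel <- function(t1, t2, sigma2) {
  if (sigma2 <= 0) stop("rbf_kernel: sigma2 must be > 0")
  exp(-sum((t1 - t2)^2) / (2 * sigma2))
}

# full kernel matrix between row sets (vectorised)
rbf_kernel_matrix <- function(T1, T2, sigma2) {
  if (sigma2 <= 0) stop("rbf_kernel_matrix: sigma2 must be > 0")
  T1 <- as.matrix(T1); T2 <- as.matrix(T2)
  d2 <- outer(rowSums(T1^2), rowSums(T2^2), "+") - 2 * tcrossprod(T1, T2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma2))
}

#' Fit a least-squares support vector machine regressor
#'
#' Solves the LS-SVM dual in one linear system
#' `[[0, 1'], [1, Omega + I/gamma]] [b; alpha] = [0; y]` with
#' `Omega_ij = K(t_i, t_j)`. The equality-constrained reformulation replaces
#' the QP of the original SVM; the solution satisfies the KKT identities
#' `sum(alpha) = 0` and `alpha_i = gamma * (y_i - yhat(t_i))`.
#'
#' @param T n x A matrix of (PLS) scores.
#' @param y numeric response, length n.
#' @param gamma regularisation, > 0 (larger = less regularised).
#' @param sigma2 squared RBF bandwidth, > 0.
#' @return an object of class `lssvm_model`: `support_scores`, `alpha`, `b`,
#'   `gamma`, `sigma2`.
#' @export
lssvm_fit <- function(T, y, gamma, sigma2) {
  T <- as.matrix(T)
  y <- as.numeric(y)
  n <- nrow(T)
  if (length(y) != n) stop("lssvm_fit: T and y dimension mismatch")
  if (n < 2L) stop("lssvm_fit: need n >= 2")
  if (gamma <= 0) stop("lssvm_fit: gamma must be > 0")
  if (!all(is.finite(T)) || !all(is.finite(y)))
    stop("lssvm_fit: non-finite inputs")
  Omega <- rbf_kernel_matrix(T, T, sigma2)
  M <- rbind(c(0, rep(1, n)),
             cbind(1, Omega + diag(1 / gamma, n)))
  kap <- kappa(M, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12)
    stop("lssvm_fit: dual system is ill-conditioned (condition ~ ",
         format(kap, digits = 3),
         "); consider a smaller gamma (stronger ridge 1/gamma)")
  sol <- solve(M, c(0, y))
  structure(list(support_scores = T, alpha = sol[-1L], b = sol[1L],
                 gamma = gamma, sigma2 = sigma2),
            class = "lssvm_model")
}

#' Predict with a fitted LS-SVM
#'
#' `yhat(t) = sum_i alpha_i K(t, t_i) + b`.
#'
#' @param object an `lssvm_model`.
#' @param T matrix of new score rows (or a single score vector).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.lssvm_model <- function(object, T, ...) {
  T <- if (is.null(dim(T))) matrix(T, nrow = 1L) else as.matrix(T)
  if (ncol(T) != ncol(object$support_scores))
    stop("predict.lssvm_model: score dimension mismatch")
  K <- rbf_kernel_matrix(T, object$support_scores, object$sigma2)
  drop(K %*% object$alpha) + object$b
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf("lssvm_model: %d support samples, gamma = %.4g, sigma2 = %.4g\n",
              length(x$alpha), x$gamma, x$sigma2))
  invisible(x)
}
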