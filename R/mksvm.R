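#' Linear kernel matrix
#'
#' `k(x, x') = x' y` entrywise between the rows of `A` and the rows of `B`.
#'
#' @param A,B Numeric matrices with the same number of columns (`B`
#'   defaults to `A`).
#' @return `nrow(A) x nrow(B)` kernel matrix.
#' @export
linear_kernel <- function(A, B = A) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    abort("feature dimension mismatch", class = "jsseconn_svm_error")
  }
  tcrossprod(A, B)
}

#' Grid of kernel weights on the 3-simplex
#'
#' All `(beta1, beta2, beta3)` with non-negative entries summing to 1 on a
#' lattice of the given step: 66 points at step 0.1, 15 at step 0.25.
#'
#' @param step Lattice step (must divide 1).
#' @return Matrix with 3 columns, one row per weight vector.
#' @export
beta_simplex_grid <- function(step = 0.1) {
  k <- round(1 / step)
  stopifnot(abs(k * step - 1) < 1e-9)
  g <- expand.grid(b1 = 0:k, b2 = 0:k)
  g <- g[g$b1 + g$b2 <= k, ]
  g <- g[order(g$b1, g$b2), ]
  m <- cbind(beta1 = g$b1, beta2 = g$b2, beta3 = k - g$b1 - g$b2) / k
  unname(m)
}

#' Train a multi-kernel SVM on precomputed kernels
#'
#' Solves the C-SVC dual on the convex kernel combination
#' `K = sum_m beta_m K_m`:
#' `max_a sum_i a_i - 0.5 sum_ij a_i a_j y_i y_j K(i, j)` subject to
#' `sum_i a_i y_i = 0`, `0 <= a_i <= C`, using a maximal-violating-pair SMO
#' (compiled; tolerance 1e-9 on the KKT gap). The bias `b` is recovered
#' from the KKT conditions on free support vectors. With `betas` at a
#' vertex of the simplex the fit coincides exactly with a single-kernel SVM
#' on that kernel.
#'
#' @param kernels List of `M` symmetric PSD kernel matrices over the same
#'   training samples.
#' @param y Labels in `{+1, -1}` (numeric) or a factor/character vector
#'   with two levels.
#' @param betas Kernel weights: non-negative, summing to 1, length `M`.
#' @param C Box constraint (> 0).
#' @return An `mksvm` model: list with `alpha`, `b`, `betas`, `C`, `y`,
#'   `support` (indices with `alpha > 0`) and `iterations`.
#' @export
mksvm_train <- function(kernels, y, betas, C) {
  if (!is.list(kernels)) kernels <- list(kernels)
  y <- as_pm1(y)
  n <- length(y)
  stopifnot(all(vapply(kernels, function(K) all(dim(K) == n), logical(1))))
  if (length(betas) != length(kernels) || any(betas < 0) ||
      abs(sum(betas) - 1) > 1e-9) {
    abort("betas must be non-negative and sum to 1",
          class = "jsseconn_svm_error")
  }
  if (!is.numeric(C) || C <= 0) {
    abort("C must be positive", class = "jsseconn_svm_error")
  }
  if (length(unique(y)) < 2L) {
    abort("training labels must contain both classes",
          class = "jsseconn_svm_error")
  }
  K <- Reduce(`+`, Map(`*`, betas, kernels))
  ev_min <- min(eigen((K + t(K)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(1, abs(max(K)))) {
    abort("combined kernel is not positive semi-definite",
          class = "jsseconn_svm_error")
  }
  fit <- .smo_solve(K, y, C)
  structure(
    list(alpha = fit$alpha, b = fit$b, betas = betas, C = C, y = y,
         support = which(fit$alpha > 1e-12), iterations = fit$iterations),
    class = "mksvm"
  )
}

#' Predict with a multi-kernel SVM
#'
#' Decision value `f(x) = sum_i y_i alpha_i sum_m beta_m k_m(x_i, x) + b`;
#' the label is its sign, with 0 mapped to +1.
#'
#' @param model An `mksvm` fit.
#' @param test_kernels List of `M` cross-kernel matrices, each
#'   `n_test x n_train` (rows: test samples, columns: the model's training
#'   samples).
#' @return Tibble with columns `decision` and `label` (+1 / -1).
#' @export
mksvm_predict <- function(model, test_kernels) {
  if (!is.list(test_kernels)) test_kernels <- list(test_kernels)
  stopifnot(length(test_kernels) == length(model$betas))
  n_train <- length(model$y)
  ok <- vapply(test_kernels, function(K) ncol(as.matrix(K)) == n_train,
               logical(1))
  if (!all(ok)) {
    abort("test kernels must have one column per training sample",
          class = "jsseconn_svm_error")
  }
  Kx <- Reduce(`+`, Map(`*`, model$betas,
                        lapply(test_kernels, as.matrix)))
  f <- as.numeric(Kx %*% (model$alpha * model$y)) + model$b
  tibble::tibble(decision = f, label = ifelse(f >= 0, 1, -1))
}

#' @export
print.mksvm <- function(x, ...) {
  cat("<mksvm> n =", length(x$y), "| C =", x$C,
      "| betas =", paste(signif(x$betas, 3), collapse = "/"),
      "| support vectors:", length(x$support), "\n")
  invisible(x)
}

#' @export
tidy.mksvm <- function(x, ...) {
  tibble::tibble(index = seq_along(x$alpha), alpha = x$alpha, y = x$y,
                 support = x$alpha > 1e-12)
}

# map labels to +1 / -1 (positive class first); numeric +-1 passes through
as_pm1 <- function(y, positive = "SZF") {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) {
      abort("numeric labels must be +1 / -1", class = "jsseconn_svm_error")
    }
    return(as.numeric(y))
  }
  y <- as.character(y)
  ifelse(y == positive, 1, -1)
}
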