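#' Maximum-margin classifiers on precomputed Gram matrices
#'
#' Both the feature-based model (polynomial kernel over sparse binary
#' vectors) and the tree-kernel model (composite SDF+SPF kernel) are trained
#' as soft-margin binary classifiers on a precomputed Gram matrix. The dual
#' problem is solved by kernlab's SMO; dual coefficients, support indices and
#' bias are extracted so decision values are recomputed directly from Gram
#' rows (`f = sum_i alpha_i y_i K(x_i, x) + b`).
#'
#' @name margin_model
NULL

#' Polynomial kernel
#'
#' `(u . v + coef0)^degree`, the kernel of the feature-based model over
#' sparse binary feature vectors.
#'
#' @param u,v Numeric (possibly sparse) vectors of equal length.
#' @param degree Polynomial degree (default 3).
#' @param coef0 Additive constant (default 1).
#' @return A number.
#' @export
poly_kernel <- function(u, v, degree = 3, coef0 = 1) {
  (sum(u * v) + coef0)^degree
}

#' Polynomial-kernel Gram matrix of sparse feature matrices
#'
#' @param X,Y Sparse binary matrices (candidates x features); `Y = NULL`
#'   computes the symmetric Gram of `X`.
#' @inheritParams poly_kernel
#' @return A dense numeric matrix.
#' @export
poly_gram <- function(X, Y = NULL, degree = 3, coef0 = 1) {
  G <- if (is.null(Y)) Matrix::tcrossprod(X) else Matrix::tcrossprod(X, Y)
  as.matrix((G + coef0)^degree)
}

#' Train a soft-margin classifier on a precomputed Gram matrix
#'
#' Solves the standard C-SVC dual with per-class cost weighting: the positive
#' class cost is multiplied by `j` (default: the ratio of negatives to
#' positives, countering class imbalance).
#'
#' @param gram Symmetric numeric Gram matrix of the training candidates.
#' @param labels Integer labels in `{-1, +1}`.
#' @param C Soft-margin cost (default 1).
#' @param j Cost factor on the positive class; `NULL` (default) uses
#'   `#negatives / #positives`.
#' @param tol SMO tolerance (default 1e-3).
#' @return A `cdr_margin_model` with support indices, dual coefficients
#'   (`alpha_i y_i`), bias, and the training configuration.
#' @export
train_margin_model <- function(gram, labels, C = 1, j = NULL, tol = 1e-3) {
  stopifnot(is.matrix(gram), nrow(gram) == ncol(gram), nrow(gram) == length(labels))
  if (max(abs(gram - t(gram))) > 1e-8) stop("Gram matrix is not symmetric")
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be in {-1, +1}")
  if (length(unique(labels)) < 2L) stop("training labels contain a single class")
  if (is.null(j)) j <- sum(labels == -1L) / sum(labels == 1L)
  y <- factor(labels, levels = c(-1L, 1L))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(gram), y, type = "C-svc",
                       C = C, class.weights = c("-1" = 1, "1" = j), tol = tol)
  sv <- unlist(kernlab::alphaindex(fit))
  coefs <- unlist(kernlab::coef(fit))
  bias <- -kernlab::b(fit)
  # orient the decision so that f > 0 <=> predicted label +1
  f_train <- as.vector(gram[, sv, drop = FALSE] %*% coefs) + bias
  flip <- if (mean(f_train[labels == 1L]) < mean(f_train[labels == -1L])) -1 else 1
  structure(list(support = sv, coef = flip * coefs, bias = flip * bias,
                 C = C, j = j, n_train = length(labels)),
            class = "cdr_margin_model")
}

#' @export
print.cdr_margin_model <- function(x, ...) {
  cat(sprintf("<cdr_margin_model: %d support vector(s) of %d, C=%g, j=%.3g>\n",
              length(x$support), x$n_train, x$C, x$j))
  invisible(x)
}

#' Decision values from Gram rows
#'
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b`, evaluated from the kernel values
#' between new candidates and the training candidates.
#'
#' @param model A `cdr_margin_model`.
#' @param gram_rows Matrix of kernel values, new candidates x training
#'   candidates (all training columns; support columns are selected
#'   internally). A vector is treated as one row.
#' @return Numeric decision values (positive = predicted relation).
#' @export
decision_value <- function(model, gram_rows) {
  if (is.vector(gram_rows)) gram_rows <- matrix(gram_rows, nrow = 1L)
  as.vector(gram_rows[, model$support, drop = FALSE] %*% model$coef) + model$bias
}

#' Logistic sigmoid
#'
#' Maps a margin decision value to a probability; `sigmoid(0) = 0.5`, so the
#' 0.5 probability boundary coincides with the separating hyperplane. The
#' transform is the plain (unfitted) logistic function, not Platt scaling.
#'
#' @param f Numeric vector.
#' @return Values in `(0, 1)`.
#' @export
sigmoid <- function(f) 1 / (1 + exp(-f))

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cdr_margin_model <- function(x, ...) {
  tibble(support_index = x$support, dual_coef = x$coef)
}

#' @export
glance.cdr_margin_model <- function(x, ...) {
  tibble(n_support = length(x$support), n_train = x$n_train,
         C = x$C, cost_factor = x$j, bias = x$bias)
}
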