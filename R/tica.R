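# Time-lagged independent component analysis: linear projections maximizing
# autocorrelation at a lag, from the generalized eigenproblem
# C(tau) v = lambda C(0) v on symmetrized covariance estimates.

#' Fit a tICA model
#'
#' Mean-centers the features, estimates the instantaneous covariance C(0)
#' and the lagged covariance C(tau) over all frame pairs at the given lag
#' (both symmetrized, so eigenvalues are real and bounded by 1), applies a
#' small ridge to C(0) (sin/cos dihedral features are near-collinear) and
#' solves the generalized eigenproblem by Cholesky whitening. Components are
#' normalized to unit C(0)-norm, so training projections have unit variance.
#'
#' @param X Numeric matrix, frames x features (column names kept as the
#'   feature schema).
#' @param lag Lag in frames (>= 1; `frames > lag + features` required for a
#'   well-conditioned estimate).
#' @param n_dims Number of components kept (default 2).
#' @param ridge Ridge scale; the regularizer added to C(0) is
#'   `ridge * trace(C0) / n_features * I`.
#' @return A `tica_model`: list with `lag`, `means`, `eigenvalues` (all,
#'   descending), `components` (features x n_dims, C(0)-orthonormal),
#'   `feature_names`, `ridge`, `C0`, `Ct`.
#' @export
fit_tica <- function(X, lag, n_dims = 2L, ridge = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (lag < 1L) stop("lag must be >= 1")
  if (n <= lag + p) stop("need more frames than lag + features")
  if (anyNA(X)) stop("missing values in feature matrix")
  a <- X[seq_len(n - lag), , drop = FALSE]
  b <- X[(lag + 1L):n, , drop = FALSE]
  mu <- colMeans(rbind(a, b))
  a <- sweep(a, 2L, mu); b <- sweep(b, 2L, mu)
  m <- nrow(a)
  C0 <- (crossprod(a) + crossprod(b)) / (2 * (m - 1))
  Ct <- crossprod(a, b) / (m - 1)
  Ct <- (Ct + t(Ct)) / 2
  lam_r <- ridge * sum(diag(C0)) / p
  C0r <- C0 + diag(lam_r, p)
  L <- tryCatch(chol(C0r), error = function(e)
    stop("C(0) rank-deficient beyond regularization: ", conditionMessage(e)))
  # whiten: solve L^-T Ct L^-1 symmetric eigenproblem
  Linv <- backsolve(L, diag(p))
  M <- t(Linv) %*% Ct %*% Linv
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  comps <- Linv %*% e$vectors          # generalized eigenvectors, v' C0r v = 1
  n_dims <- min(n_dims, p)
  V <- comps[, seq_len(n_dims), drop = FALSE]
  rownames(V) <- colnames(X)
  structure(list(lag = as.integer(lag), means = mu,
                 eigenvalues = e$values, components = V,
                 feature_names = colnames(X), ridge = ridge,
                 C0 = C0, Ct = Ct),
            class = "tica_model")
}

#' Project features onto a fitted tICA basis
#'
#' @param object A `tica_model`.
#' @param newdata Numeric matrix with the same feature columns as training.
#' @param ... Unused.
#' @return Projection matrix, frames x n_dims (columns `tIC1`, `tIC2`, ...).
#' @export
predict.tica_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (is.null(colnames(X)) || !identical(colnames(X), object$feature_names))
      stop("feature names do not match the training schema")
  }
  Y <- sweep(X, 2L, object$means) %*% object$components
  colnames(Y) <- paste0("tIC", seq_len(ncol(Y)))
  Y
}

#' @export
print.tica_model <- function(x, ...) {
  cat("tica_model: lag", x$lag, "frames;", ncol(x$components), "of",
      length(x$eigenvalues), "components kept\n")
  cat("leading eigenvalues:",
      paste(sprintf("%.4f", utils::head(x$eigenvalues, 4L)), collapse = ", "),
      "\n")
  invisible(x)
}
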