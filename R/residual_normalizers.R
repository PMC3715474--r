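# Special cases of the unified residual framework: expression Y is modeled
# as known-covariate effects (F beta) plus hidden-covariate effects (Z W)
# plus noise, and the normalized signal is the residual after subtracting
# the estimated effects. Three estimators live here: known-only ridge,
# hidden-only SVD removal, and the alternating known+hidden scheme.

#' Ridge regression of expression on known covariates
#'
#' Fits `beta` minimizing `||Y - F beta||_F^2 + lambda ||beta||_F^2` via the
#' closed form `beta = (F'F + lambda I)^{-1} F'Y`. The Gaussian prior on
#' `beta` (the ridge penalty) keeps the per-gene fits stable when covariates
#' are correlated or subjects few.
#'
#' @param Y Subjects-by-genes expression matrix.
#' @param F_known Subjects-by-m known-covariate matrix.
#' @param lambda Ridge penalty, `>= 0`; must be positive when `F'F` is
#'   singular.
#' @return An object of class `ridge_fit` with elements `beta` (m x genes)
#'   and `lambda`.
#' @export
ridge_fit <- function(Y, F_known, lambda = 0) {
  if (nrow(Y) != nrow(F_known)) stop("Y and F_known have different subject counts", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  ftf <- crossprod(F_known)
  a <- ftf + lambda * diag(ncol(F_known))
  if (lambda == 0 && rcond(a) < .Machine$double.eps * 100) {
    stop("F'F is singular; use lambda > 0", call. = FALSE)
  }
  beta <- solve(a, crossprod(F_known, Y))
  rownames(beta) <- colnames(F_known)
  colnames(beta) <- colnames(Y)
  structure(list(beta = beta, lambda = lambda), class = "ridge_fit")
}

#' Residual expression after removing known-covariate effects
#'
#' @param Y Subjects-by-genes expression matrix.
#' @param fit A `ridge_fit`.
#' @param F_known The covariate matrix used in the fit.
#' @return Expression matrix `Y - F beta` (same dimnames as `Y`).
#' @export
residual_known <- function(Y, fit, F_known) {
  stopifnot(inherits(fit, "ridge_fit"))
  if (nrow(Y) != nrow(F_known) || ncol(F_known) != nrow(fit$beta) ||
      ncol(fit$beta) != ncol(Y)) {
    stop("shape mismatch between Y, F_known and fitted beta", call. = FALSE)
  }
  out <- Y - F_known %*% fit$beta
  attr(out, "standardized") <- FALSE
  out
}

# Deterministic SVD sign convention: flip each component so its
# largest-magnitude element is positive.
fix_svd_signs <- function(u, v) {
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  list(u = u, v = v)
}

#' Remove the top-k principal components of an expression matrix
#'
#' Computes the truncated SVD of `Y` and subtracts the best rank-k
#' approximation (the Eckart-Young optimum), leaving the residual whose top
#' singular value is at most the (k+1)-th singular value of `Y`. Genes are
#' standardized first by default, the usual convention before expression
#' SVD so components are not dominated by mean expression levels.
#'
#' @param Y Subjects-by-genes expression matrix.
#' @param k Number of components to remove, `1 <= k <= min(n, g)`.
#' @param standardize Standardize gene columns first unless already flagged
#'   (default `TRUE`).
#' @return A list with `fit` (class `svd_fit`: `components` n x k with
#'   orthonormal columns, `loadings` k x genes, `singular_values`, `k`) and
#'   `residual` (the expression matrix actually decomposed minus its rank-k
#'   approximation).
#' @export
svd_remove <- function(Y, k, standardize = TRUE) {
  if (k < 1 || k > min(dim(Y))) stop("k must lie in [1, min(n, g)]", call. = FALSE)
  if (standardize && !is_standardized(Y)) Y <- suppressWarnings(standardize_genes(Y))
  s <- svd(Y, nu = k, nv = k)
  sg <- fix_svd_signs(s$u, s$v)
  low_rank <- sg$u %*% (s$d[seq_len(k)] * t(sg$v))
  residual <- Y - low_rank
  attr(residual, "standardized") <- FALSE
  attr(residual, "constant_genes") <- attr(Y, "constant_genes")
  fit <- structure(list(components = sg$u,
                        loadings = s$d[seq_len(k)] * t(sg$v),
                        singular_values = s$d[seq_len(k)],
                        k = k),
                   class = "svd_fit")
  colnames(fit$loadings) <- colnames(Y)
  rownames(fit$components) <- rownames(Y)
  list(fit = fit, residual = residual)
}

#' Ridge removal of known covariates followed by SVD removal
#'
#' A simplified approximation to joint known+hidden estimation: first the
#' ridge residual on known covariates, then removal of the top `k`
#' principal components of that residual. `k = 0` is a passthrough
#' returning the ridge residual alone.
#'
#' @inheritParams ridge_fit
#' @param k Number of principal components to remove from the ridge
#'   residual (`0` allowed).
#' @param standardize_svd Standardize genes before the SVD step (default
#'   `TRUE`).
#' @return Residual expression matrix.
#' @export
svd_plus_tech <- function(Y, F_known, lambda = 0, k = 10, standardize_svd = TRUE) {
  res <- residual_known(Y, ridge_fit(Y, F_known, lambda), F_known)
  if (k == 0) return(res)
  svd_remove(res, k, standardize = standardize_svd)$residual
}

#' Alternating estimation of known and hidden covariate effects
#'
#' Minimizes `||Y - F beta - Z W||_F^2 + lambda ||beta||_F^2` by block
#' coordinate descent: (i) ridge of `Y - Z W` on `F` for `beta`, (ii)
#' truncated SVD of `Y - F beta` for the rank-k hidden part `Z W`. Each
#' step is the exact minimizer of its block, so the objective is
#' non-increasing; iteration stops when its relative change falls below
#' `tol`. Initialized with the hidden part at zero, so the first sweep
#' reproduces the two-step ridge-then-SVD composition.
#'
#' @inheritParams ridge_fit
#' @param k Rank of the hidden part.
#' @param tol Relative objective-change threshold (default 1e-8).
#' @param max_iter Maximum outer iterations (default 100).
#' @return A list with `ridge` (a `ridge_fit`), `svd` (an `svd_fit` of the
#'   final known-residual), `residual`, `objective_trace`, `converged`,
#'   `iterations`.
#' @export
iterate_known_hidden <- function(Y, F_known, lambda = 0, k = 10,
                                 tol = 1e-8, max_iter = 100) {
  if (k < 1 || k > min(dim(Y))) stop("k must lie in [1, min(n, g)]", call. = FALSE)
  hidden <- matrix(0, nrow(Y), ncol(Y))
  obj <- function(beta, hid) {
    sum((Y - F_known %*% beta - hid)^2) + lambda * sum(beta^2)
  }
  trace <- numeric(0)
  fit <- NULL
  sfit <- NULL
  prev <- Inf
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    fit <- ridge_fit(Y - hidden, F_known, lambda)
    e <- Y - F_known %*% fit$beta
    sr <- svd_remove(e, k, standardize = FALSE)
    sfit <- sr$fit
    hidden <- e - sr$residual
    cur <- obj(fit$beta, hidden)
    trace <- c(trace, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged) {
    warning(sprintf("known+hidden alternation did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  residual <- Y - F_known %*% fit$beta - hidden
  attr(residual, "standardized") <- FALSE
  list(ridge = fit, svd = sfit, residual = residual,
       objective_trace = trace, converged = converged, iterations = it)
}
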