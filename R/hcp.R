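# HCP: hidden covariates with a prior centred on linear combinations of the
# known covariates. The model decomposes log expression Y (subjects x genes)
# as Z B + noise, with hidden factors Z drawn around F U, giving the
# penalized objective
#
#   ||Y - Z B||_F^2 + lambda1 ||Z - F U||_F^2
#                   + lambda2 ||B||_F^2 + lambda3 ||U||_F^2 .
#
# The objective is not jointly convex but is convex in each of Z, B, U with
# the others fixed, so block coordinate descent with closed-form updates
# decreases it monotonically. The normalized expression is the residual
# Y - Z B; F acts on the residual only through the prior on Z.

#' HCP objective value
#'
#' Evaluates the penalized factorization objective
#' `||Y - Z B||^2 + lambda1 ||Z - F U||^2 + lambda2 ||B||^2 + lambda3 ||U||^2`
#' (all norms Frobenius). With `F_known = NULL` the prior term and `U`
#' penalty are dropped.
#'
#' @param Y Subjects-by-genes expression matrix.
#' @param F_known Subjects-by-m known-covariate matrix, or `NULL`.
#' @param Z Subjects-by-k hidden-factor matrix.
#' @param B k-by-genes loading matrix.
#' @param U m-by-k covariate-to-factor map (ignored when `F_known` is
#'   `NULL`).
#' @param lambda1,lambda2,lambda3 Positive penalty weights on the prior
#'   term, `B`, and `U` respectively.
#' @return A single non-negative number.
#' @export
hcp_objective <- function(Y, F_known, Z, B, U = NULL,
                          lambda1 = 1, lambda2 = 1, lambda3 = 1) {
  if (nrow(Z) != nrow(Y) || ncol(B) != ncol(Y) || ncol(Z) != nrow(B)) {
    stop("shape mismatch among Y, Z, B", call. = FALSE)
  }
  val <- sum((Y - Z %*% B)^2) + lambda2 * sum(B^2)
  if (!is.null(F_known)) {
    if (is.null(U) || nrow(U) != ncol(F_known) || ncol(U) != ncol(Z)) {
      stop("shape mismatch between F_known and U", call. = FALSE)
    }
    val <- val + lambda1 * sum((Z - F_known %*% U)^2) + lambda3 * sum(U^2)
  }
  val
}

# Exact block minimizers. Each solves the stationarity condition of the
# objective in its own block:
#   U: (lambda1 F'F + lambda3 I) U = lambda1 F'Z
#   Z: Z (B B' + lambda1 I) = Y B' + lambda1 F U
#   B: (Z'Z + lambda2 I) B = Z'Y
update_u <- function(F_known, Z, lambda1, lambda3) {
  solve(lambda1 * crossprod(F_known) + lambda3 * diag(ncol(F_known)),
        lambda1 * crossprod(F_known, Z))
}
update_z <- function(Y, F_known, U, B, lambda1) {
  if (is.null(F_known)) {
    a <- tcrossprod(B)
    if (rcond(a) < .Machine$double.eps * 100) {
      stop("B B' is singular in the Z update; increase lambda2 or reduce k",
           call. = FALSE)
    }
    t(solve(a, B %*% t(Y)))
  } else {
    t(solve(tcrossprod(B) + lambda1 * diag(nrow(B)),
            B %*% t(Y) + lambda1 * t(F_known %*% U)))
  }
}
update_b <- function(Y, Z, lambda2) {
  solve(crossprod(Z) + lambda2 * diag(ncol(Z)), crossprod(Z, Y))
}

#' Fit the HCP model by block coordinate descent
#'
#' Hidden factors `Z` (subjects x k), gene loadings `B` (k x genes) and the
#' covariate-to-factor map `U` (m x k) are updated cyclically (U, Z, B) by
#' their closed-form block minimizers until the relative change of the
#' objective drops below `tol`. Initialization is `U0` from a seeded
#' standard normal scaled by `1/sqrt(m)`, `Z0 = F U0` (inside the prior
#' manifold) and `B0 = 0`; identical seed and inputs give a bit-identical
#' fit. With `F_known = NULL` the model reduces to a penalized rank-k
#' factorization (no prior term) and `Z0` is a seeded normal scaled by
#' `1/sqrt(k)`.
#'
#' The penalties balance the model's capacity: `lambda1` is the prior
#' strength pulling hidden factors toward linear combinations of known
#' covariates; `lambda2` and `lambda3` are ridge penalties on `B` and `U`.
#' In practice they are chosen by cross-validation on the downstream task
#' of interest.
#'
#' @param Y Subjects-by-genes expression matrix; gene standardization is
#'   recommended (a warning is issued otherwise).
#' @param F_known Subjects-by-m known-covariate matrix, or `NULL` for the
#'   covariate-free factorization.
#' @param k Number of hidden factors (default 20).
#' @param lambda1,lambda2,lambda3 Positive penalties (defaults 1, 1, 1).
#' @param tol Relative objective-change convergence threshold (default
#'   1e-6).
#' @param max_iter Maximum coordinate-descent sweeps (default 500).
#' @param seed Integer seed for the initialization draw (default 1).
#' @return An object of class `hcp_fit`: list with `Z`, `B`, `U` (`NULL`
#'   without covariates), `objective_trace` (initial value plus one entry
#'   per sweep, non-increasing), `converged`, `iterations`, and `params`.
#' @examples
#' sim <- generate_expression(n = 30, g = 60, seed = 1)
#' fit <- hcp_fit(standardize_genes(sim$expression), sim$covariates,
#'                k = 4, lambda1 = 5)
#' glance(fit)
#' @export
hcp_fit <- function(Y, F_known = NULL, k = 20,
                    lambda1 = 1, lambda2 = 1, lambda3 = 1,
                    tol = 1e-6, max_iter = 500, seed = 1) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (min(lambda1, lambda2, lambda3) <= 0) stop("all lambdas must be > 0", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (!is.null(F_known) && nrow(F_known) != nrow(Y)) {
    stop("Y and F_known have different subject counts", call. = FALSE)
  }
  if (!is_standardized(Y)) {
    warning("Y is not flagged as gene-standardized; HCP is usually fitted on standardized genes",
            call. = FALSE)
  }
  n <- nrow(Y)
  g <- ncol(Y)
  old_seed <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (is.null(F_known)) {
    U <- NULL
    Z <- matrix(rnorm(n * k) / sqrt(k), n, k)
  } else {
    m <- ncol(F_known)
    U <- matrix(rnorm(m * k) / sqrt(m), m, k)
    Z <- F_known %*% U
  }
  B <- matrix(0, k, g)
  obj <- function() hcp_objective(Y, F_known, Z, B, U, lambda1, lambda2, lambda3)
  trace <- obj()
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    if (is.null(F_known)) {
      # no prior term: B must move off its zero start before the Z solve
      B <- update_b(Y, Z, lambda2)
      Z <- update_z(Y, F_known, U, B, lambda1)
      B <- update_b(Y, Z, lambda2)
    } else {
      U <- update_u(F_known, Z, lambda1, lambda3)
      Z <- update_z(Y, F_known, U, B, lambda1)
      B <- update_b(Y, Z, lambda2)
    }
    if (anyNA(Z) || anyNA(B) || (!is.null(U) && anyNA(U))) {
      stop(sprintf("NaN encountered in HCP update at iteration %d", it), call. = FALSE)
    }
    cur <- obj()
    prev <- trace[length(trace)]
    trace <- c(trace, cur)
    if (abs(prev - cur) <= tol * max(abs(prev), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("HCP did not converge in %d iterations (relative change %.3g)",
                    max_iter, abs(diff(utils::tail(trace, 2))) / utils::tail(trace, 2)[1]),
            call. = FALSE)
  }
  rownames(Z) <- rownames(Y)
  colnames(Z) <- paste0("factor", seq_len(k))
  rownames(B) <- colnames(Z)
  colnames(B) <- colnames(Y)
  if (!is.null(U)) {
    rownames(U) <- colnames(F_known)
    colnames(U) <- colnames(Z)
  }
  structure(list(Z = Z, B = B, U = U,
                 objective_trace = trace, converged = converged, iterations = it,
                 params = list(k = k, lambda1 = lambda1, lambda2 = lambda2,
                               lambda3 = lambda3, tol = tol,
                               max_iter = max_iter, seed = seed,
                               has_covariates = !is.null(F_known))),
            class = "hcp_fit")
}

#' Covariate-free HCP (penalized matrix factorization)
#'
#' Drops the covariate prior entirely: minimizes
#' `||Y - Z B||^2 + lambda2 ||B||^2`, a penalized rank-k factorization whose
#' residual approaches the top-k SVD residual as `lambda2` shrinks.
#'
#' @inheritParams hcp_fit
#' @return An `hcp_fit` with `U = NULL`.
#' @export
hcp_no_covariates <- function(Y, k = 20, lambda2 = 1, tol = 1e-6,
                              max_iter = 500, seed = 1) {
  hcp_fit(Y, F_known = NULL, k = k, lambda1 = 1, lambda2 = lambda2,
          lambda3 = 1, tol = tol, max_iter = max_iter, seed = seed)
}

#' Residual expression after removing fitted hidden-covariate effects
#'
#' The normalized signal `Y - Z B`; the removed part `Z B` is the estimated
#' hidden-covariate component.
#'
#' @param Y The expression matrix the model was fitted on.
#' @param model An `hcp_fit`.
#' @return Residual expression matrix with the dimnames of `Y`.
#' @export
hcp_residual <- function(Y, model) {
  stopifnot(inherits(model, "hcp_fit"))
  if (nrow(model$Z) != nrow(Y) || ncol(model$B) != ncol(Y)) {
    stop("shape mismatch between Y and fitted model", call. = FALSE)
  }
  out <- Y - model$Z %*% model$B
  attr(out, "standardized") <- FALSE
  out
}

ols_r2 <- function(y, X) {
  # R^2 of y on [1, X]; guards the constant-y degenerate case
  vy <- sum((y - mean(y))^2)
  if (vy < .Machine$double.eps) return(0)
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / vy
}

#' Variance of the removed expression explained by known covariates
#'
#' Diagnostic for how much of the removed component `Z B` tracks the known
#' covariates: each hidden factor (column of `Z`) is regressed on `F` (with
#' intercept) giving per-factor R-squared values; the overall fraction is
#' their weighted mean with weights `||B_j.||^2 * ||Z_j||^2`, the squared
#' magnitude each factor contributes to the removed matrix. With
#' `nonlinear = TRUE` the regressors are augmented with squares and
#' pairwise products of the covariate columns, capturing non-linear
#' combinations of the known factors.
#'
#' @param model An `hcp_fit` fitted with covariates.
#' @param F_known The known-covariate matrix used in the fit.
#' @param nonlinear Augment `F` with second-order terms (default `FALSE`).
#' @return A list with `overall` (fraction in \[0, 1\]) and `per_factor`
#'   (tibble: `factor`, `r_squared`, `weight`).
#' @export
variance_explained_by_known <- function(model, F_known, nonlinear = FALSE) {
  stopifnot(inherits(model, "hcp_fit"))
  if (is.null(model$Z) || ncol(model$Z) == 0) stop("model has no hidden factors", call. = FALSE)
  X <- F_known
  if (nonlinear) {
    sq <- F_known^2
    colnames(sq) <- paste0(colnames(F_known), "^2")
    prods <- NULL
    if (ncol(F_known) >= 2) {
      cmb <- combn(ncol(F_known), 2)
      prods <- apply(cmb, 2, function(ij) F_known[, ij[1]] * F_known[, ij[2]])
      colnames(prods) <- apply(cmb, 2, function(ij) {
        paste(colnames(F_known)[ij], collapse = "*")
      })
    }
    X <- cbind(F_known, sq, prods)
  }
  r2 <- vapply(seq_len(ncol(model$Z)), function(j) ols_r2(model$Z[, j], X), numeric(1))
  w <- rowSums(model$B^2) * colSums(model$Z^2)
  if (sum(w) < .Machine$double.eps) w <- rep(1, length(w))
  list(overall = sum(w * r2) / sum(w),
       per_factor = tibble::tibble(factor = colnames(model$Z),
                                   r_squared = r2, weight = w))
}

# ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an HCP fit into a long tibble
#'
#' @param x An `hcp_fit`.
#' @param matrix Which component to tidy: `"Z"` (subject scores), `"B"`
#'   (gene loadings) or `"U"` (covariate-to-factor map).
#' @param ... Unused.
#' @return A tibble in long form with a `factor` column and, depending on
#'   `matrix`, a `subject`/`gene`/`covariate` column plus `value`.
#' @export
tidy.hcp_fit <- function(x, matrix = c("Z", "B", "U"), ...) {
  matrix <- match.arg(matrix)
  m <- x[[matrix]]
  if (is.null(m)) stop(sprintf("model has no %s component", matrix), call. = FALSE)
  id <- switch(matrix, Z = "subject", B = "factor", U = "covariate")
  long <- tibble::as_tibble(m, rownames = id) |>
    tidyr::pivot_longer(-dplyr::all_of(id), names_to = if (matrix == "B") "gene" else "factor",
                        values_to = "value")
  if (matrix == "B") long <- dplyr::rename(long, factor = "factor")
  long
}

#' One-row summary of an HCP fit
#'
#' @param x An `hcp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, penalties, iterations, convergence
#'   flag and final objective.
#' @export
glance.hcp_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$Z), n_genes = ncol(x$B), k = x$params$k,
    lambda1 = x$params$lambda1, lambda2 = x$params$lambda2,
    lambda3 = x$params$lambda3,
    iterations = x$iterations, converged = x$converged,
    objective = x$objective_trace[length(x$objective_trace)])
}

#' @export
print.hcp_fit <- function(x, ...) {
  cat(sprintf("HCP fit: %d subjects x %d genes, k = %d%s\n",
              nrow(x$Z), ncol(x$B), x$params$k,
              if (x$params$has_covariates) "" else " (no known covariates)"))
  cat(sprintf("  lambda = (%g, %g, %g); %d iterations, %s; objective %.6g\n",
              x$params$lambda1, x$params$lambda2, x$params$lambda3,
              x$iterations, if (x$converged) "converged" else "NOT converged",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Plot the coordinate-descent objective trace of an HCP fit
#'
#' @param object An `hcp_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the objective per sweep (log10 y-axis).
#' @export
autoplot.hcp_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "coordinate-descent sweep", y = "objective (log scale)",
                  title = "HCP block coordinate descent") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
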