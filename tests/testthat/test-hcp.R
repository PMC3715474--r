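make_instance <- function(n = 20, g = 30, m = 3, k = 4, seed = 1) {
  withr::with_seed(seed, {
    list(Y = matrix(rnorm(n * g), n, g),
         F_known = matrix(rnorm(n * m), n, m),
         Z = matrix(rnorm(n * k), n, k),
         B = matrix(rnorm(k * g), k, g),
         U = matrix(rnorm(m * k), m, k))
  })
}

test_that("hcp objective matches brute-force term-by-term summation", {
  inst <- make_instance(seed = 41)
  l <- c(0.7, 1.3, 2.1)
  got <- hcp_objective(inst$Y, inst$F_known, inst$Z, inst$B, inst$U,
                       l[1], l[2], l[3])
  brute <- 0
  E1 <- inst$Y - inst$Z %*% inst$B
  E2 <- inst$Z - inst$F_known %*% inst$U
  for (v in as.vector(E1)) brute <- brute + v * v
  for (v in as.vector(E2)) brute <- brute + l[1] * v * v
  for (v in as.vector(inst$B)) brute <- brute + l[2] * v * v
  for (v in as.vector(inst$U)) brute <- brute + l[3] * v * v
  expect_equal(got, brute, tolerance = 1e-12)

  # zero and exact-fit cases
  z0 <- matrix(0, 20, 4)
  expect_equal(hcp_objective(matrix(0, 20, 30), inst$F_known, z0,
                             matrix(0, 4, 30), matrix(0, 3, 4)), 0)
  Zfu <- inst$F_known %*% inst$U
  Yzb <- Zfu %*% inst$B
  expect_equal(hcp_objective(Yzb, inst$F_known, Zfu, inst$B, inst$U,
                             lambda1 = 5, lambda2 = 0, lambda3 = 0), 0,
               tolerance = 1e-20)
})

test_that("each single block update never increases the objective", {
  for (seed in 1:20) {
    inst <- make_instance(n = 12, g = 18, m = 2, k = 3, seed = seed)
    l1 <- 1.5; l2 <- 0.8; l3 <- 1.2
    obj <- function(Z, B, U) hcp_objective(inst$Y, inst$F_known, Z, B, U, l1, l2, l3)
    Z <- inst$Z; B <- inst$B; U <- inst$U
    before <- obj(Z, B, U)
    U2 <- hcpnorm:::update_u(inst$F_known, Z, l1, l3)
    expect_lte(obj(Z, B, U2), before + 1e-9 * before)
    mid <- obj(Z, B, U2)
    Z2 <- hcpnorm:::update_z(inst$Y, inst$F_known, U2, B, l1)
    expect_lte(obj(Z2, B, U2), mid + 1e-9 * mid)
    mid2 <- obj(Z2, B, U2)
    B2 <- hcpnorm:::update_b(inst$Y, Z2, l2)
    expect_lte(obj(Z2, B2, U2), mid2 + 1e-9 * mid2)
  }
})

test_that("block updates are exact minimizers (numerical-optimizer oracle)", {
  inst <- make_instance(n = 8, g = 6, m = 2, k = 2, seed = 55)
  l1 <- 2; l2 <- 0.5; l3 <- 1.5
  # Z block: optimize over vec(Z) holding B, U
  zhat <- hcpnorm:::update_z(inst$Y, inst$F_known, inst$U, inst$B, l1)
  fz <- function(z) hcp_objective(inst$Y, inst$F_known, matrix(z, 8, 2),
                                  inst$B, inst$U, l1, l2, l3)
  num <- optim(rep(0, 16), fz, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(max(abs(zhat - matrix(num$par, 8, 2))), 1e-4)
  # U block
  uhat <- hcpnorm:::update_u(inst$F_known, inst$Z, l1, l3)
  fu <- function(u) hcp_objective(inst$Y, inst$F_known, inst$Z, inst$B,
                                  matrix(u, 2, 2), l1, l2, l3)
  numu <- optim(rep(0, 4), fu, method = "BFGS",
                control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(max(abs(uhat - matrix(numu$par, 2, 2))), 1e-4)
})

test_that("hcp recovers noiseless planted data generated from its own model", {
  n <- 40; g <- 200; m <- 2; k <- 2
  withr::with_seed(42, {
    Fk <- matrix(rnorm(n * m), n, m)
    Ustar <- matrix(rnorm(m * k), m, k)
    Bstar <- matrix(rnorm(k * g), k, g)
  })
  Zstar <- Fk %*% Ustar
  Y <- Zstar %*% Bstar
  attr(Y, "standardized") <- TRUE
  fit <- suppressWarnings(
    hcp_fit(Y, Fk, k = k, lambda1 = 1, lambda2 = 1e-6, lambda3 = 1e-6,
            tol = 1e-12, max_iter = 2000, seed = 1))
  rel_err <- sqrt(sum((Y - fit$Z %*% fit$B)^2) / sum(Y^2))
  expect_lt(rel_err, 1e-3)
  expect_lt(max(abs(hcp_residual(Y, fit))) / max(abs(Y)), 1e-3)
})

test_that("a very strong prior forces hidden factors into the covariate span", {
  sim <- generate_expression(n = 30, g = 80, m = 3, k = 3, seed = 43)
  Y <- standardize_genes(sim$expression)
  fit <- hcp_fit(Y, sim$covariates, k = 3, lambda1 = 1e8, seed = 1)
  proj <- sim$covariates %*% solve(crossprod(sim$covariates),
                                   crossprod(sim$covariates, fit$Z))
  expect_lt(sqrt(sum((fit$Z - proj)^2) / sum(fit$Z^2)), 1e-4)
})

test_that("the objective trace is monotone and the fit deterministic under seed", {
  sim <- generate_expression(n = 25, g = 60, seed = 44)
  Y <- standardize_genes(sim$expression)
  f1 <- hcp_fit(Y, sim$covariates, k = 5, seed = 7)
  f2 <- hcp_fit(Y, sim$covariates, k = 5, seed = 7)
  expect_identical(f1$Z, f2$Z)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_true(all(diff(f1$objective_trace) <= 1e-9 * f1$objective_trace[1]))
  expect_length(f1$objective_trace, f1$iterations + 1)

  f3 <- hcp_fit(Y, sim$covariates, k = 5, seed = 8)
  expect_false(identical(f1$Z, f3$Z))
})

test_that("fixed point satisfies the block normal equations", {
  sim <- generate_expression(n = 20, g = 40, seed = 45)
  Y <- standardize_genes(sim$expression)
  Fk <- sim$covariates
  fit <- hcp_fit(Y, Fk, k = 4, lambda1 = 3, tol = 1e-12, max_iter = 5000, seed = 1)
  l1 <- 3; l2 <- 1; l3 <- 1
  # relative residuals of each block's normal equations, ||A X - b|| / ||b||
  u_rhs <- l1 * crossprod(Fk, fit$Z)
  u_resid <- (l1 * crossprod(Fk) + l3 * diag(3)) %*% fit$U - u_rhs
  z_rhs <- Y %*% t(fit$B) + l1 * Fk %*% fit$U
  z_resid <- fit$Z %*% (tcrossprod(fit$B) + l1 * diag(4)) - z_rhs
  b_rhs <- crossprod(fit$Z, Y)
  b_resid <- (crossprod(fit$Z) + l2 * diag(4)) %*% fit$B - b_rhs
  expect_lt(norm(u_resid, "F") / norm(u_rhs, "F"), 1e-6)
  expect_lt(norm(z_resid, "F") / norm(z_rhs, "F"), 1e-6)
  expect_lt(norm(b_resid, "F") / norm(b_rhs, "F"), 1e-6)
})

test_that("hcp residual is definitional and honours a zero-loading model", {
  sim <- generate_expression(n = 15, g = 20, seed = 46)
  Y <- standardize_genes(sim$expression)
  fit <- hcp_fit(Y, sim$covariates, k = 3, seed = 1)
  expect_lt(max(abs(Y - (fit$Z %*% fit$B + hcp_residual(Y, fit)))), 1e-10)

  fit0 <- fit
  fit0$B[] <- 0
  expect_lt(max(abs(hcp_residual(Y, fit0) - Y)), 1e-12)
})

test_that("covariate-free hcp approaches the svd residual on low-rank data", {
  n <- 25; g <- 60; k <- 3
  withr::with_seed(47, {
    Zs <- matrix(rnorm(n * k), n, k)
    Bs <- matrix(rnorm(k * g), k, g)
  })
  Y <- Zs %*% Bs + 0.05 * matrix(withr::with_seed(48, rnorm(n * g)), n, g)
  attr(Y, "standardized") <- TRUE
  fit <- hcp_no_covariates(Y, k = k, lambda2 = 1e-8, tol = 1e-12,
                           max_iter = 3000, seed = 1)
  expect_true(all(diff(fit$objective_trace) <= 1e-9 * fit$objective_trace[1]))
  hcp_norm <- sqrt(sum(hcp_residual(Y, fit)^2))
  svd_norm <- sqrt(sum(svd_remove(Y, k, standardize = FALSE)$residual^2))
  expect_lt(abs(hcp_norm - svd_norm) / svd_norm, 0.01)

  # rank-1 exact case
  Y1 <- Zs[, 1] %o% Bs[1, ]
  attr(Y1, "standardized") <- TRUE
  fit1 <- hcp_no_covariates(Y1, k = 1, lambda2 = 1e-10, tol = 1e-14,
                            max_iter = 2000, seed = 1)
  expect_lt(max(abs(hcp_residual(Y1, fit1))) / max(abs(Y1)), 1e-4)
})

test_that("variance explained by known covariates matches per-column regression", {
  n <- 50; m <- 3; k <- 4
  withr::with_seed(49, {
    Fk <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("c", 1:m)))
    U <- matrix(rnorm(m * k), m, k)
    noise <- matrix(rnorm(n * k), n, k)
    B <- matrix(rnorm(k * 30), k, 30)
  })
  # exact linear map -> all fractions 1
  fit <- structure(list(Z = Fk %*% U, B = B,
                        params = list(k = k)), class = "hcp_fit")
  colnames(fit$Z) <- paste0("factor", 1:k)
  ve <- variance_explained_by_known(fit, Fk)
  expect_equal(ve$overall, 1, tolerance = 1e-10)
  expect_equal(ve$per_factor$r_squared, rep(1, k), tolerance = 1e-10)

  # orthogonal construction -> fractions ~ 0
  Qperp <- qr.Q(qr(cbind(1, Fk)), complete = TRUE)[, (m + 2):n]
  fit_o <- fit
  fit_o$Z <- Qperp[, 1:k]
  colnames(fit_o$Z) <- paste0("factor", 1:k)
  ve_o <- variance_explained_by_known(fit_o, Fk)
  expect_lt(ve_o$overall, 1e-10)

  # noisy map -> matches independent lm() R^2 per column
  fit_n <- fit
  fit_n$Z <- Fk %*% U + 0.8 * noise
  colnames(fit_n$Z) <- paste0("factor", 1:k)
  ve_n <- variance_explained_by_known(fit_n, Fk)
  for (j in 1:k) {
    ref <- summary(lm(fit_n$Z[, j] ~ Fk))$r.squared
    expect_equal(ve_n$per_factor$r_squared[j], ref, tolerance = 1e-10)
  }
  expect_true(all(ve_n$per_factor$r_squared < 1))
  # nonlinear augmentation can only increase each fraction
  ve_nl <- variance_explained_by_known(fit_n, Fk, nonlinear = TRUE)
  expect_true(all(ve_nl$per_factor$r_squared >=
                    ve_n$per_factor$r_squared - 1e-10))
})

test_that("tidy and glance summarize a fit in broom shapes", {
  sim <- generate_expression(n = 15, g = 20, seed = 50)
  fit <- hcp_fit(standardize_genes(sim$expression), sim$covariates, k = 3, seed = 1)
  tz <- tidy(fit, "Z")
  expect_identical(names(tz), c("subject", "factor", "value"))
  expect_equal(nrow(tz), 15 * 3)
  tb <- tidy(fit, "B")
  expect_equal(nrow(tb), 3 * 20)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_equal(gl$k, 3)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("hcp validates its inputs", {
  sim <- generate_expression(n = 10, g = 12, seed = 51)
  Y <- standardize_genes(sim$expression)
  expect_error(hcp_fit(Y, sim$covariates, k = 0), "k must be")
  expect_error(hcp_fit(Y, sim$covariates, k = 2, lambda1 = 0), "lambdas must be")
  expect_error(hcp_fit(Y, sim$covariates[1:5, ], k = 2), "subject counts")
  expect_warning(hcp_fit(sim$expression, sim$covariates, k = 2), "standardized")
})
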