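test_that("resolve_k rounds half away from zero and clips", {
  expect_identical(resolve_k(0.45, 269, 598), 121L)
  expect_identical(resolve_k(0.5, 10, 50), 5L)
  expect_identical(resolve_k(0.01, 10, 10), 1L)   # lower clip
  expect_identical(resolve_k(0.99, 10, 10), 9L)   # upper clip to k0 - 1
  expect_identical(resolve_k(0.25, 10, 40), 3L)   # 2.5 rounds up, not to even
  expect_error(resolve_k(0, 10, 10), "k_fraction")
})

test_that("initialization is seeded, scaled and shaped as requested", {
  f1 <- init_factors(7, 5, 3, seed = 42)
  f2 <- init_factors(7, 5, 3, seed = 42)
  expect_identical(f1, f2)
  expect_false(identical(f1, init_factors(7, 5, 3, seed = 43)))
  expect_identical(dim(f1$X), c(7L, 3L))
  expect_identical(dim(f1$Y), c(5L, 3L))
  expect_true(all(f1$X > 0 & f1$X < 1 / sqrt(3)))
})

test_that("objective has the closed forms at zero and exact factors", {
  inst <- rand_instance(5, 4, 2, seed = 1)
  A <- inst$A
  Z <- matrix(0, 5, 2); W0 <- matrix(0, 4, 2)
  expect_equal(scmfdd_objective(A, Z, W0, inst$Wd, inst$Ws, 3, 7),
               0.5 * sum(A))
  X <- matrix(runif(10), 5, 2); Y <- matrix(runif(8), 4, 2)
  expect_equal(scmfdd_objective(X %*% t(Y), X, Y, NULL, NULL, 0, 0), 0)
  expect_error(scmfdd_objective(A, Z, matrix(0, 3, 2), NULL, NULL, 1, 1),
               "shape")
})

test_that("objective matches the term-by-term brute-force sum", {
  for (s in 1:10) {
    inst <- rand_instance(4, 3, 2, seed = s)
    expect_equal(
      scmfdd_objective(inst$A, inst$X, inst$Y, inst$Wd, inst$Ws, 0.7, 1.3),
      oracle_objective(inst$A, inst$X, inst$Y, inst$Wd, inst$Ws, 0.7, 1.3),
      tolerance = 1e-12)
  }
})

test_that("row gradients vanish at the ridge solution and drop terms at lam=0", {
  inst <- rand_instance(6, 5, 3, seed = 3)
  A <- inst$A; Y <- inst$Y; X <- inst$X
  mu <- 0.9
  # ridge stationarity
  Xr <- X
  Xr[2, ] <- as.numeric(A[2, , drop = FALSE] %*% Y %*%
                          solve(crossprod(Y) + diag(mu, 3)))
  expect_lt(max(abs(grad_x(2, A, Xr, Y, NULL, mu, 0))), 1e-12)
  # lam = 0 equals the explicit two-term form
  g <- grad_x(4, A, X, Y, inst$Wd, mu, 0)
  gref <- as.numeric(X[4, , drop = FALSE] %*% (crossprod(Y) + diag(mu, 3)) -
                       A[4, , drop = FALSE] %*% Y)
  expect_equal(g, gref, tolerance = 1e-12)
  # Wd = 0 behaves like lam = 0
  expect_equal(grad_x(1, A, X, Y, matrix(0, 6, 6), mu, 5),
               grad_x(1, A, X, Y, NULL, mu, 0), tolerance = 1e-12)
})

test_that("row updates are exact Newton steps and reduce to ridge at lam=0", {
  for (s in 1:5) {
    inst <- rand_instance(6, 5, 3, seed = s)
    X <- inst$X; Y <- inst$Y
    mu <- 0.5; lam <- 1.7
    for (i in 1:6) {
      X[i, ] <- update_x_row(i, inst$A, X, Y, inst$Wd, mu, lam)
      expect_lt(sqrt(sum(grad_x(i, inst$A, X, Y, inst$Wd, mu, lam)^2)), 1e-8)
    }
    for (j in 1:5) {
      Y[j, ] <- update_y_row(j, inst$A, X, Y, inst$Ws, mu, lam)
      expect_lt(sqrt(sum(grad_y(j, inst$A, X, Y, inst$Ws, mu, lam)^2)), 1e-8)
    }
    ridge <- as.numeric(inst$A[2, , drop = FALSE] %*% inst$Y %*%
                          solve(crossprod(inst$Y) + diag(mu, 3)))
    expect_equal(update_x_row(2, inst$A, inst$X, inst$Y, NULL, mu, 0),
                 ridge, tolerance = 1e-10)
    expect_equal(update_x_row(2, inst$A, inst$X, inst$Y,
                              matrix(0, 6, 6), mu, 5),
                 update_x_row(2, inst$A, inst$X, inst$Y, NULL, mu, 0),
                 tolerance = 1e-12)
  }
})

test_that("the objective trace is non-increasing and the fit deterministic", {
  for (s in 1:5) {
    inst <- rand_instance(12, 9, 3, seed = s)
    fit <- scmfdd_fit(inst$A, inst$Wd, inst$Ws, k = 3, mu = 0.8, lam = 1.5,
                      max_sweeps = 40, seed = s)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    refit <- scmfdd_fit(inst$A, inst$Wd, inst$Ws, k = 3, mu = 0.8, lam = 1.5,
                        max_sweeps = 40, seed = s)
    expect_identical(fit, refit)
  }
})

test_that("the fit's sweep updates equal the row-update contract", {
  # one sweep of the optimizer reproduces sequential update_x_row /
  # update_y_row applications (Gauss-Seidel order)
  inst <- rand_instance(7, 6, 3, seed = 9)
  fit1 <- scmfdd_fit(inst$A, inst$Wd, inst$Ws, k = 3, mu = 1.1, lam = 2.3,
                     max_sweeps = 1, tol = 0, seed = 5)
  fac <- init_factors(7, 6, 3, seed = 5)
  X <- fac$X; Y <- fac$Y
  for (i in 1:7) X[i, ] <- update_x_row(i, inst$A, X, Y, inst$Wd, 1.1, 2.3)
  for (j in 1:6) Y[j, ] <- update_y_row(j, inst$A, X, Y, inst$Ws, 1.1, 2.3)
  expect_equal(fit1$X, X, tolerance = 1e-10)
  expect_equal(fit1$Y, Y, tolerance = 1e-10)
})

test_that("with lam=0 the fit coincides with a plain ridge ALS oracle", {
  inst <- rand_instance(10, 8, 2, seed = 21)
  fit <- scmfdd_fit(inst$A, NULL, NULL, k = 2, mu = 0.6, lam = 0,
                    max_sweeps = 6, tol = 0, seed = 2)
  als <- oracle_als(inst$A, k = 2, mu = 0.6, sweeps = 6, seed = 2)
  expect_equal(fit$objective_trace, als$trace, tolerance = 1e-10)
  expect_equal(fit$X, als$X, tolerance = 1e-10)
  expect_equal(fit$Y, als$Y, tolerance = 1e-10)
})

test_that("a rank-1 association pattern is recovered nearly exactly", {
  u <- rep(0:1, c(4, 8)); v <- rep(1:0, c(6, 6))
  A <- outer(u, v)
  fit <- scmfdd_fit(A, NULL, NULL, k = 1, mu = 1e-3, lam = 0,
                    max_sweeps = 500, tol = 1e-12, seed = 1)
  err <- sqrt(sum((A - tcrossprod(fit$X, fit$Y))^2)) / sqrt(sum(A^2))
  expect_lt(err, 0.05)
})

test_that("tol = Inf stops after a single sweep", {
  inst <- rand_instance(6, 5, 2, seed = 2)
  fit <- scmfdd_fit(inst$A, NULL, NULL, k = 2, mu = 1, lam = 0, tol = Inf)
  expect_identical(fit$sweeps_run, 1L)
  expect_true(fit$converged)
})

test_that("predict returns X Y^T with training dimnames", {
  inst <- rand_instance(5, 4, 2, seed = 8)
  dimnames(inst$A) <- list(paste0("dr", 1:5), paste0("di", 1:4))
  fit <- scmfdd_fit(inst$A, NULL, NULL, k = 2, mu = 1, lam = 0,
                    max_sweeps = 3)
  S <- predict(fit)
  expect_identical(dimnames(S), dimnames(inst$A))
  for (i in 1:5) for (j in 1:4)
    expect_equal(S[i, j], sum(fit$X[i, ] * fit$Y[j, ]))
})

test_that("hyperparameter validation rejects bad mu, lam, k, asymmetry", {
  inst <- rand_instance(5, 4, 2, seed = 13)
  expect_error(scmfdd_fit(inst$A, k = 2, mu = 0), "'mu'")
  expect_error(scmfdd_fit(inst$A, k = 2, lam = -1), "'lam'")
  expect_error(scmfdd_fit(inst$A, k = 4), "1 <= k < min")
  Wbad <- inst$Wd; Wbad[1, 2] <- Wbad[1, 2] + 1e-4
  expect_error(scmfdd_fit(inst$A, Wd = Wbad, k = 2), "symmetric")
  expect_error(scmfdd_fit(matrix(c(0, 2), 1, 2), k = 1), "0/1")
})

test_that("normalize_scores maps extremes to 0/1 and preserves order", {
  expect_equal(normalize_scores(c(2, 4, 6)), c(0, 0.5, 1))
  x <- rnorm(20)
  nx <- normalize_scores(x)
  expect_identical(order(nx), order(x))
  expect_equal(range(nx), c(0, 1))
  expect_warning(z <- normalize_scores(c(3, 3, 3)), "constant")
  expect_identical(z, c(0, 0, 0))
})
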