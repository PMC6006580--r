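# SCMFDD core: graph-constrained low-rank factorization of the binary
# drug-disease association matrix A ~ X Y^T, with L2 regularization (mu) and
# similarity smoothness penalties (lambda) on both factor sets, fitted by
# alternating exact Newton row updates (Gauss-Seidel sweeps).

#' Resolve the latent dimension from a fraction of min(n, m)
#'
#' The latent dimension is conventionally quoted as a percentage of
#' `k0 = min(n, m)`. Rounds half away from zero and clips the result into
#' `[1, min(n, m) - 1]`.
#'
#' @param k_fraction fraction in `(0, 1)`.
#' @param n,m matrix dimensions (drugs, diseases), both at least 2.
#' @return integer latent dimension.
#' @examples
#' resolve_k(0.45, 269, 598) # 121
#' @export
resolve_k <- function(k_fraction, n, m) {
  k0 <- min(n, m)
  if (k0 < 2) stop("need min(n, m) >= 2 to choose k < min(n, m)",
                   call. = FALSE)
  if (!is.numeric(k_fraction) || k_fraction <= 0 || k_fraction >= 1)
    stop("'k_fraction' must lie in (0, 1)", call. = FALSE)
  k <- round_half_up(k_fraction * k0)
  as.integer(min(max(k, 1), k0 - 1))
}

#' Random initialization of the factor pair
#'
#' Entries are i.i.d. Uniform(0, 1) scaled by `1/sqrt(k)`, so initial
#' reconstruction scores `x_i . y_j` are O(1). Deterministic given `seed`;
#' the caller's RNG state is untouched.
#'
#' @param n,m,k dimensions.
#' @param seed integer seed.
#' @return list with matrices `X` (n x k) and `Y` (m x k).
#' @export
init_factors <- function(n, m, k, seed = 1) {
  stopifnot(n >= 1, m >= 1, k >= 1)
  with_seed(seed, {
    X <- matrix(stats::runif(n * k), n, k) / sqrt(k)
    Y <- matrix(stats::runif(m * k), m, k) / sqrt(k)
    list(X = X, Y = Y)
  })
}

# row-sum + column-sum similarity weights with the self term removed;
# the self-similarity contribution cancels in the exact row gradient
sim_coefs <- function(W) {
  C <- W + t(W)
  diag(C) <- 0
  C
}

# sum_ij w_ij ||x_i - x_j||^2, vectorized
graph_penalty <- function(X, W) {
  if (is.null(W)) return(0)
  sq <- rowSums(X^2)
  sum((rowSums(W) + colSums(W)) * sq) - 2 * sum(X * (W %*% X))
}

#' SCMFDD objective function value
#'
#' `L = 1/2 sum_ij (a_ij - x_i y_j^T)^2 + mu/2 (||X||_F^2 + ||Y||_F^2)
#'    + lambda/2 sum_ij ||x_i - x_j||^2 w^d_ij
#'    + lambda/2 sum_ij ||y_i - y_j||^2 w^s_ij`
#'
#' The reconstruction sum runs over every cell, zeros included.
#'
#' @param A binary n x m association matrix.
#' @param X,Y factor matrices (n x k, m x k).
#' @param Wd,Ws drug (n x n) and disease (m x m) similarity matrices; `NULL`
#'   drops the corresponding penalty.
#' @param mu L2 regularization weight (> 0 for a well-posed fit).
#' @param lam similarity-constraint weight (>= 0).
#' @return scalar objective value.
#' @export
scmfdd_objective <- function(A, X, Y, Wd = NULL, Ws = NULL, mu, lam) {
  if (nrow(A) != nrow(X) || ncol(A) != nrow(Y) || ncol(X) != ncol(Y))
    stop("shape mismatch among A, X, Y", call. = FALSE)
  R <- A - tcrossprod(X, Y)
  0.5 * sum(R^2) + mu / 2 * (sum(X^2) + sum(Y^2)) +
    lam / 2 * (graph_penalty(X, Wd) + graph_penalty(Y, Ws))
}

#' Gradient of the objective with respect to one drug row
#'
#' `grad x_i = x_i (Y^T Y + mu I + lambda s_i I) - A(i,:) Y
#'            - lambda sum_j (w^d_ij + w^d_ji) x_j`,
#' with `s_i = sum_j (w^d_ij + w^d_ji)`. The `j = i` self-similarity terms
#' appear in both `s_i` and the weighted sum and cancel, so the value equals
#' the exact partial derivative of the objective.
#'
#' @inheritParams scmfdd_objective
#' @param i drug row index.
#' @return numeric length-k gradient vector.
#' @export
grad_x <- function(i, A, X, Y, Wd = NULL, mu, lam) {
  xi <- X[i, , drop = FALSE]
  g <- xi %*% crossprod(Y) + mu * xi - A[i, , drop = FALSE] %*% Y
  if (!is.null(Wd) && lam != 0) {
    ci <- Wd[i, ] + Wd[, i]
    g <- g + lam * sum(ci) * xi - lam * (ci %*% X)
  }
  as.numeric(g)
}

#' Gradient of the objective with respect to one disease row
#'
#' Mirror of [grad_x()] with `X^T X`, the j-th column of `A`, and the
#' disease similarity matrix.
#'
#' @inheritParams scmfdd_objective
#' @param j disease row index (column of `A`).
#' @return numeric length-k gradient vector.
#' @export
grad_y <- function(j, A, X, Y, Ws = NULL, mu, lam) {
  yj <- Y[j, , drop = FALSE]
  g <- yj %*% crossprod(X) + mu * yj - crossprod(A[, j, drop = FALSE], X)
  if (!is.null(Ws) && lam != 0) {
    cj <- Ws[j, ] + Ws[, j]
    g <- g + lam * sum(cj) * yj - lam * (cj %*% Y)
  }
  as.numeric(g)
}

#' Per-row Newton system matrix for a drug row
#'
#' The second derivative of the objective with respect to `x_i`:
#' `Y^T Y + (mu + lambda s_i) I` where `s_i` sums the off-diagonal
#' similarity weights `w^d_ij + w^d_ji` (the diagonal term cancels against
#' the weighted-sum side of the gradient).
#'
#' @inheritParams grad_x
#' @return k x k positive-definite matrix (for `mu > 0`).
#' @export
hessian_x <- function(i, Y, Wd = NULL, mu, lam) {
  s <- if (is.null(Wd)) 0 else sum(Wd[i, ]) + sum(Wd[, i]) - 2 * Wd[i, i]
  crossprod(Y) + diag(mu + lam * s, ncol(Y))
}

#' Per-row Newton system matrix for a disease row
#' @inheritParams grad_y
#' @param X drug factor matrix.
#' @return k x k positive-definite matrix (for `mu > 0`).
#' @export
hessian_y <- function(j, X, Ws = NULL, mu, lam) {
  s <- if (is.null(Ws)) 0 else sum(Ws[j, ]) + sum(Ws[, j]) - 2 * Ws[j, j]
  crossprod(X) + diag(mu + lam * s, ncol(X))
}

#' Exact Newton update of one drug row
#'
#' Solves the row stationarity condition
#' `x_i (Y^T Y + mu I + lambda s_i I) = A(i,:) Y + lambda sum_{j != i}
#' (w^d_ij + w^d_ji) x_j` for `x_i`, i.e. the exact minimizer of the
#' objective in that row with all other rows held fixed (one Newton step on
#' a quadratic is exact). With `lam = 0` this is the ridge closed form
#' `A(i,:) Y (Y^T Y + mu I)^{-1}`.
#'
#' @inheritParams grad_x
#' @return updated length-k row vector.
#' @export
update_x_row <- function(i, A, X, Y, Wd = NULL, mu, lam) {
  rhs <- A[i, , drop = FALSE] %*% Y
  s <- 0
  if (!is.null(Wd) && lam != 0) {
    ci <- Wd[i, ] + Wd[, i]
    ci[i] <- 0
    s <- sum(ci)
    rhs <- rhs + lam * (ci %*% X)
  }
  H <- crossprod(Y) + diag(mu + lam * s, ncol(Y))
  sol <- tryCatch(solve(H, t(rhs)),
                  error = function(e) stop(
                    "singular row system; 'mu' must be > 0", call. = FALSE))
  as.numeric(sol)
}

#' Exact Newton update of one disease row
#' @inheritParams grad_y
#' @return updated length-k row vector.
#' @export
update_y_row <- function(j, A, X, Y, Ws = NULL, mu, lam) {
  rhs <- crossprod(A[, j, drop = FALSE], X)
  s <- 0
  if (!is.null(Ws) && lam != 0) {
    cj <- Ws[j, ] + Ws[, j]
    cj[j] <- 0
    s <- sum(cj)
    rhs <- rhs + lam * (cj %*% Y)
  }
  H <- crossprod(X) + diag(mu + lam * s, ncol(X))
  sol <- tryCatch(solve(H, t(rhs)),
                  error = function(e) stop(
                    "singular row system; 'mu' must be > 0", call. = FALSE))
  as.numeric(sol)
}

#' Fit the similarity-constrained matrix factorization
#'
#' Alternates full passes over drug rows then disease rows, each row update
#' being the exact minimizer of the objective in that row (Gauss-Seidel:
#' freshly updated rows are used immediately). Exact row minimization makes
#' the objective trace non-increasing. Iteration stops when the relative
#' objective change drops below `tol` or after `max_sweeps` sweeps.
#'
#' Within each half-sweep the k x k Gram matrix of the fixed factor is
#' eigendecomposed once; every row then costs one k x k transform because
#' only the scalar diagonal shift `mu + lambda s_i` varies per row.
#'
#' @param A binary n x m association matrix (drugs x diseases); dimnames, if
#'   present, carry the IDs through to the result.
#' @param Wd,Ws optional drug / disease similarity matrices; must be
#'   symmetric within `1e-8`. `NULL` disables the corresponding constraint.
#' @param k explicit latent dimension; overrides `k_fraction`.
#' @param k_fraction latent dimension as a fraction of `min(n, m)`;
#'   default 0.45.
#' @param mu L2 weight, must be > 0; default 1 (2^0).
#' @param lam similarity-constraint weight, >= 0; default 4 (2^2).
#' @param max_sweeps sweep cap; default 200.
#' @param tol relative objective-change tolerance; default 1e-6.
#' @param seed seed for the random initialization.
#' @param verbose log the objective each sweep via `message()`.
#' @return object of class `scmfdd_fit`: factors `X`, `Y`, `objective_trace`
#'   (initial value followed by one value per sweep), `sweeps_run`,
#'   `converged`, the resolved hyperparameters, and the entity IDs.
#' @export
scmfdd_fit <- function(A, Wd = NULL, Ws = NULL, k = NULL, k_fraction = 0.45,
                       mu = 1, lam = 4, max_sweeps = 200, tol = 1e-6,
                       seed = 1, verbose = FALSE) {
  assert_binary_matrix(A, "A")
  n <- nrow(A); m <- ncol(A)
  if (mu <= 0) stop("'mu' must be > 0", call. = FALSE)
  if (lam < 0) stop("'lam' must be >= 0", call. = FALSE)
  if (!is.null(Wd)) {
    assert_symmetric(Wd, "Wd")
    if (nrow(Wd) != n) stop("Wd must be n x n", call. = FALSE)
  }
  if (!is.null(Ws)) {
    assert_symmetric(Ws, "Ws")
    if (nrow(Ws) != m) stop("Ws must be m x m", call. = FALSE)
  }
  k <- if (!is.null(k)) as.integer(k) else resolve_k(k_fraction, n, m)
  if (k < 1 || k >= min(n, m))
    stop("'k' must satisfy 1 <= k < min(n, m)", call. = FALSE)

  Cd <- if (!is.null(Wd) && lam > 0) sim_coefs(Wd)
  Cs <- if (!is.null(Ws) && lam > 0) sim_coefs(Ws)
  sd_ <- if (!is.null(Cd)) rowSums(Cd) else numeric(n)
  ss_ <- if (!is.null(Cs)) rowSums(Cs) else numeric(m)

  fac <- init_factors(n, m, k, seed)
  X <- fac$X; Y <- fac$Y
  obj <- function() scmfdd_objective(A, X, Y, Wd, Ws, mu, lam)
  trace <- obj()
  converged <- FALSE
  sweeps <- 0L

  for (t in seq_len(max_sweeps)) {
    # update all drug rows against fixed Y
    EY <- eigen(crossprod(Y), symmetric = TRUE)
    AY <- A %*% Y
    for (i in seq_len(n)) {
      rhs <- AY[i, ]
      if (!is.null(Cd)) rhs <- rhs + lam * as.numeric(Cd[i, ] %*% X)
      z <- as.numeric(crossprod(EY$vectors, rhs)) /
        (EY$values + mu + lam * sd_[i])
      X[i, ] <- as.numeric(EY$vectors %*% z)
    }
    # update all disease rows against the freshly updated X
    EX <- eigen(crossprod(X), symmetric = TRUE)
    AX <- crossprod(A, X)
    for (j in seq_len(m)) {
      rhs <- AX[j, ]
      if (!is.null(Cs)) rhs <- rhs + lam * as.numeric(Cs[j, ] %*% Y)
      z <- as.numeric(crossprod(EX$vectors, rhs)) /
        (EX$values + mu + lam * ss_[j])
      Y[j, ] <- as.numeric(EX$vectors %*% z)
    }
    L <- obj()
    if (!is.finite(L)) stop("objective diverged (non-finite value)",
                            call. = FALSE)
    trace <- c(trace, L)
    sweeps <- t
    if (verbose) message(sprintf("sweep %d: objective %.6g", t, L))
    prev <- trace[length(trace) - 1]
    if (abs(L - prev) / max(1, prev) < tol) {
      converged <- TRUE
      break
    }
  }

  structure(list(X = X, Y = Y,
                 drug_ids = rownames(A), disease_ids = colnames(A),
                 objective_trace = trace, sweeps_run = sweeps,
                 converged = converged,
                 k = k, mu = mu, lam = lam, seed = seed),
            class = "scmfdd_fit")
}

#' @export
print.scmfdd_fit <- function(x, ...) {
  cat(sprintf(
    "SCMFDD fit: %d drugs x %d diseases, k = %d (mu = %g, lambda = %g)\n",
    nrow(x$X), nrow(x$Y), x$k, x$mu, x$lam))
  cat(sprintf("  %d sweep(s), %sconverged, objective %.6g\n",
              x$sweeps_run, if (x$converged) "" else "NOT ",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Predicted association scores
#'
#' The score matrix `X Y^T`. Entries are unbounded ranking scores: larger
#' means a more plausible drug-disease association. They are not clipped or
#' rescaled; use [normalize_scores()] for presentation.
#'
#' @param object a fitted `scmfdd_fit`.
#' @param ... unused.
#' @return n x m numeric score matrix with the training IDs as dimnames.
#' @export
predict.scmfdd_fit <- function(object, ...) {
  S <- tcrossprod(object$X, object$Y)
  dimnames(S) <- list(object$drug_ids, object$disease_ids)
  S
}

#' Min-max normalization of prediction scores
#'
#' Affine rescaling `(score - min) / (max - min)` used when reporting ranked
#' candidate associations. Order-preserving; a constant input has no range
#' and maps to all zeros with a warning.
#'
#' @param scores numeric vector (or matrix, normalized over all entries).
#' @return rescaled object in `[0, 1]`.
#' @export
normalize_scores <- function(scores) {
  rng <- range(scores, finite = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant scores: min-max normalization returns zeros",
            call. = FALSE)
    scores[] <- 0
    return(scores)
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}
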