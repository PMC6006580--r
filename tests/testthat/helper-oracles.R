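# Independent brute-force references used across the suite. Each oracle
# re-derives its quantity by direct enumeration of the defining formula and
# shares no code path with the implementation it checks.

# term-by-term objective: explicit double loops over every summand
oracle_objective <- function(A, X, Y, Wd, Ws, mu, lam) {
  n <- nrow(A); m <- ncol(A)
  L <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    L <- L + 0.5 * (A[i, j] - sum(X[i, ] * Y[j, ]))^2
  for (i in seq_len(n)) L <- L + mu / 2 * sum(X[i, ]^2)
  for (j in seq_len(m)) L <- L + mu / 2 * sum(Y[j, ]^2)
  if (!is.null(Wd))
    for (i in seq_len(n)) for (j in seq_len(n))
      L <- L + lam / 2 * sum((X[i, ] - X[j, ])^2) * Wd[i, j]
  if (!is.null(Ws))
    for (i in seq_len(m)) for (j in seq_len(m))
      L <- L + lam / 2 * sum((Y[i, ] - Y[j, ])^2) * Ws[i, j]
  L
}

# central finite differences of the objective with respect to one factor row
fd_grad_row <- function(which_row, i, A, X, Y, Wd, Ws, mu, lam, h = 1e-6) {
  k <- ncol(X)
  g <- numeric(k)
  for (t in seq_len(k)) {
    bump <- function(delta) {
      Xp <- X; Yp <- Y
      if (which_row == "x") Xp[i, t] <- Xp[i, t] + delta
      else Yp[i, t] <- Yp[i, t] + delta
      scmfdd_objective(A, Xp, Yp, Wd, Ws, mu, lam)
    }
    g[t] <- (bump(h) - bump(-h)) / (2 * h)
  }
  g
}

# finite-difference Jacobian of a row gradient (the row Hessian)
fd_hessian_row <- function(which_row, i, A, X, Y, Wd, Ws, mu, lam,
                           h = 1e-6) {
  k <- ncol(X)
  H <- matrix(0, k, k)
  for (t in seq_len(k)) {
    gpm <- lapply(c(h, -h), function(delta) {
      Xp <- X; Yp <- Y
      if (which_row == "x") {
        Xp[i, t] <- Xp[i, t] + delta
        grad_x(i, A, Xp, Yp, Wd, mu, lam)
      } else {
        Yp[i, t] <- Yp[i, t] + delta
        grad_y(i, A, Xp, Yp, Ws, mu, lam)
      }
    })
    H[, t] <- (gpm[[1]] - gpm[[2]]) / (2 * h)
  }
  H
}

# random small fit instance with symmetric unit-diagonal similarities
rand_instance <- function(n, m, k, seed, density = 0.3) {
  set.seed(seed)
  A <- matrix(rbinom(n * m, 1, density), n, m)
  Wd <- matrix(runif(n * n), n, n); Wd <- (Wd + t(Wd)) / 2; diag(Wd) <- 1
  Ws <- matrix(runif(m * m), m, m); Ws <- (Ws + t(Ws)) / 2; diag(Ws) <- 1
  X <- matrix(runif(n * k), n, k)
  Y <- matrix(runif(m * k), m, k)
  list(A = A, Wd = Wd, Ws = Ws, X = X, Y = Y)
}

# direct recursive evaluation of the contribution / DV / S formulas,
# no memoization, no topological sort
oracle_contributions <- function(dag, delta) {
  children_of <- function(d) dag$edges$child[dag$edges$parent == d]
  rec <- function(d) {
    if (d %in% dag$terms) return(1)
    ch <- children_of(d)
    max(vapply(ch, function(x) delta * rec(x), numeric(1)))
  }
  stats::setNames(vapply(dag$nodes, rec, numeric(1)), dag$nodes)
}

oracle_semantic_similarity <- function(dag_a, dag_b, delta) {
  ca <- oracle_contributions(dag_a, delta)
  cb <- oracle_contributions(dag_b, delta)
  shared <- intersect(names(ca), names(cb))
  if (length(shared) == 0) return(0)
  (sum(ca[shared]) + sum(cb[shared])) / (sum(ca) + sum(cb))
}

# random disease DAG over a tiny shared vocabulary (small node counts)
rand_dag <- function(seed, depth = 3, branching = 2) {
  set.seed(seed)
  one <- function() paste(
    c("R", sample(branching, sample(depth, 1), replace = TRUE)),
    collapse = ".")
  mesh_dag(unique(replicate(sample(2, 1), one())))
}

# exhaustive-threshold AUPR: recount tp/fp at each distinct score by direct
# comparison, then the same anchored trapezoid convention as the package
oracle_aupr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  rec <- prec <- numeric(0)
  for (t in th) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    rec <- c(rec, tp / P)
    prec <- c(prec, tp / (tp + fp))
  }
  keep <- rec > 0
  rec <- rec[keep]; prec <- prec[keep]
  r <- c(0, rec); p <- c(prec[1], prec)
  sum(diff(r) * (p[-length(p)] + p[-1]) / 2)
}

# pairwise-enumeration AUC (Mann-Whitney by direct double loop)
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# exhaustive-threshold best-F metrics
oracle_max_f_metrics <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  best <- list(f = -1)
  for (t in th) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / P
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    if (f > best$f)
      best <- list(sn = rec, sp = (N - fp) / N,
                   acc = (tp + N - fp) / (P + N), f = f, threshold = t)
  }
  best
}

# plain L2-regularized alternating least squares (the lambda = 0 oracle),
# identical initialization, fixed sweep count
oracle_als <- function(A, k, mu, sweeps, seed) {
  fac <- init_factors(nrow(A), ncol(A), k, seed)
  X <- fac$X; Y <- fac$Y
  tr <- scmfdd_objective(A, X, Y, NULL, NULL, mu, 0)
  for (t in seq_len(sweeps)) {
    for (i in seq_len(nrow(A)))
      X[i, ] <- solve(crossprod(Y) + diag(mu, k),
                      as.numeric(crossprod(Y, A[i, ])))
    for (j in seq_len(ncol(A)))
      Y[j, ] <- solve(crossprod(X) + diag(mu, k),
                      as.numeric(crossprod(X, A[, j])))
    tr <- c(tr, scmfdd_objective(A, X, Y, NULL, NULL, mu, 0))
  }
  list(X = X, Y = Y, trace = tr)
}

# shared masking protocol for the recovery experiments: hide a random 20%
# of the known positives
mask_positives <- function(A, frac, seed) {
  pos <- which(A == 1)
  set.seed(seed)
  held <- sample(pos, round(frac * length(pos)))
  Atr <- A
  Atr[held] <- 0
  list(Atr = Atr, held = held, neg = which(A == 0))
}

heldout_aupr <- function(fit, masked) {
  S <- tcrossprod(fit$X, fit$Y)
  scores <- c(S[masked$held], S[masked$neg])
  labels <- c(rep(1, length(masked$held)), rep(0, length(masked$neg)))
  aupr(scores, labels)
}
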