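# Planted-structure fixtures: a low-rank binary association matrix plus
# similarity matrices that are informative about the planted factors, so the
# whole pipeline is testable without any external downloads.

cosine_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(M / nrm)
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  S
}

# symmetric uniform noise rescaled to [0, 1]
noise_matrix <- function(n) {
  U <- matrix(stats::runif(n * n), n, n)
  W <- (U + t(U)) / 2
  rng <- range(W)
  if (rng[1] == rng[2]) return(matrix(0.5, n, n))
  (W - rng[1]) / (rng[2] - rng[1])
}

#' Generate a planted low-rank drug-disease benchmark
#'
#' Draws nonnegative latent factors `X_true` (n x k_true) and `Y_true`
#' (m x k_true) with i.i.d. zero-inflated entries: each entry is active with
#' probability 1/2 and active loadings are Uniform(0.5, 1.5). Entities
#' sharing active factors form overlapping classes with comparable row
#' norms, so the planted associations are driven by factor alignment rather
#' than entity popularity and factor-derived similarities carry real
#' neighborhood information. The score matrix
#' `S = X_true Y_true^T` is thresholded at the quantile that yields the
#' requested richness (fraction of positive cells), giving exact density
#' control; `bernoulli = TRUE` instead samples each cell with probability
#' proportional to its score.
#'
#' Similarities are mixtures `W = alpha * cosine(factors) +
#' (1 - alpha) * noise` with symmetric uniform noise rescaled to `[0, 1]`
#' and the diagonal forced to 1. At `alpha = 1` the drug similarity equals
#' the cosine similarity of the planted drug factors exactly; at `alpha = 0`
#' it is pure noise.
#'
#' @param n,m drug and disease counts.
#' @param k_true planted rank, `1 <= k_true < min(n, m)`.
#' @param richness target fraction of positive cells in `(0, 1)`;
#'   default 0.1.
#' @param alpha similarity informativeness in `[0, 1]`; default 0.9.
#' @param seed generator seed; the dataset is fully determined by it.
#' @param bernoulli sample labels stochastically instead of quantile
#'   thresholding; achieved density must stay within 20% of `richness`.
#' @return object of class `scmfdd_synth`: `A`, `Wd`, `Ws`, `X_true`,
#'   `Y_true`, `positive_cells` and the generating parameters.
#' @export
synthetic_dataset <- function(n, m, k_true, richness = 0.1, alpha = 0.9,
                              seed = 1, bernoulli = FALSE) {
  stopifnot(n >= 2, m >= 2)
  if (k_true < 1 || k_true >= min(n, m))
    stop("'k_true' must satisfy 1 <= k_true < min(n, m)", call. = FALSE)
  if (richness <= 0 || richness >= 1)
    stop("'richness' must lie in (0, 1)", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]",
                                   call. = FALSE)
  npos <- round_half_up(richness * n * m)
  if (npos < 1 || npos >= n * m)
    stop("infeasible richness: no threshold yields ", npos,
         " positives in a ", n, " x ", m, " matrix", call. = FALSE)
  out <- with_seed(seed, {
    X <- matrix(stats::rbinom(n * k_true, 1, 0.5) *
                  stats::runif(n * k_true, 0.5, 1.5), n, k_true)
    Y <- matrix(stats::rbinom(m * k_true, 1, 0.5) *
                  stats::runif(m * k_true, 0.5, 1.5), m, k_true)
    S <- tcrossprod(X, Y)
    A <- matrix(0, n, m)
    if (bernoulli) {
      p <- pmin(1, S * (richness / mean(S)))
      A[] <- stats::rbinom(n * m, 1, p)
      if (abs(mean(A) - richness) > 0.2 * richness)
        stop("infeasible richness: achieved density ", signif(mean(A), 3),
             " deviates more than 20% from ", richness, call. = FALSE)
    } else {
      A[order(S, decreasing = TRUE)[seq_len(npos)]] <- 1
    }
    Wd <- alpha * cosine_rows(X) + (1 - alpha) * noise_matrix(n)
    Ws <- alpha * cosine_rows(Y) + (1 - alpha) * noise_matrix(m)
    diag(Wd) <- 1
    diag(Ws) <- 1
    list(A = A, Wd = Wd, Ws = Ws, X_true = X, Y_true = Y)
  })
  drug_ids <- sprintf("drug_%03d", seq_len(n))
  disease_ids <- sprintf("disease_%03d", seq_len(m))
  dimnames(out$A) <- list(drug_ids, disease_ids)
  dimnames(out$Wd) <- list(drug_ids, drug_ids)
  dimnames(out$Ws) <- list(disease_ids, disease_ids)
  structure(c(out,
              list(positive_cells = which(out$A == 1, arr.ind = TRUE),
                   n = n, m = m, k_true = k_true, richness = richness,
                   alpha = alpha, seed = seed, bernoulli = bernoulli)),
            class = "scmfdd_synth")
}

#' @export
print.scmfdd_synth <- function(x, ...) {
  cat(sprintf(
    "synthetic benchmark: %d drugs x %d diseases, planted rank %d\n",
    x$n, x$m, x$k_true))
  cat(sprintf("  %d positives (richness %.3f, requested %.3f), alpha %.2f, seed %d\n",
              nrow(x$positive_cells), mean(x$A), x$richness, x$alpha, x$seed))
  invisible(x)
}

#' Filter sparse entities by minimum association count
#'
#' Removes drugs with fewer than `min_count` associations and diseases with
#' fewer than `min_count` associations, repeating until no further removal
#' is needed: dropping one side can push entities of the other side below
#' the threshold, so the filter iterates to a fixed point.
#'
#' @param A binary association matrix with dimnames.
#' @param min_count minimum associations per surviving drug and disease.
#' @return the stable submatrix (possibly with zero rows/columns); attribute
#'   `iterations` records how many passes were needed.
#' @export
richness_filter <- function(A, min_count) {
  assert_binary_matrix(A, "A")
  if (min_count < 1) stop("'min_count' must be >= 1", call. = FALSE)
  iter <- 0L
  repeat {
    keep_r <- rowSums(A) >= min_count
    A2 <- A[keep_r, , drop = FALSE]
    keep_c <- colSums(A2) >= min_count
    A2 <- A2[, keep_c, drop = FALSE]
    iter <- iter + 1L
    if (all(keep_r) && all(keep_c)) break
    A <- A2
  }
  attr(A2, "iterations") <- iter
  A2
}

#' Synthetic MeSH-like disease hierarchies
#'
#' Random tree numbers over a small synthetic vocabulary: all paths descend
#' from a single root category, so every pair of diseases shares at least
#' the root and pairwise semantic similarity is nondegenerate. Each disease
#' gets one full-depth path and, with probability 0.3, a second one.
#'
#' @param depth levels below nothing, i.e. tree-number component count
#'   (>= 1).
#' @param branching children per level of the synthetic vocabulary.
#' @param disease_count number of diseases.
#' @param seed generator seed.
#' @return named list of [mesh_dag()] objects (`disease_01`, ...).
#' @export
mesh_fixture <- function(depth = 3, branching = 3, disease_count = 10,
                         seed = 1) {
  stopifnot(depth >= 1, branching >= 1, disease_count >= 1)
  with_seed(seed, {
    path <- function() {
      parts <- c("C01",
                 sprintf("%03d", sample.int(branching, depth - 1,
                                            replace = TRUE)))
      paste(parts[seq_len(depth)], collapse = ".")
    }
    dags <- lapply(seq_len(disease_count), function(i) {
      tn <- path()
      if (stats::runif(1) < 0.3) tn <- unique(c(tn, path()))
      mesh_dag(tn, disease_id = sprintf("disease_%02d", i))
    })
    names(dags) <- sprintf("disease_%02d", seq_len(disease_count))
    dags
  })
}
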