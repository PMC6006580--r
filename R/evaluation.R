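# Five-fold cross-validation over known associations and ranking metrics.
# Positives are the held-out associations; negatives are every cell that is
# 0 in the full association matrix. AUPR is the primary metric because
# unobserved pairs vastly outnumber known associations.

#' Randomly partition the known associations into folds
#'
#' Splits the positive cells of `A` into `fold_count` near-equal subsets
#' (sizes differ by at most one); each subset is held out once during
#' cross-validation.
#'
#' @param A binary association matrix.
#' @param fold_count number of folds; default 5.
#' @param seed partition seed.
#' @return object of class `fold_plan`: parallel vectors `drug`, `disease`,
#'   `fold` over the positive cells, plus `fold_count` and `seed`.
#' @export
make_folds <- function(A, fold_count = 5, seed = 1) {
  assert_binary_matrix(A, "A")
  pos <- which(A == 1, arr.ind = TRUE)
  P <- nrow(pos)
  if (P < fold_count)
    stop("need at least as many positives as folds", call. = FALSE)
  lab <- with_seed(seed, sample(rep(seq_len(fold_count), length.out = P)))
  structure(list(drug = pos[, 1], disease = pos[, 2], fold = lab,
                 fold_count = fold_count, seed = seed),
            class = "fold_plan")
}

#' Mask one fold's positives out of the training matrix
#'
#' Returns a copy of `A` with the held-out fold's positive cells set to 0;
#' everything else is unchanged. The model never sees the test associations.
#'
#' @param A binary association matrix.
#' @param plan a [make_folds()] plan for `A`.
#' @param held_fold fold label to hold out.
#' @return masked binary matrix of the same shape.
#' @export
mask_training <- function(A, plan, held_fold) {
  stopifnot(inherits(plan, "fold_plan"))
  if (!held_fold %in% seq_len(plan$fold_count))
    stop("'held_fold' out of range", call. = FALSE)
  sel <- plan$fold == held_fold
  A[cbind(plan$drug[sel], plan$disease[sel])] <- 0
  A
}

# tie-grouped confusion counts at every distinct score threshold
# (predict positive when score >= threshold), descending thresholds
threshold_counts <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("degenerate evaluation: need both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)
  data.frame(threshold = s[keep],
             tp = cumsum(l == 1)[keep],
             fp = cumsum(l == 0)[keep],
             P = P, N = N)
}

#' Precision-recall curve points
#'
#' Precision and recall at every distinct score threshold (ties grouped),
#' thresholds descending so recall is non-decreasing down the rows.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 truth labels.
#' @return data frame with `threshold`, `tp`, `fp`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels) {
  ct <- threshold_counts(scores, labels)
  data.frame(threshold = ct$threshold, tp = ct$tp, fp = ct$fp,
             recall = ct$tp / ct$P,
             precision = ct$tp / (ct$tp + ct$fp))
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration of precision over recall across the tie-grouped
#' threshold points with positive recall, anchored at recall 0 with the
#' precision of the earliest threshold that retrieves a positive. A perfect
#' ranking scores 1; the worst ranking of a single positive among `N`
#' instances scores `1/N`.
#'
#' @inheritParams pr_curve
#' @return scalar in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  pc <- pr_curve(scores, labels)
  pc <- pc[pc$recall > 0, , drop = FALSE]
  r <- c(0, pc$recall)
  p <- c(pc$precision[1], pc$precision)
  sum(diff(r) * (p[-length(p)] + p[-1]) / 2)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, ties counted one half.
#'
#' @inheritParams pr_curve
#' @return scalar in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("degenerate evaluation: need both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Thresholded classification metrics: SN, SP, ACC, F
#'
#' Binarizes the scores at a cutoff and reports sensitivity (recall),
#' specificity, accuracy and F-measure. The default `"max_f"` rule scans all
#' distinct score thresholds and keeps the one maximizing F (ties: highest
#' threshold); `"fixed"` uses the supplied `threshold`; `"top_n"` predicts
#' the `n_top` best-scoring instances positive.
#'
#' @inheritParams pr_curve
#' @param rule cutoff rule: `"max_f"`, `"fixed"` or `"top_n"`.
#' @param threshold cutoff for `rule = "fixed"` (score >= threshold is
#'   predicted positive).
#' @param n_top count for `rule = "top_n"`.
#' @return list with `sn`, `sp`, `acc`, `f`, the `threshold` used and the
#'   `rule` name.
#' @export
binary_metrics <- function(scores, labels,
                           rule = c("max_f", "fixed", "top_n"),
                           threshold = NULL, n_top = NULL) {
  rule <- match.arg(rule)
  ct <- threshold_counts(scores, labels)
  at <- function(tp, fp) {
    fn <- ct$P[1] - tp; tn <- ct$N[1] - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / ct$P[1]
    list(sn = rec, sp = tn / ct$N[1],
         acc = (tp + tn) / (ct$P[1] + ct$N[1]),
         f = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
  idx <- switch(rule,
    max_f = {
      fs <- mapply(function(tp, fp) at(tp, fp)$f, ct$tp, ct$fp)
      which.max(fs) # first max = highest threshold on ties
    },
    fixed = {
      if (is.null(threshold)) stop("'threshold' required for rule 'fixed'",
                                   call. = FALSE)
      w <- which(ct$threshold >= threshold)
      if (length(w) == 0) NA_integer_ else max(w)
    },
    top_n = {
      if (is.null(n_top)) stop("'n_top' required for rule 'top_n'",
                               call. = FALSE)
      which.min(abs(ct$tp + ct$fp - n_top))
    })
  if (is.na(idx)) { # fixed threshold above every score: nothing predicted
    m <- at(0, 0)
    thr <- threshold
  } else {
    m <- at(ct$tp[idx], ct$fp[idx])
    thr <- ct$threshold[idx]
  }
  c(m, list(threshold = thr, rule = rule))
}

#' Cross-validate SCMFDD on a known-association matrix
#'
#' For each fold: the fold's positives are masked out of `A`, a model is
#' fitted on the rest, and the fitted scores are evaluated on the held-out
#' positives against all cells that are 0 in the full matrix (training
#' positives are excluded from the evaluated set). Reports per-fold and mean
#' AUPR, AUC, SN, SP, ACC and F.
#'
#' @param A binary association matrix.
#' @param Wd,Ws optional similarity matrices, passed to [scmfdd_fit()].
#' @param fold_count number of folds; default 5.
#' @param seed seed for the fold partition and (offset per fold) the fits.
#' @param plan optional pre-built [make_folds()] plan; overrides
#'   `fold_count`/`seed` for the partition.
#' @param threshold_rule cutoff rule for the thresholded metrics; see
#'   [binary_metrics()].
#' @param ... hyperparameters forwarded to [scmfdd_fit()] (`k`, `k_fraction`,
#'   `mu`, `lam`, `max_sweeps`, `tol`, `verbose`).
#' @return object of class `scmfdd_cv`: `per_fold` data frame, `mean` named
#'   vector, the `plan`, and the threshold rule.
#' @export
cross_validate <- function(A, Wd = NULL, Ws = NULL, fold_count = 5, seed = 1,
                           plan = NULL, threshold_rule = "max_f", ...) {
  assert_binary_matrix(A, "A")
  plan <- plan %||% make_folds(A, fold_count, seed)
  neg <- which(A == 0)
  rows <- vector("list", plan$fold_count)
  for (f in seq_len(plan$fold_count)) {
    Atr <- mask_training(A, plan, f)
    lost_r <- sum(rowSums(Atr) == 0 & rowSums(A) > 0)
    lost_c <- sum(colSums(Atr) == 0 & colSums(A) > 0)
    if (lost_r > 0 || lost_c > 0)
      message(sprintf(
        "fold %d: %d drug(s) and %d disease(s) lost all training positives",
        f, lost_r, lost_c))
    fit <- scmfdd_fit(Atr, Wd, Ws, seed = seed + f, ...)
    S <- tcrossprod(fit$X, fit$Y)
    sel <- plan$fold == f
    held <- cbind(plan$drug[sel], plan$disease[sel])
    scores <- c(S[held], S[neg])
    labels <- c(rep(1, nrow(held)), rep(0, length(neg)))
    bm <- binary_metrics(scores, labels, rule = threshold_rule)
    rows[[f]] <- data.frame(fold = f,
                            aupr = aupr(scores, labels),
                            auc = auroc(scores, labels),
                            sn = bm$sn, sp = bm$sp, acc = bm$acc, f = bm$f)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, -1]),
                 plan = plan, threshold_rule = threshold_rule),
            class = "scmfdd_cv")
}

#' @export
print.scmfdd_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (threshold rule: %s)\n",
              x$plan$fold_count, x$threshold_rule))
  print(round(x$per_fold, 4), row.names = FALSE)
  cat("mean:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Grid search over the SCMFDD hyperparameters
#'
#' Runs [cross_validate()] for every combination of the supplied
#' `k_fraction`, `mu` and `lam` values, reusing one fold plan so that all
#' combinations see identical train/test splits. The canonical grids are
#' `mu, lam` over powers of two from `2^-3` to `2^3` and `k_fraction` from
#' 5% to 50% in 5% steps; any subset can be supplied.
#'
#' @param A binary association matrix.
#' @param Wd,Ws optional similarity matrices.
#' @param k_fractions,mus,lams numeric grids (non-empty).
#' @param fold_count,seed fold-plan settings.
#' @param ... further arguments forwarded to [cross_validate()]
#'   (`max_sweeps`, `tol`, `threshold_rule`, ...).
#' @return data frame with one row per combination (`k_fraction`, `mu`,
#'   `lam`, mean metrics) and a logical `best` column flagging the single
#'   highest-AUPR row.
#' @export
grid_search <- function(A, Wd = NULL, Ws = NULL,
                        k_fractions = c(0.05, 0.25, 0.45),
                        mus = 2^c(-3, 0, 3), lams = 2^c(-3, 0, 3),
                        fold_count = 5, seed = 1, ...) {
  if (length(k_fractions) == 0 || length(mus) == 0 || length(lams) == 0)
    stop("all three grids must be non-empty", call. = FALSE)
  plan <- make_folds(A, fold_count, seed)
  combos <- expand.grid(k_fraction = k_fractions, mu = mus, lam = lams,
                        KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(r) {
    cv <- cross_validate(A, Wd, Ws, plan = plan, seed = seed,
                         k_fraction = combos$k_fraction[r],
                         mu = combos$mu[r], lam = combos$lam[r], ...)
    cbind(combos[r, , drop = FALSE], as.data.frame(as.list(cv$mean)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$best <- FALSE
  out$best[which.max(out$aupr)] <- TRUE
  out
}
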