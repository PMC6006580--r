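# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the caller's RNG state so library calls never perturb user
#' simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# 0/1 matrix check used by several entry points
assert_binary_matrix <- function(A, what = "A") {
  if (!is.matrix(A) || !is.numeric(A))
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  if (any(!is.finite(A)) || any(A != 0 & A != 1))
    stop(sprintf("'%s' must contain only 0/1 entries", what), call. = FALSE)
  invisible(A)
}

assert_symmetric <- function(W, what = "W", tol = 1e-8) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop(sprintf("'%s' must be a square matrix", what), call. = FALSE)
  if (max(abs(W - t(W))) > tol)
    stop(sprintf("'%s' is not symmetric within tolerance %g", what, tol),
         call. = FALSE)
  invisible(W)
}

# round-half-away-from-zero for positive x (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)
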