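#' Jaccard similarity of two binary feature vectors
#'
#' Drugs are described by presence/absence descriptor vectors (for example the
#' 881 PubChem substructure keys). The Jaccard score is the number of
#' descriptors both drugs carry divided by the number of descriptors carried
#' by either drug.
#'
#' When both vectors are all-zero the union is empty and the ratio is
#' undefined; the score is defined as 0, so featureless drugs contribute no
#' similarity constraint.
#'
#' @param p,q numeric 0/1 vectors of equal length.
#' @return a score in `[0, 1]`.
#' @examples
#' jaccard(c(1, 1, 0), c(1, 0, 1)) # 1/3
#' @export
jaccard <- function(p, q) {
  if (length(p) != length(q))
    stop("feature vectors must have equal length", call. = FALSE)
  if (any(p != 0 & p != 1) || any(q != 0 & q != 1))
    stop("feature vectors must be binary (0/1)", call. = FALSE)
  u <- sum(p == 1 | q == 1)
  if (u == 0) return(0)
  sum(p == 1 & q == 1) / u
}

#' Pairwise drug-drug Jaccard similarity matrix
#'
#' Vectorized Jaccard similarity over all row pairs of a binary feature
#' table. Rows are drugs, columns are descriptors.
#'
#' Drugs with no set bits get similarity 0 against everything, including
#' themselves (their diagonal entry is 0); a warning reports them.
#'
#' @param bits numeric 0/1 matrix, drugs in rows; row names are drug IDs.
#' @return symmetric similarity matrix with the input row order preserved.
#' @export
pairwise_jaccard <- function(bits) {
  if (!is.matrix(bits) || nrow(bits) < 1)
    stop("'bits' must be a non-empty 0/1 matrix", call. = FALSE)
  assert_binary_matrix(bits, "bits")
  inter <- tcrossprod(bits)
  rs <- rowSums(bits)
  uni <- outer(rs, rs, `+`) - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  if (any(rs == 0)) {
    empty <- if (!is.null(rownames(bits))) {
      paste(rownames(bits)[rs == 0], collapse = ", ")
    } else {
      paste(which(rs == 0), collapse = ", ")
    }
    warning("all-zero feature vectors (similarity set to 0, including ",
            "self-similarity): ", empty, call. = FALSE)
  }
  dimnames(S) <- list(rownames(bits), rownames(bits))
  S
}

#' Build a disease MeSH ancestor DAG from tree numbers
#'
#' MeSH assigns each disease one or more dot-delimited tree numbers (for
#' example `"C04.557.337"`); every prefix of a tree number denotes an
#' ancestor term. The DAG contains all prefixes of all given tree numbers as
#' nodes, with an edge from each prefix to its one-component extension, and
#' the full tree numbers mark the disease's own term(s). Multiple tree
#' numbers are merged by node union, so shared prefixes appear once.
#'
#' Nodes are keyed by the tree-number prefix string. Users holding the MeSH
#' vocabulary can supply `term_map` (named character vector, prefix ->
#' descriptor ID) to collapse prefixes of the same descriptor into one node.
#'
#' @param tree_numbers character vector of dot-delimited hierarchy codes.
#' @param disease_id optional identifier stored with the DAG.
#' @param term_map optional named character vector mapping tree-number
#'   prefixes to term identifiers.
#' @return an object of class `mesh_dag` with elements `disease_id`, `nodes`,
#'   `edges` (data frame of parent/child pairs) and `terms` (the disease's
#'   own term node(s)).
#' @export
mesh_dag <- function(tree_numbers, disease_id = NULL, term_map = NULL) {
  tree_numbers <- unique(trimws(as.character(tree_numbers)))
  tree_numbers <- tree_numbers[nzchar(tree_numbers)]
  if (length(tree_numbers) == 0)
    stop("no tree numbers given: disease lacks MeSH descriptor data",
         call. = FALSE)
  key <- function(x) {
    if (is.null(term_map)) return(x)
    ifelse(x %in% names(term_map), unname(term_map[x]), x)
  }
  nodes <- character()
  parent <- character()
  child <- character()
  terms <- character()
  for (tn in tree_numbers) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1]]
    prefixes <- vapply(seq_along(parts), function(i)
      paste(parts[seq_len(i)], collapse = "."), character(1))
    ids <- key(prefixes)
    nodes <- union(nodes, ids)
    if (length(ids) > 1) {
      parent <- c(parent, ids[-length(ids)])
      child <- c(child, ids[-1])
    }
    terms <- union(terms, ids[length(ids)])
  }
  edges <- unique(data.frame(parent = parent, child = child,
                             stringsAsFactors = FALSE))
  edges <- edges[edges$parent != edges$child, , drop = FALSE]
  structure(list(disease_id = disease_id, nodes = nodes, edges = edges,
                 terms = terms),
            class = "mesh_dag")
}

#' Semantic contribution of each DAG node
#'
#' The disease's own term contributes 1. Every ancestor contributes
#' `delta` times the largest contribution among its children inside the DAG,
#' so a term's contribution decays with its distance from the disease. With
#' the default `delta = 0.5` a chain ancestor at depth `h` contributes
#' `0.5^h`.
#'
#' @param dag a [mesh_dag()] object.
#' @param delta semantic contribution (decay) factor in `(0, 1)`; default 0.5.
#' @return named numeric vector of contributions over `dag$nodes`, all in
#'   `(0, 1]`.
#' @export
dag_contributions <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "mesh_dag"))
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1)
    stop("'delta' must be a single value in (0, 1)", call. = FALSE)
  kids <- split(dag$edges$child, dag$edges$parent)
  contrib <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  state <- stats::setNames(integer(length(dag$nodes)), dag$nodes) # 0 new 1 open 2 done
  visit <- function(d) {
    if (state[[d]] == 2L) return(contrib[[d]])
    if (state[[d]] == 1L)
      stop("cycle detected in DAG at node '", d, "'", call. = FALSE)
    state[[d]] <<- 1L
    val <- if (d %in% dag$terms) {
      1
    } else {
      ch <- kids[[d]]
      if (is.null(ch) || length(ch) == 0)
        stop("node '", d, "' is neither the disease term nor an ancestor ",
             "of it (no children in DAG)", call. = FALSE)
      max(vapply(ch, function(x) delta * visit(x), numeric(1)))
    }
    contrib[[d]] <<- val
    state[[d]] <<- 2L
    val
  }
  for (d in dag$nodes) visit(d)
  contrib
}

#' Semantic value of a disease
#'
#' The sum of the semantic contributions of all nodes in the disease's
#' ancestor DAG; it normalizes pairwise semantic similarity.
#'
#' @param contrib named contribution vector from [dag_contributions()].
#' @return positive scalar.
#' @export
semantic_value <- function(contrib) {
  if (length(contrib) == 0) stop("empty contribution map", call. = FALSE)
  sum(contrib)
}

#' Semantic similarity between two diseases
#'
#' Terms shared by the two ancestor DAGs contribute the sum of their
#' contributions in each DAG; the total is normalized by the two semantic
#' values:
#' `S(A,B) = sum_{d in N(A) & N(B)} (C_A(d) + C_B(d)) / (DV(A) + DV(B))`.
#' Identical DAGs score exactly 1; disjoint DAGs score 0.
#'
#' @param dag_a,dag_b [mesh_dag()] objects.
#' @param delta decay factor, see [dag_contributions()].
#' @return a score in `[0, 1]`.
#' @export
semantic_similarity <- function(dag_a, dag_b, delta = 0.5) {
  ca <- dag_contributions(dag_a, delta)
  cb <- dag_contributions(dag_b, delta)
  shared <- intersect(names(ca), names(cb))
  if (length(shared) == 0) return(0)
  (sum(ca[shared]) + sum(cb[shared])) / (sum(ca) + sum(cb))
}

#' Pairwise disease-disease semantic similarity matrix
#'
#' Computes each disease's contribution map once and evaluates all pairs.
#'
#' @param dags list of [mesh_dag()] objects; names (or the DAGs'
#'   `disease_id`s) become row/column names.
#' @param delta decay factor; default 0.5.
#' @return symmetric unit-diagonal similarity matrix in disease input order.
#' @export
pairwise_semantic <- function(dags, delta = 0.5) {
  if (length(dags) == 0) stop("no DAGs given", call. = FALSE)
  contribs <- lapply(dags, dag_contributions, delta = delta)
  dv <- vapply(contribs, sum, numeric(1))
  n <- length(dags)
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        shared <- intersect(names(contribs[[i]]), names(contribs[[j]]))
        s <- if (length(shared) == 0) 0 else
          (sum(contribs[[i]][shared]) + sum(contribs[[j]][shared])) /
            (dv[i] + dv[j])
        S[i, j] <- S[j, i] <- s
      }
    }
  }
  ids <- names(dags)
  if (is.null(ids))
    ids <- vapply(dags, function(d) d$disease_id %||% NA_character_,
                  character(1))
  if (!anyNA(ids)) dimnames(S) <- list(ids, ids)
  S
}

#' Validate a user-supplied similarity matrix
#'
#' For precomputed drug or disease similarity matrices (as shipped with
#' published benchmark datasets). Requires a square matrix symmetric within
#' `tol` (small asymmetries are averaged away with a warning); negative
#' entries are clipped to 0 and entries above 1 to 1, each with a warning.
#'
#' @param W numeric square matrix.
#' @param tol symmetry tolerance; default `1e-8`.
#' @return validated symmetric matrix with entries in `[0, 1]`.
#' @export
as_similarity_matrix <- function(W, tol = 1e-8) {
  assert_symmetric(W, "W", tol)
  if (max(abs(W - t(W))) > 0) {
    warning("similarity matrix symmetrized by averaging (asymmetry <= ",
            format(tol), ")", call. = FALSE)
    W <- (W + t(W)) / 2
  }
  if (any(W < 0)) {
    warning(sum(W < 0), " negative similarity entries clipped to 0",
            call. = FALSE)
    W[W < 0] <- 0
  }
  if (any(W > 1)) {
    warning(sum(W > 1), " similarity entries above 1 clipped to 1",
            call. = FALSE)
    W[W > 1] <- 1
  }
  W
}
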