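# Delimited-text readers and writers. Tab-separated is the primary dialect
# (disease names may contain commas); `sep` switches to comma where needed.
# Matrix writers emit full double precision so write -> read round-trips are
# lossless; the CLI's ranked-pair report rounds to 6 significant digits.

fmt_num <- function(x) sprintf("%.15g", x)

#' Read a drug-disease association matrix
#'
#' Accepts either a two-column edge list (drug ID, disease ID; optional
#' `drug<sep>disease` header) or a dense labeled 0/1 matrix whose header
#' starts with an empty or `"id"` cell followed by disease IDs. The format
#' is auto-detected. Edge-list entity order is first appearance; duplicate
#' edges collapse to a single 1 with a warning.
#'
#' @param path input file.
#' @param sep field separator; default tab.
#' @return binary matrix with drug row names and disease column names.
#' @export
read_associations <- function(path, sep = "\t") {
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  first <- as.character(raw[1, ])
  dense <- ncol(raw) > 1 &&
    (first[1] %in% c("", "id")) &&
    all(unlist(raw[-1, -1]) %in% c("0", "1"))
  if (dense) {
    diseases <- first[-1]
    drugs <- raw[-1, 1]
    A <- matrix(as.numeric(as.matrix(raw[-1, -1])), nrow = length(drugs),
                dimnames = list(drugs, diseases))
    assert_binary_matrix(A, basename(path))
    return(A)
  }
  if (ncol(raw) != 2)
    stop("unknown association format in '", path,
         "': need a 2-column edge list or a dense labeled 0/1 matrix",
         call. = FALSE)
  if (identical(tolower(first), c("drug", "disease"))) raw <- raw[-1, ]
  drugs <- unique(raw[[1]])
  diseases <- unique(raw[[2]])
  A <- matrix(0, length(drugs), length(diseases),
              dimnames = list(drugs, diseases))
  if (anyDuplicated(raw))
    warning("duplicate edges collapsed to single associations",
            call. = FALSE)
  A[cbind(match(raw[[1]], drugs), match(raw[[2]], diseases))] <- 1
  A
}

#' Write an association matrix
#'
#' @param A binary matrix with dimnames.
#' @param path output file.
#' @param format `"edge"` (two-column list of the positive cells, with
#'   header) or `"dense"` (labeled 0/1 matrix).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_associations <- function(A, path, format = c("edge", "dense"),
                               sep = "\t") {
  format <- match.arg(format)
  assert_binary_matrix(A, "A")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("'A' needs row and column names to be written", call. = FALSE)
  if (format == "edge") {
    pos <- which(A == 1, arr.ind = TRUE)
    ord <- order(pos[, 1], pos[, 2])
    df <- data.frame(drug = rownames(A)[pos[ord, 1]],
                     disease = colnames(A)[pos[ord, 2]])
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    write_labeled_matrix(A, path, sep)
  }
  invisible(path)
}

write_labeled_matrix <- function(M, path, sep = "\t") {
  header <- paste(c("id", colnames(M)), collapse = sep)
  body <- vapply(seq_len(nrow(M)), function(i)
    paste(c(rownames(M)[i], fmt_num(M[i, ])), collapse = sep), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

read_labeled_matrix <- function(path, sep = "\t") {
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  cols <- as.character(raw[1, -1])
  rows <- raw[-1, 1]
  M <- matrix(as.numeric(as.matrix(raw[-1, -1])), nrow = length(rows),
              dimnames = list(rows, cols))
  M
}

#' Read a similarity matrix
#'
#' Dense labeled matrix whose row and column identifiers must match (same
#' set, same order). Validated through [as_similarity_matrix()]: small
#' asymmetries are averaged away and out-of-range entries clipped, each
#' with a warning.
#'
#' @param path input file.
#' @param sep field separator.
#' @return validated symmetric similarity matrix.
#' @export
read_similarity_matrix <- function(path, sep = "\t") {
  M <- read_labeled_matrix(path, sep)
  if (!identical(rownames(M), colnames(M)))
    stop("row/column identifiers disagree in '", path, "'", call. = FALSE)
  as_similarity_matrix(M)
}

#' Write a similarity (or any labeled numeric) matrix
#' @param W matrix with dimnames.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(W, path, sep = "\t") {
  if (is.null(rownames(W)) || is.null(colnames(W)))
    stop("'W' needs row and column names to be written", call. = FALSE)
  write_labeled_matrix(W, path, sep)
}

#' Read a binary drug feature table
#'
#' Header row of descriptor IDs (leading `id` cell), first column drug IDs,
#' cells 0/1.
#'
#' @param path input file.
#' @param sep field separator.
#' @return 0/1 matrix, drugs in rows.
#' @export
read_feature_table <- function(path, sep = "\t") {
  M <- read_labeled_matrix(path, sep)
  assert_binary_matrix(M, basename(path))
  M
}

#' Read disease MeSH tree numbers
#'
#' Two columns: disease ID, tree number; repeated disease IDs accumulate
#' multiple tree numbers. Disease order is first appearance.
#'
#' @param path input file.
#' @param sep field separator.
#' @return named list mapping disease ID to a character vector of tree
#'   numbers.
#' @export
read_mesh <- function(path, sep = "\t") {
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 2)
    stop("MeSH file must have two columns (disease ID, tree number)",
         call. = FALSE)
  if (identical(tolower(as.character(raw[1, ])), c("disease", "tree_number")))
    raw <- raw[-1, ]
  ids <- unique(raw[[1]])
  out <- lapply(ids, function(d) unique(raw[[2]][raw[[1]] == d]))
  names(out) <- ids
  out
}

#' Align similarity matrices to an association matrix
#'
#' Re-indexes `Wd` and `Ws` to the drug and disease order of `A`. Every drug
#' of `A` must appear in `Wd` and every disease in `Ws`; missing entities
#' raise an error naming them. Extra entities in the similarity matrices are
#' dropped.
#'
#' @param A association matrix with dimnames.
#' @param Wd,Ws similarity matrices with matching dimnames (either may be
#'   `NULL` to skip).
#' @return list with `A`, `Wd`, `Ws` consistently ordered.
#' @export
align_entities <- function(A, Wd = NULL, Ws = NULL) {
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("'A' needs row and column names for alignment", call. = FALSE)
  realign <- function(W, ids, what) {
    if (is.null(W)) return(NULL)
    missing <- setdiff(ids, rownames(W))
    if (length(missing) > 0)
      stop("similarity matrix '", what, "' is missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    W[ids, ids, drop = FALSE]
  }
  list(A = A,
       Wd = realign(Wd, rownames(A), "Wd"),
       Ws = realign(Ws, colnames(A), "Ws"))
}
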