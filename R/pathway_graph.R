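# Pathway label-dependence graph: co-occurrence counts, conditional
# probabilities, binarization, column re-weighting, word-vector node init.

#' Count pairwise pathway co-occurrence
#'
#' @param labels n x C binary matrix (or a \code{compound_table}).
#' @return A list with \code{U} (C x C symmetric co-occurrence counts, zero
#'   diagonal) and \code{N} (per-label occurrence totals).
#' @export
count_cooccurrence <- function(labels) {
  if (inherits(labels, "compound_table")) labels <- labels$labels
  labels <- as.matrix(labels)
  U <- crossprod(labels)     # U_ij = number of compounds with both i and j
  N <- diag(U)
  diag(U) <- 0
  list(U = unname(U), N = unname(N))
}

#' Conditional label probabilities from co-occurrence counts
#'
#' \code{P[i, j]} is the probability of label j occurring given label i,
#' \code{U[i, j] / N[i]}. Rows for labels absent from the data (N = 0) are
#' zeroed: a degenerate-fold guard. P is generally asymmetric.
#'
#' @param stats Output of \code{\link{count_cooccurrence}}.
#' @return C x C matrix with entries in [0, 1].
#' @export
conditional_probability <- function(stats) {
  N <- stats$N
  denom <- ifelse(N > 0, N, 1)
  P <- stats$U / denom
  P[N == 0, ] <- 0
  P
}

#' Binarize a conditional-probability matrix
#'
#' Hard-thresholds \code{P} at \code{tau} to drop weak, noisy label edges;
#' the diagonal is forced to zero (self-dependence enters later through the
#' identity term of the propagation operator).
#'
#' @param P C x C conditional-probability matrix.
#' @param tau Threshold in (0, 1).
#' @return C x C binary matrix.
#' @export
binarize_dependence <- function(P, tau) {
  stopifnot(tau > 0, tau < 1)
  M <- (P >= tau) * 1
  diag(M) <- 0
  M
}

#' Re-weight a binary dependence matrix by its column sums
#'
#' Each entry is divided by its column total, so every nonzero column of the
#' result sums to one; all-zero columns stay zero.
#'
#' @param M C x C binary matrix.
#' @return C x C re-weighted matrix.
#' @export
reweight_dependence <- function(M) {
  cs <- colSums(M)
  denom <- ifelse(cs > 0, cs, 1)
  sweep(M, 2, denom, "/")
}

#' Build the full pathway dependence graph from training labels
#'
#' Runs the chain co-occurrence counts -> conditional probabilities ->
#' binarization at \code{tau} -> column re-weighting, and attaches node
#' features.
#'
#' @param labels n x C binary training-label matrix (or a
#'   \code{compound_table}). Use training folds only to avoid leakage.
#' @param tau Binarization threshold.
#' @param node_features C x r node feature matrix Q (see
#'   \code{\link{init_pathway_features}}).
#' @return A list with \code{U}, \code{N}, \code{P}, \code{M}, \code{M_w},
#'   \code{tau} and \code{Q}.
#' @export
build_dependence_graph <- function(labels, tau, node_features) {
  stats <- count_cooccurrence(labels)
  P <- conditional_probability(stats)
  M <- binarize_dependence(P, tau)
  M_w <- reweight_dependence(M)
  stopifnot(nrow(node_features) == nrow(M))
  list(U = stats$U, N = stats$N, P = P, M = M, M_w = M_w,
       tau = tau, Q = node_features)
}

#' Read a word-vector file in GloVe text format
#'
#' One token per line followed by whitespace-separated floats; all vectors
#' must share one width.
#'
#' @param path Path to the vector file.
#' @return Numeric matrix with tokens as row names.
#' @export
read_word_vectors <- function(path) {
  if (!file.exists(path)) stop("word-vector file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: empty word-vector file")
  parts <- strsplit(trimws(lines), "\\s+")
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L || widths[1] < 2L)
    stop("format error: inconsistent vector widths in word-vector file")
  tokens <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(x) {
    v <- suppressWarnings(as.numeric(x[-1]))
    if (anyNA(v)) stop("format error: non-numeric entry in word-vector file")
    v
  }, numeric(widths[1] - 1L)))
  rownames(vecs) <- tokens
  vecs
}

tokenize_name <- function(name) {
  x <- tolower(name)
  x <- gsub("[[:punct:]]", " ", x)
  strsplit(trimws(x), "\\s+")[[1]]
}

#' Initialize pathway node features from pre-trained word vectors
#'
#' Each pathway name is lowercased, stripped of punctuation and split on
#' whitespace; its feature vector is the unweighted mean of its in-vocabulary
#' token vectors. Out-of-vocabulary tokens are skipped; a name with no
#' in-vocabulary token gets a reproducible standard-normal vector. With
#' \code{random = TRUE} (the random-initialization ablation) every row is a
#' seeded standard-normal vector and the vector file is ignored.
#'
#' @param pathway_names Character vector of C pathway names.
#' @param wordvec_file Path to a GloVe text-format vector file, or a matrix
#'   as returned by \code{\link{read_word_vectors}}.
#' @param r Feature width; defaults to the vector file's width.
#' @param seed Seed for random rows.
#' @param random If TRUE, ignore the vectors and use Gaussian rows.
#' @return C x r matrix Q with pathway names as row names.
#' @export
init_pathway_features <- function(pathway_names, wordvec_file = NULL,
                                  r = NULL, seed = 1L, random = FALSE) {
  C <- length(pathway_names)
  if (random) {
    if (is.null(r)) stop("r must be given for random initialization")
    Q <- with_local_seed(seed, matrix(stats::rnorm(C * r), C, r))
    rownames(Q) <- pathway_names
    return(Q)
  }
  vecs <- if (is.matrix(wordvec_file)) wordvec_file
          else read_word_vectors(wordvec_file)
  if (is.null(r)) r <- ncol(vecs)
  if (r != ncol(vecs))
    stop(sprintf("word vectors have width %d, expected r = %d",
                 ncol(vecs), r))
  Q <- matrix(0, C, r, dimnames = list(pathway_names, NULL))
  for (i in seq_len(C)) {
    toks <- tokenize_name(pathway_names[i])
    hit <- toks[toks %in% rownames(vecs)]
    if (length(hit)) {
      Q[i, ] <- colMeans(vecs[hit, , drop = FALSE])
    } else {
      Q[i, ] <- with_local_seed(seed + i, stats::rnorm(r))
    }
  }
  Q
}

#' Path to the bundled miniature word-vector fixture
#'
#' A small GloVe text-format file (10-d vectors over a few dozen
#' metabolism-vocabulary tokens) used by tests and examples. The vectors are
#' synthetic, not trained embeddings.
#'
#' @return File path.
#' @export
mini_word_vectors_path <- function() {
  system.file("extdata", "mini_word_vectors.txt", package = "mlpathway",
              mustWork = TRUE)
}
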