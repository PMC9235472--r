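# Compound encoder: multi-head graph attention, graph convolution,
# max/mean readout.

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
relu <- function(x) pmax(x, 0)

# Row-wise softmax restricted to masked entries; unmasked entries are 0.
masked_row_softmax <- function(scores, mask) {
  out <- matrix(0, nrow(scores), ncol(scores))
  for (i in seq_len(nrow(scores))) {
    idx <- which(mask[i, ] > 0)
    v <- scores[i, idx]
    e <- exp(v - max(v))
    out[i, idx] <- e / sum(e)
  }
  out
}

#' Multi-head graph-attention layer over a molecular graph
#'
#' Each head k linearly maps atom features through its weight matrix, scores
#' every neighbor pair (i, j) with
#' \code{LeakyReLU(a_k' [W_k h_i || W_k h_j])}, normalizes scores by a
#' softmax over atom i's neighborhood (neighbors plus self), aggregates
#' neighbor features with those attention coefficients, and applies ReLU.
#' Head outputs are concatenated.
#'
#' @param graph A \code{\link{smiles_to_graph}} molecule graph.
#' @param params A \code{gat_params} list (\code{W}: per-head input x
#'   head-dim matrices; \code{a}: per-head score vectors of length twice the
#'   head dim; \code{K}; \code{leaky_slope}).
#' @return A list with \code{features} (N x K*s matrix) and \code{attn}
#'   (an \code{attention_map}: per-head N x N coefficient matrices, zero
#'   off-neighborhood; rows sum to one over each neighborhood).
#' @export
gat_layer <- function(graph, params) {
  fwd <- gat_forward(graph$atom_features,
                     graph$adjacency + diag(nrow(graph$adjacency)), params)
  list(features = fwd$out,
       attn = structure(list(alpha = fwd$alpha, mask = fwd$mask,
                             n_atoms = graph$n_atoms),
                        class = "attention_map"))
}

# Core forward pass; mask = A + I. Returns intermediates for backprop.
gat_forward <- function(X, mask, params) {
  N <- nrow(X); K <- params$K; s <- ncol(params$W[[1]])
  out <- matrix(0, N, K * s)
  alpha <- vector("list", K); H <- vector("list", K)
  E <- vector("list", K); Mpre <- vector("list", K)
  for (k in seq_len(K)) {
    Hk <- X %*% params$W[[k]]                   # N x s
    a1 <- params$a[[k]][seq_len(s)]
    a2 <- params$a[[k]][s + seq_len(s)]
    f <- drop(Hk %*% a1); g <- drop(Hk %*% a2)
    Ek <- outer(f, rep(1, N)) + outer(rep(1, N), g)
    Lk <- leaky_relu(Ek, params$leaky_slope)
    Ak <- masked_row_softmax(Lk, mask)
    Mk <- Ak %*% Hk
    out[, (k - 1) * s + seq_len(s)] <- relu(Mk)
    alpha[[k]] <- Ak; H[[k]] <- Hk; E[[k]] <- Ek; Mpre[[k]] <- Mk
  }
  list(out = out, alpha = alpha, H = H, E = E, Mpre = Mpre, mask = mask)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes \code{D^(-1/2) (A + I) D^(-1/2)} where D is the degree matrix
#' of A + I: the propagation operator of the compound graph convolution.
#'
#' @param A N x N symmetric binary adjacency matrix.
#' @return N x N normalized operator.
#' @export
norm_adjacency <- function(A) {
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' Graph-convolution layer on atom features
#'
#' \code{ReLU(D^(-1/2) (A + I) D^(-1/2) H W)}: symmetric-normalized
#' neighborhood aggregation followed by a learnable linear map and ReLU.
#'
#' @param features N x w input atom-feature matrix.
#' @param adjacency N x N symmetric binary adjacency.
#' @param params A \code{gcn_params} list with weight matrix \code{W_A}.
#' @return N x ncol(W_A) matrix.
#' @export
gcn_layer <- function(features, adjacency, params) {
  S <- norm_adjacency(adjacency)
  relu(S %*% features %*% params$W_A)
}

#' Max/mean readout of atom features into a compound embedding
#'
#' Concatenates the columnwise maximum and the columnwise mean, giving a
#' permutation-invariant embedding of length twice the atom-feature width.
#'
#' @param atom_features N x t matrix.
#' @return Numeric vector of length 2t.
#' @export
readout <- function(atom_features) {
  m <- as.matrix(atom_features)
  c(apply(m, 2, max), colMeans(m))
}

#' Encode one compound into an embedding vector
#'
#' Runs the full compound encoder: graph attention, graph convolution, then
#' the max/mean readout; the attention map is retained for interpretation.
#'
#' @param graph A molecule graph.
#' @param gat GAT parameters.
#' @param gcn GCN parameters.
#' @return A list with \code{embedding} (length 2 * ncol(W_A)) and
#'   \code{attn} (the \code{attention_map}).
#' @export
encode_compound <- function(graph, gat, gcn) {
  g <- gat_layer(graph, gat)
  hc <- gcn_layer(g$features, graph$adjacency, gcn)
  list(embedding = readout(hc), attn = g$attn)
}
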