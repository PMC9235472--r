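# Pathway encoder: two graph-convolution layers over the label-dependence
# graph with row-normalized propagation.

# Row-normalized propagation operator D_x^{-1} M_x with M_x = alpha*M_w + I.
pathway_propagation <- function(M_w, alpha) {
  C <- nrow(M_w)
  Mx <- alpha * M_w + diag(C)
  Mx / rowSums(Mx)
}

#' One graph-convolution layer over the pathway dependence graph
#'
#' Computes \code{LeakyReLU(D_x^(-1) M_x H W)} with
#' \code{M_x = alpha * M_w + I_C} and D_x the diagonal of M_x's row sums.
#' The propagation operator is row-stochastic for every alpha in [0, 1], so
#' each pathway's update is a convex combination of itself and the labels it
#' depends on, weighted by the trade-off coefficient alpha.
#'
#' @param H C x w input node-feature matrix.
#' @param M_w Re-weighted dependence matrix (see
#'   \code{\link{reweight_dependence}}).
#' @param W w x w' weight matrix.
#' @param alpha Trade-off coefficient in [0, 1].
#' @param slope LeakyReLU negative slope (default 0.01).
#' @return C x w' matrix.
#' @export
pathway_gcn_layer <- function(H, M_w, W, alpha, slope = 0.01) {
  Pr <- pathway_propagation(M_w, alpha)
  leaky_relu(Pr %*% H %*% W, slope)
}

#' Encode all pathways into an embedding matrix
#'
#' Stacks two \code{\link{pathway_gcn_layer}} passes over the dependence
#' graph, mapping the C x r node-feature matrix Q to the C x B pathway
#' embedding matrix O used by the dot-product predictor.
#'
#' @param Q C x r initial node features (word-vector means).
#' @param M_w Re-weighted dependence matrix.
#' @param params Pathway parameters: \code{W0}, \code{W1}, \code{alpha},
#'   \code{leaky_slope}.
#' @return C x B matrix O.
#' @export
encode_pathways <- function(Q, M_w, params) {
  H1 <- pathway_gcn_layer(Q, M_w, params$W0, params$alpha,
                          params$leaky_slope)
  pathway_gcn_layer(H1, M_w, params$W1, params$alpha, params$leaky_slope)
}
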