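# Model / training configuration.

#' Training and architecture configuration
#'
#' Defaults reproduce the reference architecture: a 10-head GAT whose heads
#' each output 78 features (780 concatenated), a GCN keeping width 780, a
#' 1560-d max/mean compound embedding, a 1560-1500-1024 adapter, 300-d
#' word-vector pathway features and two 1024-d pathway GCN layers; Adam at
#' learning rate 5e-4, 200 epochs, batch size 256, dependence threshold
#' tau = 0.5 and propagation trade-off alpha = 0.3.
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param tau Dependence-graph binarization threshold in (0, 1).
#' @param alpha Label-propagation trade-off coefficient in [0, 1].
#' @param heads Number of attention heads K.
#' @param gat_head_dim Output width s of each attention head.
#' @param gcn_dim Output width of the compound GCN layer (default K * s).
#' @param adapter_hidden Hidden width of the adapter network.
#' @param pathway_feature_dim Width r of the pathway node features.
#' @param pathway_hidden Width of the first pathway GCN layer.
#' @param pathway_out Width B of the pathway embeddings (must match the
#'   adapter output; forced to 2 * gcn_dim under the no-adapter ablation).
#' @param attention_slope LeakyReLU slope of the attention scores.
#' @param pathway_slope LeakyReLU slope of the pathway GCN activation.
#' @param decision_threshold Probability threshold for positive calls.
#' @param ablation One of \code{"none"}, \code{"no_pathway_encoder"},
#'   \code{"no_adapter"}, \code{"random_label_init"}.
#' @param seed Integer seed controlling initialization and batching.
#' @return A \code{train_config} list.
#' @export
train_config <- function(epochs = 200L, batch_size = 256L,
                         learning_rate = 5e-4, tau = 0.5, alpha = 0.3,
                         heads = 10L, gat_head_dim = 78L, gcn_dim = NULL,
                         adapter_hidden = 1500L,
                         pathway_feature_dim = 300L,
                         pathway_hidden = 1024L, pathway_out = 1024L,
                         attention_slope = 0.2, pathway_slope = 0.01,
                         decision_threshold = 0.5,
                         ablation = c("none", "no_pathway_encoder",
                                      "no_adapter", "random_label_init"),
                         seed = 1L) {
  ablation <- match.arg(ablation)
  if (is.null(gcn_dim)) gcn_dim <- heads * gat_head_dim
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            tau > 0, tau < 1, alpha >= 0, alpha <= 1, heads >= 1,
            gat_head_dim >= 1, decision_threshold > 0,
            decision_threshold < 1)
  if (ablation == "no_adapter") pathway_out <- 2L * gcn_dim
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, tau = tau, alpha = alpha,
    heads = as.integer(heads), gat_head_dim = as.integer(gat_head_dim),
    gcn_dim = as.integer(gcn_dim),
    adapter_hidden = as.integer(adapter_hidden),
    pathway_feature_dim = as.integer(pathway_feature_dim),
    pathway_hidden = as.integer(pathway_hidden),
    pathway_out = as.integer(pathway_out),
    attention_slope = attention_slope, pathway_slope = pathway_slope,
    decision_threshold = decision_threshold,
    ablation = ablation, seed = as.integer(seed)
  ), class = "train_config")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize all learnable model parameters
#'
#' @param config A \code{\link{train_config}}.
#' @param n_labels Number of pathway classes C.
#' @return A \code{model_state} list holding GAT, compound-GCN, pathway-GCN
#'   and adapter parameters (plus a free pathway-embedding matrix under the
#'   no-pathway-encoder ablation).
#' @export
init_model <- function(config, n_labels) {
  q <- atom_feature_width()
  s <- config$gat_head_dim; K <- config$heads
  G <- config$gcn_dim; B <- config$pathway_out
  with_local_seed(config$seed, {
    gat <- list(
      W = lapply(seq_len(K), function(k) glorot(q, s)),
      a = lapply(seq_len(K), function(k) stats::runif(2 * s, -0.1, 0.1)),
      K = K, leaky_slope = config$attention_slope)
    class(gat) <- "gat_params"
    gcn <- list(W_A = glorot(K * s, G))
    class(gcn) <- "gcn_params"
    adapter <- if (config$ablation == "no_adapter") NULL else list(
      W1 = glorot(2 * G, config$adapter_hidden),
      b1 = numeric(config$adapter_hidden),
      W2 = glorot(config$adapter_hidden, B),
      b2 = numeric(B))
    pathway <- if (config$ablation == "no_pathway_encoder") NULL else list(
      W0 = glorot(config$pathway_feature_dim, config$pathway_hidden),
      W1 = glorot(config$pathway_hidden, B),
      alpha = config$alpha, leaky_slope = config$pathway_slope)
    O_free <- if (config$ablation == "no_pathway_encoder")
      glorot(n_labels, B) else NULL
    structure(list(gat = gat, gcn = gcn, adapter = adapter,
                   pathway = pathway, O_free = O_free,
                   config = config, n_labels = as.integer(n_labels)),
              class = "model_state")
  })
}
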