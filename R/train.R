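# End-to-end training: forward/backward passes, Adam, cross-validation,
# ablations, grid search.

lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# Per-compound constants reused across epochs.
prepare_graph_cache <- function(table) {
  lapply(seq_along(table$ids), function(i) {
    g <- smiles_to_graph(table$smiles[i])
    list(graph = g,
         X = g$atom_features,
         mask = g$adjacency + diag(g$n_atoms),
         S = norm_adjacency(g$adjacency))
  })
}

# Forward pass for one compound, keeping intermediates for backprop.
forward_compound <- function(entry, state, O) {
  cfg <- state$config
  gf <- gat_forward(entry$X, entry$mask, state$gat)
  P1 <- entry$S %*% gf$out
  pre <- P1 %*% state$gcn$W_A
  HC <- relu(pre)
  G <- ncol(HC); N <- nrow(HC)
  imax <- apply(HC, 2, which.max)
  z <- c(HC[cbind(imax, seq_len(G))], colMeans(HC))
  if (is.null(state$adapter)) {
    zt <- z; upre <- NULL; u <- NULL
  } else {
    upre <- drop(z %*% state$adapter$W1) + state$adapter$b1
    u <- relu(upre)
    zt <- drop(u %*% state$adapter$W2) + state$adapter$b2
  }
  logits <- drop(O %*% zt)
  list(gf = gf, P1 = P1, pre = pre, HC = HC, imax = imax, z = z,
       upre = upre, u = u, zt = zt, logits = logits, N = N, G = G)
}

# Backward pass for one compound; accumulates into the gradient env.
backward_compound <- function(entry, fw, gy, state, gr) {
  cfg <- state$config
  gr$dO <- gr$dO + outer(gy, fw$zt)
  dzt <- drop(crossprod(gr$O, gy))
  if (is.null(state$adapter)) {
    dz <- dzt
  } else {
    ad <- state$adapter
    gr$adapter.W2 <- gr$adapter.W2 + outer(fw$u, dzt)
    gr$adapter.b2 <- gr$adapter.b2 + dzt
    du <- drop(ad$W2 %*% dzt) * (fw$upre > 0)
    gr$adapter.W1 <- gr$adapter.W1 + outer(fw$z, du)
    gr$adapter.b1 <- gr$adapter.b1 + du
    dz <- drop(ad$W1 %*% du)
  }
  G <- fw$G; N <- fw$N
  dmax <- dz[seq_len(G)]; dmean <- dz[G + seq_len(G)]
  dHC <- outer(rep(1 / N, N), dmean)
  dHC[cbind(fw$imax, seq_len(G))] <- dHC[cbind(fw$imax, seq_len(G))] + dmax
  dpre <- dHC * (fw$pre > 0)
  gr$gcn.W_A <- gr$gcn.W_A + crossprod(fw$P1, dpre)
  dHA <- entry$S %*% tcrossprod(dpre, state$gcn$W_A)
  s <- ncol(state$gat$W[[1]]); slope <- state$gat$leaky_slope
  for (k in seq_len(state$gat$K)) {
    ck <- (k - 1) * s + seq_len(s)
    Ak <- fw$gf$alpha[[k]]; Hk <- fw$gf$H[[k]]; Ek <- fw$gf$E[[k]]
    dM <- dHA[, ck, drop = FALSE] * (fw$gf$Mpre[[k]] > 0)
    dAk <- tcrossprod(dM, Hk)
    dHk <- crossprod(Ak, dM)
    rs <- rowSums(Ak * dAk)
    dL <- Ak * (dAk - rs)
    dE <- dL * lrelu_grad(Ek, slope)
    df <- rowSums(dE); dg <- colSums(dE)
    a1 <- state$gat$a[[k]][seq_len(s)]
    a2 <- state$gat$a[[k]][s + seq_len(s)]
    dHk <- dHk + outer(df, a1) + outer(dg, a2)
    gr$gat.a[[k]] <- gr$gat.a[[k]] +
      c(drop(crossprod(Hk, df)), drop(crossprod(Hk, dg)))
    gr$gat.W[[k]] <- gr$gat.W[[k]] + crossprod(entry$X, dHk)
  }
  invisible(NULL)
}

# Pathway-encoder forward keeping intermediates.
forward_pathways <- function(state, dep) {
  pw <- state$pathway
  Pr <- pathway_propagation(dep$M_w, pw$alpha)
  PQ <- Pr %*% dep$Q
  pre1 <- PQ %*% pw$W0
  H1 <- leaky_relu(pre1, pw$leaky_slope)
  PH1 <- Pr %*% H1
  pre2 <- PH1 %*% pw$W1
  O <- leaky_relu(pre2, pw$leaky_slope)
  list(Pr = Pr, PQ = PQ, pre1 = pre1, H1 = H1, PH1 = PH1, pre2 = pre2,
       O = O)
}

backward_pathways <- function(state, pf, dO, gr) {
  pw <- state$pathway
  dpre2 <- dO * lrelu_grad(pf$pre2, pw$leaky_slope)
  gr$pathway.W1 <- gr$pathway.W1 + crossprod(pf$PH1, dpre2)
  dH1 <- crossprod(pf$Pr, tcrossprod(dpre2, pw$W1))
  dpre1 <- dH1 * lrelu_grad(pf$pre1, pw$leaky_slope)
  gr$pathway.W0 <- gr$pathway.W0 + crossprod(pf$PQ, dpre1)
  invisible(NULL)
}

fresh_gradients <- function(state, C) {
  gr <- new.env(parent = emptyenv())
  gr$dO <- matrix(0, C, state$config$pathway_out)
  gr$gat.W <- lapply(state$gat$W, function(w) array(0, dim(w)))
  gr$gat.a <- lapply(state$gat$a, function(a) numeric(length(a)))
  gr$gcn.W_A <- array(0, dim(state$gcn$W_A))
  if (!is.null(state$adapter)) {
    gr$adapter.W1 <- array(0, dim(state$adapter$W1))
    gr$adapter.b1 <- numeric(length(state$adapter$b1))
    gr$adapter.W2 <- array(0, dim(state$adapter$W2))
    gr$adapter.b2 <- numeric(length(state$adapter$b2))
  }
  if (!is.null(state$pathway)) {
    gr$pathway.W0 <- array(0, dim(state$pathway$W0))
    gr$pathway.W1 <- array(0, dim(state$pathway$W1))
  }
  gr
}

# Flatten learnable parameters to a named list (for Adam bookkeeping).
collect_params <- function(state) {
  p <- list()
  for (k in seq_along(state$gat$W)) {
    p[[paste0("gat.W.", k)]] <- state$gat$W[[k]]
    p[[paste0("gat.a.", k)]] <- state$gat$a[[k]]
  }
  p$gcn.W_A <- state$gcn$W_A
  if (!is.null(state$adapter)) {
    p$adapter.W1 <- state$adapter$W1; p$adapter.b1 <- state$adapter$b1
    p$adapter.W2 <- state$adapter$W2; p$adapter.b2 <- state$adapter$b2
  }
  if (!is.null(state$pathway)) {
    p$pathway.W0 <- state$pathway$W0; p$pathway.W1 <- state$pathway$W1
  }
  if (!is.null(state$O_free)) p$O_free <- state$O_free
  p
}

restore_params <- function(state, p) {
  for (k in seq_along(state$gat$W)) {
    state$gat$W[[k]] <- p[[paste0("gat.W.", k)]]
    state$gat$a[[k]] <- p[[paste0("gat.a.", k)]]
  }
  state$gcn$W_A <- p$gcn.W_A
  if (!is.null(state$adapter)) {
    state$adapter$W1 <- p$adapter.W1; state$adapter$b1 <- p$adapter.b1
    state$adapter$W2 <- p$adapter.W2; state$adapter$b2 <- p$adapter.b2
  }
  if (!is.null(state$pathway)) {
    state$pathway$W0 <- p$pathway.W0; state$pathway$W1 <- p$pathway.W1
  }
  if (!is.null(state$O_free)) state$O_free <- p$O_free
  state
}

collect_gradients <- function(state, gr) {
  g <- list()
  for (k in seq_along(state$gat$W)) {
    g[[paste0("gat.W.", k)]] <- gr$gat.W[[k]]
    g[[paste0("gat.a.", k)]] <- gr$gat.a[[k]]
  }
  g$gcn.W_A <- gr$gcn.W_A
  if (!is.null(state$adapter)) {
    g$adapter.W1 <- gr$adapter.W1; g$adapter.b1 <- gr$adapter.b1
    g$adapter.W2 <- gr$adapter.W2; g$adapter.b2 <- gr$adapter.b2
  }
  if (!is.null(state$pathway)) {
    g$pathway.W0 <- gr$pathway.W0; g$pathway.W1 <- gr$pathway.W1
  }
  if (!is.null(state$O_free)) g$O_free <- gr$dO
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

resolve_node_features <- function(pathway_names, config, word_vectors) {
  if (config$ablation == "random_label_init") {
    return(init_pathway_features(pathway_names, r = config$pathway_feature_dim,
                                 seed = config$seed, random = TRUE))
  }
  if (is.null(word_vectors)) word_vectors <- mini_word_vectors_path()
  vecs <- if (is.matrix(word_vectors)) word_vectors
          else read_word_vectors(word_vectors)
  init_pathway_features(pathway_names, vecs, seed = config$seed)
}

#' Train the model on one table of compounds
#'
#' Builds the pathway dependence graph from the training records only,
#' initializes all parameters from the configuration seed, and minimizes the
#' multi-label cross-entropy by minibatch Adam. Under the
#' \code{no_pathway_encoder} ablation the pathway embedding matrix is a free
#' learnable matrix; under \code{no_adapter} the compound embedding feeds
#' the dot-product scorer directly; under \code{random_label_init} the
#' pathway node features are seeded Gaussian vectors instead of word-vector
#' means.
#'
#' @param table Training \code{compound_table} (SMILES must be valid; run
#'   \code{\link{filter_valid_structures}} first if unsure).
#' @param config A \code{\link{train_config}}.
#' @param word_vectors Path to a GloVe text-format file or a vector matrix;
#'   defaults to the bundled miniature fixture file.
#' @param graph_cache Optional precomputed graph cache (internal reuse).
#' @param verbose Print the per-epoch training loss.
#' @return A trained \code{model_state}; carries \code{dependence},
#'   \code{pathway_names}, the per-epoch \code{loss_trajectory} and the
#'   final pathway embedding matrix \code{O}.
#' @export
train_fold <- function(table, config, word_vectors = NULL,
                       graph_cache = NULL, verbose = FALSE) {
  stopifnot(inherits(table, "compound_table"))
  if (!length(table$ids)) stop("empty training set")
  C <- ncol(table$labels)
  if (is.null(graph_cache)) graph_cache <- prepare_graph_cache(table)
  Q <- resolve_node_features(table$pathway_names, config, word_vectors)
  if (config$ablation != "random_label_init" &&
      config$pathway_feature_dim != ncol(Q)) {
    config$pathway_feature_dim <- ncol(Q)
  }
  dep <- build_dependence_graph(table$labels, config$tau, Q)
  state <- init_model(config, C)
  state$dependence <- dep
  state$pathway_names <- table$pathway_names

  Y <- table$labels
  n <- nrow(Y)
  params <- collect_params(state)
  opt <- adam_init(params)
  losses <- numeric(config$epochs)

  O0 <- if (is.null(state$pathway)) state$O_free
        else forward_pathways(state, dep)$O
  initial_loss <- mean(vapply(seq_len(n), function(i) {
    multilabel_loss(forward_compound(graph_cache[[i]], state, O0)$logits,
                    Y[i, ])
  }, numeric(1)))

  with_local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      starts <- seq(1L, n, by = config$batch_size)
      for (b in starts) {
        idx <- ord[b:min(b + config$batch_size - 1L, n)]
        gr <- fresh_gradients(state, C)
        pf <- NULL
        if (is.null(state$pathway)) {
          O <- state$O_free
        } else {
          pf <- forward_pathways(state, dep)
          O <- pf$O
        }
        gr$O <- O
        batch_loss <- 0
        for (i in idx) {
          fw <- forward_compound(graph_cache[[i]], state, O)
          y <- Y[i, ]
          batch_loss <- batch_loss + multilabel_loss(fw$logits, y)
          gy <- multilabel_loss_grad(fw$logits, y) / length(idx)
          backward_compound(graph_cache[[i]], fw, gy, state, gr)
        }
        if (!is.null(state$pathway)) backward_pathways(state, pf, gr$dO, gr)
        grads <- collect_gradients(state, gr)
        upd <- adam_step(params, grads, opt, config$learning_rate)
        params <- upd$params; opt <- upd$opt
        state <- restore_params(state, params)
        epoch_loss <- epoch_loss + batch_loss
      }
      losses[epoch] <- epoch_loss / n
      if (verbose) message(sprintf("epoch %3d  loss %.5f", epoch,
                                   losses[epoch]))
    }
  })
  state$initial_loss <- initial_loss
  state$loss_trajectory <- losses
  state$O <- if (is.null(state$pathway)) state$O_free
             else forward_pathways(state, dep)$O
  state
}

#' Score compounds with a trained model
#'
#' @param state Trained \code{model_state}.
#' @param table A \code{compound_table} (or a list of molecule graphs).
#' @param keep_attention Also return per-compound attention maps.
#' @return A list with \code{logits} (n x C), \code{probabilities},
#'   \code{decisions}, and optionally \code{attention}.
#' @export
predict_pathways <- function(state, table, keep_attention = FALSE) {
  graphs <- if (inherits(table, "compound_table")) {
    lapply(table$smiles, smiles_to_graph)
  } else table
  C <- state$n_labels
  O <- state$O
  logits <- matrix(0, length(graphs), C)
  attn <- if (keep_attention) vector("list", length(graphs)) else NULL
  for (i in seq_along(graphs)) {
    enc <- encode_compound(graphs[[i]], state$gat, state$gcn)
    zt <- if (is.null(state$adapter)) enc$embedding
          else adapt(enc$embedding, state$adapter)
    logits[i, ] <- score_pathways(O, zt)
    if (keep_attention) attn[[i]] <- enc$attn
  }
  colnames(logits) <- state$pathway_names
  out <- list(logits = logits,
              probabilities = stats::plogis(logits),
              decisions = decide(logits, state$config$decision_threshold))
  if (keep_attention) out$attention <- attn
  out
}

#' Evaluate a trained model on held-out compounds
#'
#' @param state Trained \code{model_state}.
#' @param table Held-out \code{compound_table} with the same label set.
#' @param zero_based_coverage Use the 0-based coverage convention.
#' @return Named list of the eight multi-label metrics.
#' @export
evaluate_model <- function(state, table, zero_based_coverage = FALSE) {
  stopifnot(ncol(table$labels) == state$n_labels)
  pred <- predict_pathways(state, table)
  multilabel_metrics(table$labels, pred$logits, pred$decisions,
                     zero_based_coverage = zero_based_coverage)
}

#' k-fold cross-validation
#'
#' Trains k models, each on k-1 folds with the dependence graph rebuilt
#' from that training split only (no leakage from held-out compounds), and
#' evaluates on the held-out fold.
#'
#' @param table A \code{compound_table}.
#' @param config A \code{\link{train_config}}.
#' @param k Number of folds (default 10).
#' @param word_vectors Word-vector source (see \code{\link{train_fold}}).
#' @param verbose Print per-fold progress.
#' @return A \code{metrics_report}: per-fold metric data frame plus
#'   \code{mean} and \code{sd} per metric.
#' @export
cross_validate <- function(table, config, k = 10L, word_vectors = NULL,
                           verbose = FALSE) {
  split <- make_cv_split(table, k, config$seed)
  cache <- prepare_graph_cache(table)
  metric_names <- c("accuracy", "precision", "recall", "f1",
                    "hamming_loss", "ranking_loss", "coverage", "one_error")
  per_fold <- matrix(NA_real_, k, length(metric_names),
                     dimnames = list(NULL, metric_names))
  for (fold in seq_len(k) - 1L) {
    tr <- which(split$fold != fold); te <- which(split$fold == fold)
    state <- train_fold(subset_compound_table(table, tr), config,
                        word_vectors = word_vectors,
                        graph_cache = cache[tr])
    pred_graphs <- lapply(cache[te], `[[`, "graph")
    pred <- predict_pathways(state, pred_graphs)
    m <- multilabel_metrics(table$labels[te, , drop = FALSE], pred$logits,
                            pred$decisions)
    per_fold[fold + 1L, ] <- unlist(m)[metric_names]
    if (verbose)
      message(sprintf("fold %d/%d  f1 %.3f", fold + 1L, k,
                      per_fold[fold + 1L, "f1"]))
  }
  structure(list(per_fold = as.data.frame(per_fold),
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2, stats::sd),
                 k = k, seed = config$seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  for (nm in names(x$mean))
    cat(sprintf("  %-13s %.4f +/- %.4f\n", nm, x$mean[nm], x$sd[nm]))
  invisible(x)
}

#' Grid search over the dependence threshold and trade-off coefficient
#'
#' Reduced-scale utility mirroring the tau/alpha grid experiment: for each
#' (tau, alpha) pair a model is trained on a random 80% split and its micro
#' accuracy measured on the remaining 20%.
#'
#' @param table A \code{compound_table}.
#' @param tau_values,alpha_values Numeric grids.
#' @param config Base configuration.
#' @param word_vectors Word-vector source.
#' @return Matrix of held-out accuracies (rows = tau, cols = alpha), with
#'   the best cell recorded in attribute \code{"best"}.
#' @export
grid_search <- function(table, tau_values, alpha_values, config,
                        word_vectors = NULL) {
  n <- length(table$ids)
  holdout <- with_local_seed(config$seed,
                             sample.int(n, size = max(1L, round(0.2 * n))))
  tr_tab <- subset_compound_table(table, setdiff(seq_len(n), holdout))
  te_tab <- subset_compound_table(table, holdout)
  cache_tr <- prepare_graph_cache(tr_tab)
  surface <- matrix(NA_real_, length(tau_values), length(alpha_values),
                    dimnames = list(tau = tau_values, alpha = alpha_values))
  for (i in seq_along(tau_values)) for (j in seq_along(alpha_values)) {
    cfg <- config
    cfg$tau <- tau_values[i]; cfg$alpha <- alpha_values[j]
    state <- train_fold(tr_tab, cfg, word_vectors = word_vectors,
                        graph_cache = cache_tr)
    surface[i, j] <- evaluate_model(state, te_tab)$accuracy
  }
  best <- which(surface == max(surface), arr.ind = TRUE)[1, ]
  attr(surface, "best") <- c(tau = tau_values[best[1]],
                             alpha = alpha_values[best[2]])
  surface
}
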