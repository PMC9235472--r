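# Independent brute-force oracles: explicit per-pair loops, no shared code
# with the layer implementations.

oracle_leaky <- function(x, slope) if (x > 0) x else slope * x

# Graph attention, one molecule: loops over atoms, neighbors and heads.
oracle_gat <- function(X, A, params) {
  N <- nrow(X)
  K <- params$K
  s <- ncol(params$W[[1]])
  out <- matrix(0, N, K * s)
  alpha_all <- lapply(seq_len(K), function(k) matrix(0, N, N))
  for (k in seq_len(K)) {
    W <- params$W[[k]]
    a1 <- params$a[[k]][1:s]
    a2 <- params$a[[k]][s + (1:s)]
    H <- matrix(0, N, s)
    for (i in seq_len(N)) H[i, ] <- as.numeric(X[i, ] %*% W)
    for (i in seq_len(N)) {
      nbrs <- c(i, which(A[i, ] == 1))
      e <- numeric(length(nbrs))
      for (m in seq_along(nbrs)) {
        j <- nbrs[m]
        e[m] <- oracle_leaky(sum(a1 * H[i, ]) + sum(a2 * H[j, ]),
                             params$leaky_slope)
      }
      w <- exp(e - max(e)); w <- w / sum(w)
      agg <- numeric(s)
      for (m in seq_along(nbrs)) {
        alpha_all[[k]][i, nbrs[m]] <- w[m]
        agg <- agg + w[m] * H[nbrs[m], ]
      }
      out[i, (k - 1) * s + (1:s)] <- pmax(agg, 0)
    }
  }
  list(features = out, alpha = alpha_all)
}

# Graph convolution: explicit construction of the normalized operator.
oracle_gcn <- function(H, A, W) {
  N <- nrow(A)
  At <- A + diag(N)
  D <- diag(N)
  for (i in seq_len(N)) D[i, i] <- sum(At[i, ])
  Dh <- diag(N)
  for (i in seq_len(N)) Dh[i, i] <- 1 / sqrt(D[i, i])
  pre <- Dh %*% At %*% Dh %*% H %*% W
  pmax(pre, 0)
}

# Pathway-graph convolution layer: explicit row normalization and loops.
oracle_pathway_layer <- function(H, M_w, W, alpha, slope) {
  C <- nrow(M_w)
  Mx <- alpha * M_w + diag(C)
  out_pre <- matrix(0, C, ncol(W))
  for (i in seq_len(C)) {
    mix <- numeric(ncol(H))
    di <- sum(Mx[i, ])
    for (j in seq_len(C)) mix <- mix + Mx[i, j] / di * H[j, ]
    out_pre[i, ] <- as.numeric(mix %*% W)
  }
  apply(out_pre, c(1, 2), oracle_leaky, slope = slope)
}

# Random small test graph (connected not required; no self loops).
random_graph_features <- function(n, q, p_edge = 0.5) {
  A <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p_edge) A[i, j] <- A[j, i] <- 1
    }
  }
  X <- matrix(stats::rnorm(n * q), n, q)
  list(A = A, X = X)
}

random_gat_params <- function(q, s, K, slope = 0.2) {
  structure(list(
    W = lapply(seq_len(K), function(k) matrix(stats::rnorm(q * s, sd = 0.5), q, s)),
    a = lapply(seq_len(K), function(k) stats::rnorm(2 * s, sd = 0.5)),
    K = K, leaky_slope = slope), class = "gat_params")
}

# Wrap a feature matrix + adjacency as a molecule_graph for layer calls.
as_fake_graph <- function(X, A) {
  structure(list(n_atoms = nrow(X), atom_features = X, adjacency = A,
                 bond_list = which(upper.tri(A) & A == 1, arr.ind = TRUE),
                 symbols = rep("C", nrow(X)), smiles = "<synthetic>"),
            class = "molecule_graph")
}
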