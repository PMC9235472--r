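test_that("attention layer matches the brute-force oracle on random graphs", {
  set.seed(101)
  for (trial in 1:6) {
    n <- sample(2:6, 1)
    g <- random_graph_features(n, q = 7)
    params <- random_gat_params(q = 7, s = 5, K = 3)
    got <- gat_layer(as_fake_graph(g$X, g$A), params)
    want <- oracle_gat(g$X, g$A, params)
    expect_lt(max(abs(got$features - want$features)), 1e-5)
    for (k in 1:3) {
      expect_lt(max(abs(got$attn$alpha[[k]] - want$alpha[[k]])), 1e-5)
    }
  }
})

test_that("attention degenerates correctly for equal and isolated atoms", {
  # two bonded atoms with identical features: attention 1/2 everywhere
  X <- rbind(c(1, 0, 1), c(1, 0, 1))
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  set.seed(7)
  params <- random_gat_params(q = 3, s = 4, K = 2)
  got <- gat_layer(as_fake_graph(X, A), params)
  for (k in 1:2) {
    expect_equal(got$attn$alpha[[k]], matrix(0.5, 2, 2), tolerance = 1e-12)
  }

  # isolated atom: self-attention 1, output ReLU(W'h)
  X1 <- matrix(c(0.5, -1, 2), 1, 3)
  A1 <- matrix(0, 1, 1)
  got1 <- gat_layer(as_fake_graph(X1, A1), params)
  expect_equal(got1$attn$alpha[[1]][1, 1], 1)
  want <- pmax(drop(X1 %*% params$W[[1]]), 0)
  expect_equal(drop(got1$features[1, 1:4]), want, tolerance = 1e-12)
})

test_that("attention rows sum to one over each neighborhood", {
  set.seed(11)
  g <- random_graph_features(5, q = 7)
  params <- random_gat_params(q = 7, s = 4, K = 4)
  got <- gat_layer(as_fake_graph(g$X, g$A), params)
  for (k in 1:4) {
    expect_equal(unname(rowSums(got$attn$alpha[[k]])), rep(1, 5),
                 tolerance = 1e-12)
  }
})

test_that("graph convolution matches the explicit normalized propagation", {
  set.seed(21)
  g <- random_graph_features(5, q = 6)
  W <- matrix(rnorm(6 * 4), 6, 4)
  got <- gcn_layer(g$X, g$A, list(W_A = W))
  expect_lt(max(abs(got - oracle_gcn(g$X, g$A, W))), 1e-5)

  # isolated atom: normalization is the identity
  X1 <- matrix(rnorm(6), 1, 6)
  got1 <- gcn_layer(X1, matrix(0, 1, 1), list(W_A = W))
  expect_equal(got1, pmax(X1 %*% W, 0), tolerance = 1e-12)

  # identical inputs on a symmetric 2-atom graph give identical outputs
  X2 <- rbind(c(1, 2, 3, 0, 1, -1), c(1, 2, 3, 0, 1, -1))
  got2 <- gcn_layer(X2, matrix(c(0, 1, 1, 0), 2, 2), list(W_A = W))
  expect_equal(got2[1, ], got2[2, ])
})

test_that("readout concatenates max and mean pooling", {
  expect_equal(readout(rbind(c(1, 2), c(3, 0))), c(3, 2, 2, 1))
  v <- c(0.3, -2, 5)
  expect_equal(readout(matrix(v, 1)), c(v, v))
  set.seed(3)
  m <- matrix(rnorm(20), 5, 4)
  expect_equal(readout(m), readout(m[sample(5), ]))
})

test_that("the full encoder composes the three stages", {
  g <- smiles_to_graph("CCO")
  set.seed(31)
  gat <- random_gat_params(q = 78, s = 6, K = 2)
  gcn <- list(W_A = matrix(rnorm(12 * 5, sd = 0.3), 12, 5))
  enc <- encode_compound(g, gat, gcn)
  manual <- readout(gcn_layer(gat_layer(g, gat)$features, g$adjacency, gcn))
  expect_equal(enc$embedding, manual, tolerance = 1e-12)
  expect_length(enc$embedding, 10)

  # zero weights give the zero embedding
  gat0 <- gat
  gat0$W <- lapply(gat0$W, function(w) w * 0)
  enc0 <- encode_compound(g, gat0, gcn)
  expect_true(all(enc0$embedding == 0))
})

test_that("the embedding is invariant to atom permutation", {
  set.seed(41)
  g <- random_graph_features(6, q = 9, p_edge = 0.6)
  gat <- random_gat_params(q = 9, s = 5, K = 3)
  gcn <- list(W_A = matrix(rnorm(15 * 4), 15, 4))
  fg <- as_fake_graph(g$X, g$A)
  z1 <- encode_compound(fg, gat, gcn)$embedding
  perm <- sample(6)
  fg2 <- as_fake_graph(g$X[perm, ], g$A[perm, perm])
  z2 <- encode_compound(fg2, gat, gcn)$embedding
  expect_lt(max(abs(z1 - z2)), 1e-5)
})

test_that("default-sized encoder emits the 1560-d embedding", {
  cfg <- train_config(seed = 2)
  state <- init_model(cfg, n_labels = 11)
  g <- smiles_to_graph("CCO")
  enc <- encode_compound(g, state$gat, state$gcn)
  expect_length(enc$embedding, 1560L)
})
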