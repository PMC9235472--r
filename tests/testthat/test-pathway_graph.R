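# Hand-derived reference for the 3-label toy (label sets {1,2}, {1}, {2,3}):
#   N = (2, 2, 1); U_12 = 1, U_23 = 1, U_13 = 0
#   P = [[0, 1/2, 0], [1/2, 0, 1/2], [0, 1, 0]]
#   M (tau = 0.5): edges 1->2, 2->1, 2->3, 3->2; column sums (1, 2, 1)
#   M_w = [[0, 1/2, 0], [1, 0, 1], [0, 1/2, 0]]

test_that("co-occurrence counting matches hand enumeration", {
  st <- count_cooccurrence(toy_labelsets())
  expect_equal(st$N, c(2, 2, 1))
  expect_equal(st$U, matrix(c(0, 1, 0,
                              1, 0, 1,
                              0, 1, 0), 3, byrow = TRUE))

  # no co-occurrence among singletons
  singles <- diag(3)
  expect_true(all(count_cooccurrence(singles)$U == 0))

  # duplicating every label set doubles U and N
  dup <- rbind(toy_labelsets(), toy_labelsets())
  st2 <- count_cooccurrence(dup)
  expect_equal(st2$U, 2 * st$U)
  expect_equal(st2$N, 2 * st$N)
})

test_that("conditional probabilities are asymmetric and guarded", {
  P <- conditional_probability(count_cooccurrence(toy_labelsets()))
  expect_equal(P, matrix(c(0, 0.5, 0,
                           0.5, 0, 0.5,
                           0, 1, 0), 3, byrow = TRUE))
  expect_false(isSymmetric(P))
  expect_true(all(P >= 0 & P <= 1))

  # a label that never occurs gets a zero row, not NaN
  st <- count_cooccurrence(matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(st$N, c(2, 0))
  P0 <- conditional_probability(st)
  expect_equal(P0[2, ], c(0, 0))
  expect_false(anyNA(P0))
})

test_that("binarization thresholds as specified and is monotone", {
  P <- conditional_probability(count_cooccurrence(toy_labelsets()))
  M <- binarize_dependence(P, 0.5)
  expect_equal(M, matrix(c(0, 1, 0,
                           1, 0, 1,
                           0, 1, 0), 3, byrow = TRUE))
  # a threshold just above the largest entry removes every edge
  P_scaled <- P * 0.8
  expect_true(all(binarize_dependence(P_scaled, max(P_scaled) + 1e-9) == 0))
  # raising tau never adds edges
  taus <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (i in seq_len(length(taus) - 1)) {
    M_lo <- binarize_dependence(P, taus[i])
    M_hi <- binarize_dependence(P, taus[i + 1])
    expect_true(all(M_hi <= M_lo))
  }
})

test_that("column re-weighting matches hand values and normalizes columns", {
  M <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, byrow = TRUE)
  Mw <- reweight_dependence(M)
  expect_equal(Mw, matrix(c(0, 0.5, 0,
                            1, 0, 1,
                            0, 0.5, 0), 3, byrow = TRUE))
  cs <- colSums(Mw)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
  # all-zero matrix passes through unharmed
  expect_equal(reweight_dependence(matrix(0, 3, 3)), matrix(0, 3, 3))
})

test_that("the full dependence chain reproduces the toy end to end", {
  Q <- matrix(rnorm(3 * 4), 3, 4)
  dep <- build_dependence_graph(toy_labelsets(), 0.5, Q)
  expect_equal(dep$M_w, matrix(c(0, 0.5, 0,
                                 1, 0, 1,
                                 0, 0.5, 0), 3, byrow = TRUE))
  expect_false(isSymmetric(dep$P))
})

test_that("word vectors load from GloVe text format", {
  vecs <- read_word_vectors(mini_word_vectors_path())
  expect_true(is.matrix(vecs))
  expect_equal(ncol(vecs), 10L)
  expect_true(all(c("metabolism", "energy", "amino") %in% rownames(vecs)))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("tok 1.0 2.0", "tok2 1.0"), bad)
  expect_error(read_word_vectors(bad), "format error")
})

test_that("pathway feature initialization averages tokens and handles OOV", {
  vecs <- read_word_vectors(mini_word_vectors_path())
  Q <- init_pathway_features(c("energy metabolism", "zzz qqq"), vecs,
                             seed = 4)
  expect_equal(dim(Q), c(2L, 10L))
  expect_equal(Q[1, ],
               unname(colMeans(vecs[c("energy", "metabolism"), ])))
  # all-OOV row is a reproducible Gaussian vector
  Q2 <- init_pathway_features(c("energy metabolism", "zzz qqq"), vecs,
                              seed = 4)
  expect_identical(Q, Q2)
  # tokenization strips punctuation and case
  Q3 <- init_pathway_features("Energy, METABOLISM!", vecs, seed = 1)
  expect_equal(Q3[1, ], Q[1, ])

  # full-random ablation mode
  R1 <- init_pathway_features(c("a", "b"), r = 10, seed = 9, random = TRUE)
  R2 <- init_pathway_features(c("a", "b"), r = 10, seed = 9, random = TRUE)
  expect_identical(R1, R2)
  expect_equal(dim(R1), c(2L, 10L))
})
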