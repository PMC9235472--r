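# Single-sample toy used across the metric tests:
#   truth   Y = (1, 0, 1, 0)
#   scores  S = (0.9, 0.8, 0.1, 0.2)
#   calls   D = (1, 1, 0, 0)
toy_Y <- matrix(c(1, 0, 1, 0), 1)
toy_S <- matrix(c(0.9, 0.8, 0.1, 0.2), 1)
toy_D <- matrix(c(1, 1, 0, 0), 1)

test_that("hamming loss counts disagreeing cells", {
  expect_equal(hamming_loss(toy_Y, toy_D), 0.5)
  expect_equal(hamming_loss(toy_Y, toy_Y), 0)
  expect_equal(hamming_loss(toy_Y, 1 - toy_Y), 1)
})

test_that("micro accuracy/precision/recall/F1 match the confusion counts", {
  m <- prf_accuracy(toy_Y, toy_D)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)

  perfect <- prf_accuracy(toy_Y, toy_Y)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1,
                                  recall = 1, f1 = 1))

  # nothing predicted, nothing true: ratios 0 by convention, accuracy 1
  expect_warning(
    expect_warning(
      m0 <- prf_accuracy(matrix(0, 2, 3), matrix(0, 2, 3)),
      "precision undefined"),
    "recall undefined")
  expect_equal(m0$accuracy, 1)
  expect_equal(m0$precision, 0)
  expect_equal(m0$recall, 0)
})

test_that("ranking loss enumerates reversed pairs", {
  expect_equal(ranking_loss(toy_Y, toy_S), 0.5)
  # perfectly separated scores
  expect_equal(ranking_loss(toy_Y, matrix(c(5, -1, 4, -2), 1)), 0)
  # an all-true sample has no pairs and is excluded from the average
  Y <- rbind(c(1, 1), c(1, 0))
  S <- rbind(c(0.1, 0.9), c(0.9, 0.1))
  expect_equal(ranking_loss(Y, S), 0)
})

test_that("coverage finds the worst-ranked true label", {
  expect_equal(coverage(toy_Y, toy_S), 4)
  expect_equal(coverage(toy_Y, toy_S, zero_based = TRUE), 3)
  expect_equal(coverage(matrix(c(1, 0, 0), 1),
                        matrix(c(9, 2, 1), 1)), 1)
  expect_equal(coverage(matrix(1, 1, 5), matrix(rnorm(5), 1)), 5)
})

test_that("one-error checks the top-ranked label with index tie-break", {
  expect_equal(one_error(toy_Y, toy_S), 0)
  expect_equal(one_error(matrix(c(0, 1), 1), matrix(c(0.9, 0.1), 1)), 1)
  # exact tie between a true and a false label: lowest index wins
  expect_equal(one_error(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), 0)
  expect_equal(one_error(matrix(c(0, 1), 1), matrix(c(0.5, 0.5), 1)), 1)
})

test_that("micro accuracy and hamming loss are exact complements", {
  set.seed(8)
  for (i in 1:5) {
    Y <- matrix(rbinom(60, 1, 0.4), 10, 6)
    D <- matrix(rbinom(60, 1, 0.5), 10, 6)
    m <- suppressWarnings(prf_accuracy(Y, D))
    expect_equal(m$accuracy + hamming_loss(Y, D), 1)
  }
})

test_that("ranking metrics are invariant to monotone score transforms", {
  set.seed(9)
  Y <- matrix(rbinom(40, 1, 0.4), 8, 5)
  Y[rowSums(Y) == 0, 1] <- 1
  S <- matrix(rnorm(40), 8, 5)
  for (f in list(function(x) 2 * x + 3, function(x) exp(x),
                 function(x) stats::plogis(x))) {
    expect_equal(ranking_loss(Y, S), ranking_loss(Y, f(S)))
    expect_equal(coverage(Y, S), coverage(Y, f(S)))
    expect_equal(one_error(Y, S), one_error(Y, f(S)))
  }
})

test_that("the bundled aggregate computes all eight metrics at once", {
  m <- multilabel_metrics(toy_Y, toy_S, toy_D)
  expect_named(m, c("accuracy", "precision", "recall", "f1",
                    "hamming_loss", "ranking_loss", "coverage",
                    "one_error"))
  expect_equal(m$hamming_loss, 0.5)
  expect_equal(m$ranking_loss, 0.5)
  expect_equal(m$coverage, 4)
  expect_equal(m$one_error, 0)
})
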