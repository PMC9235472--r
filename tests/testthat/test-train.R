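test_that("training reduces the loss and is deterministic given the seed", {
  tab <- generate_fixture(60, 3, seed = 13)
  cfg <- tiny_config(epochs = 8L, seed = 4L)
  s1 <- train_fold(tab, cfg)
  expect_lt(tail(s1$loss_trajectory, 1), s1$initial_loss)
  s2 <- train_fold(tab, cfg)
  expect_equal(tail(s1$loss_trajectory, 1), tail(s2$loss_trajectory, 1),
               tolerance = 1e-6)
  expect_error(train_fold(subset_compound_table(tab, integer(0)),
                          cfg), "empty training set")
})

test_that("all three ablation arms train and lower their loss", {
  tab <- generate_fixture(60, 3, seed = 14)
  for (arm in c("no_pathway_encoder", "no_adapter", "random_label_init")) {
    cfg <- tiny_config(epochs = 6L, seed = 2L, ablation = arm)
    st <- train_fold(tab, cfg)
    expect_lt(tail(st$loss_trajectory, 1), st$initial_loss)
    expect_equal(nrow(st$O), 3L)
  }
  # no-adapter arm must emit pathway embeddings at the compound width
  cfg <- tiny_config(epochs = 2L, ablation = "no_adapter")
  st <- train_fold(tab, cfg)
  expect_equal(ncol(st$O), 2L * cfg$gcn_dim)
})

test_that("prediction emits calibrated shapes and consistent decisions", {
  tab <- generate_fixture(40, 3, seed = 15)
  cfg <- tiny_config(epochs = 4L, seed = 1L)
  st <- train_fold(tab, cfg)
  pred <- predict_pathways(st, tab)
  expect_equal(dim(pred$logits), c(40L, 3L))
  expect_equal(pred$probabilities, stats::plogis(pred$logits))
  expect_equal(pred$decisions,
               decide(pred$logits, cfg$decision_threshold))
  m <- evaluate_model(st, tab)
  expect_true(all(is.finite(unlist(m))))
})

test_that("cross-validation aggregates per-fold metrics without leakage", {
  tab <- generate_fixture(50, 3, seed = 16)
  cfg <- tiny_config(epochs = 3L, seed = 3L)
  rep <- cross_validate(tab, cfg, k = 2L)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_fold), 2L)
  expect_true(all(is.finite(unlist(rep$per_fold))))
  expect_equal(unname(rep$mean["f1"]), mean(rep$per_fold$f1))

  # the dependence graph inside each fold is built from training folds only
  split <- make_cv_split(tab, 2L, cfg$seed)
  tr0 <- which(split$fold != 0L)
  st <- train_fold(subset_compound_table(tab, tr0), cfg)
  expect_equal(st$dependence$N,
               unname(colSums(tab$labels[tr0, , drop = FALSE])))
})

test_that("grid search returns a valid accuracy surface", {
  tab <- generate_fixture(40, 3, seed = 17)
  cfg <- tiny_config(epochs = 2L, seed = 1L)
  surf <- grid_search(tab, c(0.3, 0.6), c(0.2, 0.8), cfg)
  expect_equal(dim(surf), c(2L, 2L))
  expect_true(all(surf >= 0 & surf <= 1))
  best <- attr(surf, "best")
  expect_true(best["tau"] %in% c(0.3, 0.6))
  expect_true(best["alpha"] %in% c(0.2, 0.8))
})
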