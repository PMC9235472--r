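test_that("CSV round-trips identically through write and read", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path)
  tab <- read_dataset(path)
  expect_s3_class(tab, "compound_table")
  expect_equal(length(tab$ids), 3L)
  expect_equal(ncol(tab$labels), 2L)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(tab, path2)
  tab2 <- read_dataset(path2)
  expect_equal(tab, tab2)
})

test_that("malformed input is rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = "a", notsmiles = "C", l1 = 1, l2 = 0),
                   path, row.names = FALSE)
  expect_error(read_dataset(path), "smiles")

  path3 <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path3, labels = matrix(c(1, 0, 2, 1, 0, 1), 3, 2))
  expect_error(read_dataset(path3), "row 3")

  path4 <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path4)
  expect_error(read_dataset(path4, label_columns = c("nope")), "nope")
})

test_that("structure filtering removes exactly the unparsable records", {
  tab <- new_compound_table(
    c("a", "b", "c"), c("C", "not_a_smiles", "CCO"),
    matrix(c(1, 1, 1, 0, 1, 0), 3, 2), c("p1", "p2"))
  out <- filter_valid_structures(tab)
  expect_equal(length(out$table$ids), 2L)
  expect_equal(out$removed_ids, "b")
  # idempotent on the already-filtered table
  again <- filter_valid_structures(out$table)
  expect_equal(again$table, out$table)
  expect_length(again$removed_ids, 0L)
})

test_that("label statistics reproduce hand counts and are permutation-stable", {
  tab <- new_compound_table(c("a", "b"), c("C", "CC"),
                            matrix(c(1, 1, 0, 1), 2, 2), c("p1", "p2"))
  st <- label_statistics(tab)
  expect_equal(unname(st$per_label), c(2, 1))
  expect_equal(st$single_label, 1L)
  expect_equal(st$multi_label, 1L)
  expect_equal(st$total_entries, 3)

  one <- new_compound_table("a", "C", matrix(c(1, 0), 1, 2), c("p1", "p2"))
  st1 <- label_statistics(one)
  expect_equal(st1$single_label, 1L)
  expect_equal(st1$multi_label, 0L)
  expect_equal(st1$total_entries, 1)

  tab2 <- generate_fixture(30, 3, seed = 5)
  perm <- sample(30)
  st_a <- label_statistics(tab2)
  st_b <- label_statistics(subset_compound_table(tab2, perm))
  expect_equal(st_a$per_label, st_b$per_label)
  expect_equal(st_a$total_entries, st_b$total_entries)
})

test_that("cross-validation folds are balanced and deterministic", {
  tab <- generate_fixture(10, 2, seed = 3)
  s1 <- make_cv_split(tab, 5, seed = 9)
  expect_equal(as.integer(table(s1$fold)), rep(2L, 5))
  s2 <- make_cv_split(tab, 5, seed = 9)
  expect_identical(s1$fold, s2$fold)

  tab11 <- generate_fixture(11, 2, seed = 3)
  s3 <- make_cv_split(tab11, 5, seed = 1)
  expect_equal(sort(as.integer(table(s3$fold))), c(2L, 2L, 2L, 2L, 3L))

  expect_error(make_cv_split(tab, 11, seed = 1), "exceeds")
})

test_that("fixture generator plants the requested co-occurrence", {
  # forced dependence: joint equals the first label's marginal
  C <- 2
  J <- matrix(c(0.3, 0.3, 0.3, 0.6), 2, 2)
  tab <- generate_fixture(100, 2, J, seed = 21)
  with_l0 <- tab$labels[, 1] == 1
  expect_true(all(tab$labels[with_l0, 2] == 1))

  # independent labels: conditional close to marginal at n = 2000
  J2 <- matrix(c(0.5, 0.25, 0.25, 0.5), 2, 2)
  tab2 <- generate_fixture(2000, 2, J2, seed = 22, structure_strength = 0)
  l0 <- tab2$labels[, 1] == 1
  cond <- mean(tab2$labels[l0, 2])
  expect_lt(abs(cond - 0.5), 0.05)

  # infeasible joints are rejected
  bad <- matrix(c(0.2, 0.5, 0.5, 0.2), 2, 2)
  expect_error(generate_fixture(10, 2, bad, seed = 1), "infeasible")
})

test_that("every generated fixture SMILES yields a valid molecular graph", {
  tab <- generate_fixture(60, 6, seed = 77)
  out <- filter_valid_structures(tab)
  expect_length(out$removed_ids, 0L)
  # deterministic given the seed
  tab2 <- generate_fixture(60, 6, seed = 77)
  expect_identical(tab$smiles, tab2$smiles)
  expect_identical(tab$labels, tab2$labels)
})
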