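# Small shared fixtures built in code.

# The 3-label toy used throughout the dependence-graph tests:
# label sets {1,2}, {1}, {2,3} (1-based).
toy_labelsets <- function() {
  matrix(c(1, 1, 0,
           1, 0, 0,
           0, 1, 1), nrow = 3, byrow = TRUE)
}

toy_table <- function() {
  tab <- generate_fixture(8, 3, seed = 42)
  tab
}

tiny_config <- function(...) {
  reduced_config(epochs = 5L, batch_size = 16L, heads = 2L,
                 gat_head_dim = 8L, adapter_hidden = 16L,
                 pathway_hidden = 16L, pathway_out = 16L, ...)
}

write_toy_csv <- function(path,
                          ids = c("a", "b", "c"),
                          smiles = c("C", "CC", "CCO"),
                          labels = matrix(c(1, 0, 1, 1, 1, 1), 3, 2),
                          label_names = c("carbohydrate metabolism",
                                          "energy metabolism")) {
  df <- data.frame(id = ids, smiles = smiles, check.names = FALSE)
  lab <- as.data.frame(labels)
  names(lab) <- label_names
  utils::write.csv(cbind(df, lab), path, row.names = FALSE, quote = FALSE)
  path
}
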