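# Attention-based per-bond interpretation.

#' Per-bond importance from attention coefficients
#'
#' For each undirected bond (i, j) the importance is the mean of the
#' attention coefficients over all heads and both directions (i -> j and
#' j -> i); the coefficients are direction-specific but chemical bonds are
#' not. Optionally min-max rescaled to [0, 1] within the compound for
#' display; raw weights are always retained.
#'
#' @param attn An \code{attention_map} from \code{\link{gat_layer}} /
#'   \code{\link{encode_compound}}.
#' @param graph The molecule graph the map was computed on.
#' @param compound_id Identifier recorded in the output.
#' @param rescale Add a min-max rescaled weight column.
#' @return A \code{bond_importance} data frame with columns
#'   \code{compound_id}, \code{atom_i}, \code{atom_j}, \code{weight} and
#'   (if \code{rescale}) \code{weight_scaled}.
#' @export
bond_importance <- function(attn, graph, compound_id = graph$smiles,
                            rescale = TRUE) {
  stopifnot(inherits(attn, "attention_map"))
  if (attn$n_atoms != graph$n_atoms)
    stop("attention map and molecule graph have different atom counts")
  bl <- graph$bond_list
  K <- length(attn$alpha)
  w <- vapply(seq_len(nrow(bl)), function(b) {
    i <- bl[b, 1]; j <- bl[b, 2]
    mean(vapply(attn$alpha, function(A) (A[i, j] + A[j, i]) / 2,
                numeric(1)))
  }, numeric(1))
  out <- data.frame(compound_id = rep(compound_id, nrow(bl)),
                    atom_i = bl[, 1], atom_j = bl[, 2], weight = w,
                    stringsAsFactors = FALSE)
  if (rescale && nrow(out)) {
    rng <- range(out$weight)
    out$weight_scaled <- if (diff(rng) > 0)
      (out$weight - rng[1]) / diff(rng) else rep(0.5, nrow(out))
  }
  class(out) <- c("bond_importance", "data.frame")
  out
}

#' Export bond importances to CSV
#'
#' @param imp A \code{bond_importance} data frame (or several row-bound).
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
export_importance <- function(imp, path) {
  utils::write.csv(as.data.frame(imp), path, row.names = FALSE)
  invisible(path)
}

#' Read back an exported bond-importance CSV
#' @param path CSV path written by \code{\link{export_importance}}.
#' @return A \code{bond_importance} data frame.
#' @export
read_importance <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("bond_importance", "data.frame")
  out
}

#' Bond importances for a table of compounds under a trained model
#'
#' Convenience wrapper: encodes each compound with the trained parameters
#' and aggregates per-bond attention weights, annotated with the bonded
#' element symbols so substructure classes (e.g. sulfur/phosphorus bonds
#' versus carbon-carbon backbone bonds) can be compared.
#'
#' @param state Trained \code{model_state}.
#' @param table A \code{compound_table}.
#' @return A \code{bond_importance} data frame with extra columns
#'   \code{symbol_i}, \code{symbol_j}.
#' @export
model_bond_importance <- function(state, table) {
  rows <- lapply(seq_along(table$ids), function(i) {
    g <- smiles_to_graph(table$smiles[i])
    if (!nrow(g$bond_list)) return(NULL)
    enc <- encode_compound(g, state$gat, state$gcn)
    imp <- bond_importance(enc$attn, g, compound_id = table$ids[i])
    imp$symbol_i <- g$symbols[imp$atom_i]
    imp$symbol_j <- g$symbols[imp$atom_j]
    imp
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bond_importance", "data.frame")
  out
}
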